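#!/usr/bin/env Rscript
# Stage 7: inference. Permutation test of the paddock-field distance
# contrast and rank correlation between agonistic approaches and spacing.

suppressPackageStartupMessages(library(equiprox))

out <- "results/analysis"
meta <- yaml::read_yaml(file.path(out, "config.yaml"))

dy <- lapply(names(meta$conditions), function(cond) {
  read.csv(file.path(out, sprintf("dyad_distances_%s.csv", cond)))
})
names(dy) <- names(meta$conditions)
fp <- fisher_pitman(dy$paddock$median_cm, dy$field$median_cm,
                    n_iter = 1000, seed = meta$seed)
cat(sprintf(
  "paddock vs field per-dyad medians: difference of means %.0f cm, Monte-Carlo p = %.4g (1000 iterations)\n",
  fp$observed_stat, fp$p_value))

edf <- do.call(rbind, lapply(names(meta$conditions), function(cond) {
  d <- dy[[cond]]
  ev <- read.csv(file.path(out, sprintf("events_%s.csv", cond)))
  ap <- ev[ev$kind == "approach", ]
  counts <- table(factor(paste(ap$a, ap$b, sep = "|"), levels = d$dyad))
  data.frame(median_cm = d$median_cm, n_approach = as.integer(counts))
}))
rho <- spearman_rho(edf$n_approach, edf$median_cm)
cat(sprintf(
  "Spearman correlation, approaches per dyad vs median distance: rho = %.3f over %d dyad-conditions\n",
  rho, nrow(edf)))

jsonlite::write_json(
  list(fisher_pitman = list(observed_diff_cm = fp$observed_stat,
                            p_value = fp$p_value, n_iter = fp$n_iter),
       spearman_approaches_vs_distance = rho),
  file.path(out, "stats.json"), auto_unbox = TRUE, digits = 6, pretty = TRUE)
cat("wrote", file.path(out, "stats.json"), "\n")
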
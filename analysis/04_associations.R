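#!/usr/bin/env Rscript
# Stage 4: time in proximity bins, closest / least frequent associates and
# affiliation strata per condition.

suppressPackageStartupMessages(library(equiprox))

out <- "results/analysis"
meta <- yaml::read_yaml(file.path(out, "config.yaml"))

for (cond in names(meta$conditions)) {
  roster <- unlist(meta$conditions[[cond]]$roster)
  series <- series_from_table(
    read.csv(file.path(out, sprintf("cleaned_%s.csv", cond))))
  assoc <- association_matrix(series, roster)
  write.csv(as.data.frame(assoc$fractions[, , 1]),
            file.path(out, sprintf("close_fraction_%s.csv", cond)))
  at <- associate_table(assoc, cond)
  write.csv(at, file.path(out, sprintf("associates_%s.csv", cond)),
            row.names = FALSE)
  write.csv(affiliation_strata(assoc, cond),
            file.path(out, sprintf("affiliation_strata_%s.csv", cond)),
            row.names = FALSE)
  mutual <- sum(vapply(seq_len(nrow(at)), function(i) {
    at$closest[at$animal == at$closest[i]] == at$animal[i]
  }, TRUE))
  cat(sprintf(
    "%s: mean close-proximity fraction with closest associate %.1f%%, with least frequent %.2f%%; %d horses in mutual closest pairs\n",
    cond, 100 * mean(at$closest_frac), 100 * mean(at$least_frequent_frac),
    mutual))
}
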
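#!/usr/bin/env Rscript
# Stage 2: apply the four cleaning rules (range, frozen-run, feeder
# proximity, replicate averaging) to the raw streams and persist one
# cleaned series table per condition.

suppressPackageStartupMessages(library(equiprox))

out <- "results/analysis"
meta <- yaml::read_yaml(file.path(out, "config.yaml"))

for (cond in names(meta$conditions)) {
  mc <- meta$conditions[[cond]]
  enc <- enclosure_config(mc$length_m, mc$width_m, n_horses = mc$n_horses,
                          tracking_hours = mc$tracking_hours,
                          area_m2 = mc$area_m2,
                          feeder_channel = if (isTRUE(mc$feeder)) "FEEDER")
  raw <- load_distance_csv(file.path(out, "raw",
                                     sprintf("%s_distances.csv", cond)),
                           roster = unlist(mc$roster))
  cl <- clean_distances(raw$data, enc)
  write.csv(cl$report, file.path(out, sprintf("cleaning_%s.csv", cond)),
            row.names = FALSE)
  write.csv(series_to_table(cl$series),
            file.path(out, sprintf("cleaned_%s.csv", cond)),
            row.names = FALSE)
  rp <- cl$report
  cat(sprintf(
    "%s: %d raw channel samples; removed %d out-of-range, %d frozen, %d feeder; %d averaged samples kept\n",
    cond, sum(rp$raw), sum(rp$removed_range), sum(rp$removed_frozen),
    sum(rp$removed_feeder), sum(rp$kept_averaged)))
}
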
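#!/usr/bin/env Rscript
# Within-speed ideal-observer classification of edge orientation from
# intensity measures (peak, mean rate) and firing-rate profiles. Profiles
# carry far more orientation information than intensity.

suppressPackageStartupMessages(library(edgecode))

records <- load_dataset("results/dataset")
res <- list()
for (r in records) {
  ts <- segment_trials(r)
  for (v in sort(unique(ts$meta$speed_mm_s))) {
    res[[length(res) + 1]] <- intensity_classify_within(ts, v, "peak")
    res[[length(res) + 1]] <- intensity_classify_within(ts, v, "mean")
    res[[length(res) + 1]] <- profile_classify_within(ts, v, "temporal")
    res[[length(res) + 1]] <- profile_classify_within(ts, v, "spatial")
  }
}
res <- do.call(rbind, res)
write.csv(res, "results/within_speed.csv", row.names = FALSE)

summ <- aggregate_results(res, by = c("type", "scheme"))
summ <- summ[order(summ$scheme, summ$type), ]
cat("mean within-speed accuracy (chance 0.25), averaged over speeds:\n")
print(summ, digits = 3, row.names = FALSE)
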
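#!/usr/bin/env Rscript
# Segment every neuron into 8 mm response windows and compute the intensity
# measures. Reproduces the qualitative speed dependence of the responses:
# mean (and peak) firing rate rise with scanning speed while the number of
# spikes per edge passage falls.

suppressPackageStartupMessages(library(edgecode))

records <- load_dataset("results/dataset")
features <- do.call(rbind, lapply(records, function(r) {
  feature_table(segment_trials(r))
}))
write.csv(features, "results/features.csv", row.names = FALSE)

cat("feature rows:", nrow(features), "\n\n")
trend <- aggregate(cbind(n_spikes, mean_hz, peak_hz) ~ type + speed_mm_s,
                   features, mean)
trend <- trend[order(trend$type, trend$speed_mm_s), ]
print(trend, digits = 3, row.names = FALSE)

for (m in c("peak", "mean")) {
  fit <- fit_population_speed_function(features, m)
  for (tp in names(fit$fits)) {
    cat(sprintf("%s %s-rate speed line: %.3f Hz/(mm/s) x v + %.1f Hz\n",
                tp, m, fit$fits[[tp]]$slope, fit$fits[[tp]]$intercept))
  }
}
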
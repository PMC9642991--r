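#!/usr/bin/env Rscript
# Across-speed (speed-invariant) classification. Intensity measures fail
# across speeds -- with or without normalisation by the population
# speed-intensity line -- while firing-rate profiles remain informative
# when represented in the spatial domain (spikes referenced to drum
# position), and not in the temporal domain.

suppressPackageStartupMessages(library(edgecode))

records <- load_dataset("results/dataset")
features <- read.csv("results/features.csv")
fit <- fit_population_speed_function(features, "peak")

res <- list()
for (r in records) {
  ts <- segment_trials(r)
  for (v in sort(unique(ts$meta$speed_mm_s))) {
    res[[length(res) + 1]] <- intensity_classify_across(ts, v, "peak")
    res[[length(res) + 1]] <- intensity_classify_across(ts, v, "peak",
                                                        normalize = TRUE,
                                                        fit = fit)
    res[[length(res) + 1]] <- intensity_classify_across(ts, v, "mean")
    res[[length(res) + 1]] <- profile_classify_across(ts, v, "temporal")
    res[[length(res) + 1]] <- profile_classify_across(ts, v, "spatial")
  }
}
res <- do.call(rbind, res)
write.csv(res, "results/across_speed.csv", row.names = FALSE)

cat("mean across-speed accuracy by core speed (chance 0.25):\n")
summ <- aggregate_results(res, by = c("scheme", "core_speed"))
wide <- reshape(summ[, c("scheme", "core_speed", "mean_accuracy")],
                idvar = "core_speed", timevar = "scheme",
                direction = "wide")
print(wide[order(wide$core_speed), ], digits = 3, row.names = FALSE)
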
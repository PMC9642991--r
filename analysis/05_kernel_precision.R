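#!/usr/bin/env Rscript
# Spatial precision of spiking: convolve spatial spike trains with Gaussian
# kernels (5-1280 um), correlate across speeds, and find the kernel SD
# maximising the same-minus-different orientation correlation difference
# ("best kernel"). Convert the type-averaged precision to an equivalent
# sinusoidal period.

suppressPackageStartupMessages(library(edgecode))

records <- load_dataset("results/dataset")
curves <- do.call(rbind, lapply(records, function(r) {
  correlation_curves(segment_trials(r))
}))
write.csv(curves, "results/kernel_curves.csv", row.names = FALSE)

bk <- best_kernel(curves)
write.csv(bk$per_neuron, "results/best_kernels.csv", row.names = FALSE)

cat("difference curve, averaged over neurons and core speeds:\n")
print(aggregate(diff ~ sigma_um, curves, mean), digits = 3,
      row.names = FALSE)

ok <- !bk$per_neuron$flagged
type_kernels <- tapply(bk$per_neuron$mean_best_sigma_um[ok],
                       bk$per_neuron$type[ok], mean)
cat("\nmean best kernel by type (um):\n")
print(round(type_kernels, 1))

sigma <- mean(type_kernels)
cat(sprintf("\ntype-averaged precision %.1f um -> sinusoidal period %.2f mm\n",
            sigma, gaussian_to_period(sigma) / 1000))
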
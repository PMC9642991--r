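#!/usr/bin/env Rscript
# Summary figures from the tables written by the earlier scripts: the
# speed-invariance contrast, the kernel difference curves, and pairwise
# accuracy by angular difference. Styling is utilitarian.

suppressPackageStartupMessages({
  library(edgecode)
  library(ggplot2)
})

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

acc <- read.csv("results/across_speed.csv")
summ <- aggregate_results(acc, by = c("type", "scheme", "core_speed"))
p1 <- ggplot(summ, aes(core_speed, mean_accuracy, colour = scheme)) +
  geom_line() + geom_point(size = 1) +
  geom_hline(yintercept = 0.25, linetype = 2) +
  facet_wrap(~type) + scale_x_log10() +
  labs(x = "core speed (mm/s)", y = "proportion correct",
       title = "Across-speed orientation classification") +
  theme_minimal()
ggsave("results/figures/across_speed.png", p1, width = 7, height = 3.5,
       dpi = 150)

cc <- read.csv("results/kernel_curves.csv")
cs <- aggregate(diff ~ type + sigma_um, cc, mean)
p2 <- ggplot(cs, aes(sigma_um, diff, colour = type)) +
  geom_line() + geom_point(size = 1) + scale_x_log10() +
  labs(x = "kernel SD (um)", y = "same - different R²",
       title = "Correlation difference vs kernel width") +
  theme_minimal()
ggsave("results/figures/kernel_curves.png", p2, width = 5, height = 3.5,
       dpi = 150)

pw <- read.csv("results/pairwise.csv")
ps <- aggregate(accuracy ~ type + dtheta + core_speed, pw, mean)
p3 <- ggplot(ps, aes(core_speed, accuracy, colour = factor(dtheta))) +
  geom_line() + geom_point(size = 1) +
  geom_hline(yintercept = 0.5, linetype = 2) +
  facet_wrap(~type) + scale_x_log10() +
  labs(x = "core speed (mm/s)", y = "proportion correct",
       colour = "delta theta (deg)",
       title = "Pairwise discrimination by angular difference") +
  theme_minimal()
ggsave("results/figures/pairwise.png", p3, width = 7, height = 3.5,
       dpi = 150)

cat("wrote results/figures/{across_speed,kernel_curves,pairwise}.png\n")
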
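test_that("well-separated intensities are classified perfectly within speed", {
  vals <- c(`-10` = 100, `-5` = 200, `5` = 300, `10` = 400)
  ts <- intensity_trial_set(function(o, v, k) vals[as.character(o)])
  res <- intensity_classify_within(ts, 30, "peak")
  expect_equal(res$accuracy, 1)
  expect_equal(res$n_decisions, 60)
  expect_equal(res$chance, 0.25)
})

test_that("ties count as incorrect under the strict argmax rule", {
  ts <- intensity_trial_set(function(o, v, k) 150)
  expect_equal(intensity_classify_within(ts, 30, "peak")$accuracy, 0)
})

test_that("orientation-blind intensities classify at chance", {
  set.seed(7)
  accs <- replicate(800, {
    ts <- intensity_trial_set(function(o, v, k) runif(1, 50, 500),
                              speeds = 30)
    intensity_classify_within(ts, 30, "peak")$accuracy
  })
  expect_lt(abs(mean(accs) - 0.25), 3 * sd(accs) / sqrt(length(accs)))
})

test_that("the population speed-intensity line matches hand OLS", {
  mk <- function(speed, val) {
    data.frame(neuron_id = "n1", type = "FA-1", speed_mm_s = speed,
               peak_hz = val, mean_hz = val)
  }
  ft <- rbind(mk(15, 20), mk(30, 30), mk(60, 50))
  fit <- fit_population_speed_function(ft, "mean")
  # hand OLS: slope = Sxy/Sxx = 700/1050, intercept = ybar - slope * xbar
  expect_equal(fit$fits[["FA-1"]]$slope, 700 / 1050, tolerance = 1e-9)
  expect_equal(fit$fits[["FA-1"]]$intercept, 10, tolerance = 1e-9)
  flat <- fit_population_speed_function(rbind(mk(15, 40), mk(60, 40)), "mean")
  expect_equal(flat$fits[["FA-1"]]$slope, 0, tolerance = 1e-12)
  expect_error(fit_population_speed_function(mk(30, 10), "mean"), "2 speeds")
})

test_that("speed normalization rescues multiplicative speed coding", {
  # intensity = orientation signal x speed: useless across speeds raw,
  # perfectly separable once divided by the fitted population line
  sig <- c(`-10` = 1, `-5` = 2, `5` = 3, `10` = 4)
  ts <- intensity_trial_set(function(o, v, k) sig[as.character(o)] * v,
                            speeds = c(15, 30, 60, 120))
  fit <- fit_population_speed_function(feature_table(ts), "peak")
  raw <- intensity_classify_across(ts, 15, "peak")
  norm <- intensity_classify_across(ts, 15, "peak", normalize = TRUE,
                                    fit = fit)
  expect_equal(norm$accuracy, 1)
  expect_lt(raw$accuracy, 0.6)
})

test_that("pure speed coding stays at chance with or without normalization", {
  set.seed(17)
  accs <- replicate(150, {
    ts <- intensity_trial_set(function(o, v, k) v * runif(1, 0.95, 1.05),
                              speeds = c(15, 30, 60))
    fit <- fit_population_speed_function(feature_table(ts), "peak")
    c(intensity_classify_across(ts, 15, "peak")$accuracy,
      intensity_classify_across(ts, 15, "peak", normalize = TRUE,
                                fit = fit)$accuracy)
  })
  for (r in 1:2) {
    expect_lt(abs(mean(accs[r, ]) - 0.25),
              3 * sd(accs[r, ]) / sqrt(ncol(accs)) + 1e-9)
  }
})

test_that("template-structured profiles classify perfectly; empty ones never", {
  ts <- template_trial_set(noise_um = 1)
  expect_equal(profile_classify_within(ts, 30, "spatial")$accuracy, 1)
  expect_equal(profile_classify_across(ts, 30, "spatial")$accuracy, 1)
  # all-empty trials: zero-variance profiles correlate 0 -> all ties
  empty <- ts
  empty$trials <- lapply(empty$trials, function(x)
    list(times_s = numeric(0), positions_um = numeric(0)))
  empty$meta$n_spikes <- 0L; empty$meta$flagged <- TRUE
  expect_equal(profile_classify_within(empty, 30, "spatial")$accuracy, 0)
})

test_that("across-speed classification requires at least two speeds", {
  ts <- template_trial_set(speeds = 30)
  expect_error(profile_classify_across(ts, 30, "spatial"), ">= 2 speeds")
  expect_error(intensity_classify_across(ts, 30, "peak"), ">= 2 speeds")
  expect_error(classify_convolved(ts, 70), ">= 2 speeds")
})

test_that("missing conditions raise errors naming them", {
  ts <- template_trial_set(speeds = c(15, 30))
  expect_error(profile_classify_within(ts, 90), "90")
  expect_error(intensity_classify_across(ts, 90, "peak"), "90")
})

test_that("pairwise decisions use the documented pair structure", {
  ts <- template_trial_set(noise_um = 1, speeds = c(15, 30, 60))
  pw <- pairwise_accuracy(ts, scheme = "profile-spatial")
  expect_setequal(unique(pw$dtheta), c(5, 10, 15, 20))
  n20 <- pw$n_decisions[pw$dtheta == 20 & pw$core_speed == 15]
  n5 <- pw$n_decisions[pw$dtheta == 5 & pw$core_speed == 15]
  # 20 deg: one pair (-10, +10); 5 deg: two pairs
  expect_equal(n20, 30 * 2)
  expect_equal(n5, 2 * 30 * 2)
  expect_equal(unique(pw$chance), 0.5)
  # separable templates -> perfect pairwise discrimination
  expect_true(all(pw$accuracy == 1))
  expect_error(pairwise_accuracy(ts, scheme = "profile-spatial",
                                 dtheta = 25), "not available")
})

test_that("confusion matrix blocks are row-stochastic with identity pattern when separable", {
  ts <- template_trial_set(noise_um = 1, speeds = c(15, 30))
  M <- smoothed_matrix(ts, 70)
  R <- suppressWarnings(cor(M)); R[is.na(R)] <- 0
  CM <- confusion_matrix(ts, R)
  expect_equal(dim(CM), c(8, 8))
  # each 4-column block of each row sums to 1
  for (v2 in c(15, 30)) {
    blk <- CM[, grepl(sprintf("^v%g_", v2), colnames(CM))]
    expect_equal(unname(rowSums(blk)), rep(1, 8))
  }
  # separable templates: all mass on the correct orientation
  for (v in c(15, 30)) for (v2 in c(15, 30)) for (o in c(-10, -5, 5, 10)) {
    expect_equal(unname(CM[sprintf("v%g_th%g", v, o),
                           sprintf("v%g_th%g", v2, o)]), 1)
  }
})

test_that("shuffling orientation labels preserves the design bookkeeping", {
  ts <- template_trial_set()
  set.seed(3)
  sh <- shuffle_orientations(ts)
  tab <- table(sh$meta$orientation_deg, sh$meta$speed_mm_s)
  expect_true(all(tab == 15))
  expect_true(all(tapply(sh$meta$trial_index,
                         interaction(sh$meta$speed_mm_s,
                                     sh$meta$orientation_deg),
                         function(x) identical(sort(x), 1:15))))
  # signals untouched
  expect_identical(sh$trials, ts$trials)
})
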
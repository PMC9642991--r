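test_that("dataset generation is reproducible from the seed", {
  cfg <- sim_config(n_fa = 1, n_sa = 1, speeds_mm_s = c(15, 60), seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$records[[1]]$spikes, b$records[[1]]$spikes)
  expect_identical(a$truth, b$truth)
  # and the canonical files are byte-identical
  p1 <- withr::local_tempdir(); p2 <- withr::local_tempdir()
  save_dataset(a$records, p1); save_dataset(b$records, p2)
  f1 <- readLines(file.path(p1, "fa_01", "spikes.csv"))
  f2 <- readLines(file.path(p2, "fa_01", "spikes.csv"))
  expect_identical(f1, f2)
})

test_that("FA-1 models carry about twice the subfields of SA-1 models", {
  set.seed(21)
  n_fa <- replicate(400, nrow(sample_neuron_model("FA-1")$centers_um))
  n_sa <- replicate(400, nrow(sample_neuron_model("SA-1")$centers_um))
  expect_equal(mean(n_fa) / mean(n_sa), 2, tolerance = 0.08)
  # centres lie within the stated ellipse
  m <- sample_neuron_model("FA-1")
  hp <- default_hyperparams("FA-1")
  expect_true(all((m$centers_um[, 1] / hp$ellipse_um[1])^2 +
                    (m$centers_um[, 2] / hp$ellipse_um[2])^2 <= 1))
  expect_error(sample_neuron_model("FA-1", list(ellipse_um = c(0, 100))),
               "degenerate")
})

test_that("edge drive matches its closed form and peaks where the line hits the subfield", {
  m <- structure(list(type = "FA-1",
                      centers_um = matrix(c(0, 0), 1),
                      amplitude = 1, sigma_sub_um = 100),
                 class = "subfield_model")
  expect_equal(edge_drive(m, 0, 0), 1)
  expect_equal(edge_drive(m, 0, 100), exp(-0.5))
  # off-axis subfield: maximum where the tilted line passes through it
  m$centers_um <- matrix(c(0, 500), 1)
  for (th in c(-10, 7)) {
    opt <- optimize(function(x) edge_drive(m, th, x),
                    c(-500, 500), maximum = TRUE)
    expect_equal(opt$maximum, -500 * tan(th * pi / 180), tolerance = 0.5)
  }
})

test_that("a silent model produces no spikes", {
  set.seed(1)
  m <- sample_neuron_model("FA-1", list(gain_hz = 0, background_hz = 0))
  expect_length(simulate_trial(m, 5, 30), 0)
})

test_that("spike count scales as (v/v0)^(beta-1) across speeds", {
  set.seed(31)
  m <- sample_neuron_model("FA-1", list(
    n_subfields = 1, sigma_sub_um = 100, amplitude = 1, gain_hz = 3000,
    background_hz = 0, refractory_s = 0, beta = 0.5, jitter_um = 0))
  m$centers_um <- matrix(c(0, 0), 1)
  n15 <- mean(replicate(500, length(simulate_trial(m, 0, 15))))
  n180 <- mean(replicate(500, length(simulate_trial(m, 0, 180))))
  expect_equal(n15 / n180, sqrt(180 / 15), tolerance = 0.12)
})

test_that("simulated spikes respect the refractory period and are ordered", {
  set.seed(41)
  m <- sample_neuron_model("FA-1")
  for (i in 1:20) {
    t <- simulate_trial(m, 10, 45)
    if (length(t) > 1) expect_true(all(diff(t) >= m$refractory_s))
  }
})

test_that("the factorial design is complete and counts/rates follow speed", {
  dat <- generate_dataset(sim_config(n_fa = 2, n_sa = 2, seed = 51))
  expect_length(dat$records, 4)
  ts <- segment_trials(dat$records[["fa_01"]])
  expect_equal(nrow(ts$meta), 4 * 8 * 15)
  ft <- feature_table(ts)
  agg <- aggregate(cbind(n_spikes, mean_hz) ~ speed_mm_s, ft, mean)
  agg <- agg[order(agg$speed_mm_s), ]
  # count decreases and mean rate increases with speed (0 < beta < 1)
  expect_true(all(diff(agg$n_spikes) < 0))
  expect_true(all(diff(agg$mean_hz) > 0))
})

test_that("without jitter the spatial response is speed invariant in expectation", {
  set.seed(61)
  m <- sample_neuron_model("FA-1", list(jitter_um = 0))
  smooth_mean <- function(v) {
    grid <- seq(-6000, 6000, by = 20)
    acc <- numeric(length(grid))
    for (i in 1:15) {
      t <- simulate_trial(m, 5, v)
      x <- -6000 + t * v * 1000
      for (p in x) acc <- acc + dnorm(grid, p, 100)
    }
    acc / 15
  }
  expect_gt(cor(smooth_mean(15), smooth_mean(180)), 0.9)
})

test_that("measured trial-to-trial spatial scatter grows with the jitter knob", {
  # SD of the centre of mass of spike positions across repeated trials
  set.seed(71)
  com_sd <- vapply(c(0, 40, 160), function(j) {
    m <- sample_neuron_model("FA-1", list(jitter_um = j))
    coms <- replicate(40, {
      t <- simulate_trial(m, 0, 30)
      mean(-6000 + t * 30000)
    })
    sd(coms)
  }, numeric(1))
  expect_true(all(diff(com_sd) > 0))
})
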
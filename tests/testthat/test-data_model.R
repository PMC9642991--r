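test_that("spike times map to drum positions by linear interpolation", {
  trace <- constant_speed_trace(30, 20)
  expect_equal(spikes_to_positions(0.1, trace), 3000)
  # exactly at a trace sample
  expect_equal(spikes_to_positions(trace$time_s[5], trace),
               trace$position_um[5])
  piece <- data.frame(time_s = c(0, 1), position_um = c(0, 1000))
  expect_equal(spikes_to_positions(0.25, piece), 250)
  expect_error(spikes_to_positions(1.5, piece), "outside")
  expect_length(spikes_to_positions(numeric(0), trace), 0)
})

test_that("spike-to-position mapping preserves order (monotone trace)", {
  trace <- constant_speed_trace(45, 50)
  t <- sort(runif(40, 0, max(trace$time_s)))
  p <- spikes_to_positions(t, trace)
  expect_true(all(diff(p) >= 0))
})

test_that("a saved dataset loads back field-identical", {
  dat <- generate_dataset(sim_config(n_fa = 1, n_sa = 1,
                                     speeds_mm_s = c(15, 60), seed = 3))
  path <- withr::local_tempdir()
  save_dataset(dat$records, path, truth = lapply(dat$truth, unclass))
  back <- load_dataset(path)
  expect_setequal(names(back), names(dat$records))
  for (id in names(back)) {
    expect_equal(back[[id]]$spikes, dat$records[[id]]$spikes,
                 ignore_attr = TRUE)
    expect_equal(back[[id]]$type, dat$records[[id]]$type)
    expect_equal(back[[id]]$layout$line_positions,
                 dat$records[[id]]$layout$line_positions,
                 ignore_attr = TRUE)
    expect_equal(record_speeds(back[[id]]), record_speeds(dat$records[[id]]))
  }
  expect_true(file.exists(file.path(path, "truth.json")))
})

test_that("loading an empty directory returns an empty list with a warning", {
  path <- withr::local_tempdir()
  expect_warning(out <- load_dataset(path), "no neuron directories")
  expect_identical(out, list())
})

test_that("records with non-monotone spike times fail validation", {
  layout <- stimulus_layout()
  trace <- constant_speed_trace(30, 200)
  spikes <- data.frame(speed_mm_s = 30, rotation = 1, presentation = 1,
                       orientation_deg = -10, spike_time_s = c(0.2, 0.1))
  expect_error(neuron_record("bad", "FA-1", spikes, list(`30` = trace),
                             layout),
               "non-monotone")
  # and load_dataset reports rather than silently dropping
  dat <- generate_dataset(sim_config(n_fa = 1, n_sa = 0,
                                     speeds_mm_s = 30, seed = 4))
  path <- withr::local_tempdir()
  save_dataset(dat$records, path)
  sp <- read.csv(file.path(path, "fa_01", "spikes.csv"))
  sp$spike_time_s[2] <- sp$spike_time_s[1] - 0.05
  write.csv(sp, file.path(path, "fa_01", "spikes.csv"), row.names = FALSE)
  expect_error(load_dataset(path), "fa_01")
  expect_warning(out <- load_dataset(path, strict = FALSE), "fa_01")
  expect_length(out, 0)
})

test_that("missing metadata fields raise a schema error naming the field", {
  spikes <- data.frame(speed_mm_s = 30, rotation = 1,
                       orientation_deg = -10, spike_time_s = 0.1)
  expect_error(neuron_record("x", "FA-1", spikes,
                             list(`30` = constant_speed_trace(30, 200)),
                             stimulus_layout()),
               "presentation")
})

test_that("segmentation yields the full factorial trial bookkeeping", {
  dat <- generate_dataset(sim_config(n_fa = 1, n_sa = 0,
                                     speeds_mm_s = c(15, 60), seed = 5))
  rec <- dat$records[[1]]
  ts <- segment_trials(rec)
  counts <- table(ts$meta$orientation_deg, ts$meta$speed_mm_s)
  expect_true(all(counts == 15))
  expect_equal(nrow(ts$meta), 4 * 15 * 2)
  # windowing only removes spikes
  expect_lte(sum(ts$meta$n_spikes), nrow(rec$spikes))
  # all positions inside the closed window
  pos <- unlist(lapply(ts$trials, `[[`, "positions_um"))
  expect_true(all(pos >= 0 & pos <= 8000))
  # trial_index runs 1..15 within each condition
  expect_true(all(tapply(ts$meta$trial_index,
                         interaction(ts$meta$speed_mm_s,
                                     ts$meta$orientation_deg),
                         function(x) identical(sort(x), 1:15))))
  # window duration matches 8 mm / v for constant-speed traces
  expect_equal(ts$meta$duration_s[ts$meta$speed_mm_s == 15],
               rep(8 / 15, 60), tolerance = 1e-9)
})

test_that("window boundaries are closed and empty trials are flagged", {
  layout <- stimulus_layout()
  lp <- layout$line_positions[1, ]  # orientation -10, presentation 1
  v <- 30; v_um <- v * 1000
  trace <- constant_speed_trace(v, 200)
  # too few pooled spikes for centre-of-mass -> window centred on the line
  edge_hi <- lp$position_mm * 1000 + 4000
  spikes <- data.frame(
    speed_mm_s = v, rotation = c(1, 2, 3), presentation = 1,
    orientation_deg = -10,
    spike_time_s = c(edge_hi, edge_hi + 0.001, edge_hi + 10000) / v_um)
  rec <- neuron_record("edge", "FA-1", spikes, list(`30` = trace), layout)
  ts <- segment_trials(rec)
  m <- ts$meta[ts$meta$orientation_deg == -10 & ts$meta$presentation == 1, ]
  tr <- ts$trials[ts$meta$orientation_deg == -10 & ts$meta$presentation == 1]
  # rotation 1: spike exactly on the upper boundary is included at 8000 um
  expect_equal(tr[[which(m$rotation == 1)]]$positions_um, 8000)
  # rotation 2: spike just past the boundary is excluded
  expect_length(tr[[which(m$rotation == 2)]]$positions_um, 0)
  # rotation 3: spike 10 mm away -> empty, flagged trial
  expect_length(tr[[which(m$rotation == 3)]]$positions_um, 0)
  expect_true(all(m$flagged[m$rotation %in% 2:3]))
})
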
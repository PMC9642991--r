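# Fixtures built in code: small simulated datasets and hand-constructed
# trial sets for oracle tests.

# simulated neuron, reduced speed set for cheap unit tests
tiny_trial_set <- function(seed = 5, type = "FA-1",
                           speeds = c(15, 60), hyper = list()) {
  cfg <- sim_config(n_fa = as.integer(type == "FA-1"),
                    n_sa = as.integer(type == "SA-1"),
                    speeds_mm_s = speeds, seed = seed,
                    hyper_fa = hyper, hyper_sa = hyper)
  dat <- generate_dataset(cfg)
  segment_trials(dat$records[[1]])
}

# hand-constructed trial_set: one trial per row of `spec`, a data frame with
# speed_mm_s, orientation_deg, rotation, presentation and a list column
# `times_s`; positions follow from the constant speed label
manual_trial_set <- function(spec, window_um = 8000, id = "manual",
                             type = "FA-1") {
  meta <- spec[, c("speed_mm_s", "orientation_deg", "rotation",
                   "presentation")]
  meta$duration_s <- window_um / (meta$speed_mm_s * 1000)
  trials <- lapply(seq_len(nrow(spec)), function(i) {
    t <- spec$times_s[[i]]
    list(times_s = t, positions_um = t * spec$speed_mm_s[i] * 1000)
  })
  meta$n_spikes <- vapply(trials, function(tr) length(tr$times_s), integer(1))
  meta$flagged <- meta$n_spikes < 2
  meta$trial_index <- stats::ave(seq_len(nrow(meta)),
                                 meta$speed_mm_s, meta$orientation_deg,
                                 FUN = seq_along)
  structure(list(neuron_id = id, type = type, window_um = window_um,
                 meta = meta, trials = trials),
            class = "trial_set")
}

# trial set in which every trial has two spikes chosen so that its peak
# firing rate equals a prescribed value; `value_fun(orientation, speed,
# trial_index)` -> peak rate in Hz
intensity_trial_set <- function(value_fun, speeds = c(15, 30, 60),
                                orientations = c(-10, -5, 5, 10),
                                n_trials = 15) {
  rows <- expand.grid(trial = seq_len(n_trials), orientation_deg = orientations,
                      speed_mm_s = speeds)
  rows$rotation <- (rows$trial - 1) %/% 5 + 1
  rows$presentation <- (rows$trial - 1) %% 5 + 1
  rows$times_s <- lapply(seq_len(nrow(rows)), function(i) {
    pk <- value_fun(rows$orientation_deg[i], rows$speed_mm_s[i], rows$trial[i])
    c(0.001, 0.001 + 1 / pk)
  })
  manual_trial_set(rows)
}

# trial set with orientation-specific spike-position templates (plus
# per-trial positional noise, um) for profile/kernel classification tests
template_trial_set <- function(noise_um = 1, speeds = c(15, 30, 60),
                               n_trials = 15, seed = 1) {
  set.seed(seed)
  templates <- list(
    `-10` = c(1500, 2200, 2600, 5100),
    `-5`  = c(1800, 3500, 3900, 6200),
    `5`   = c(2500, 4400, 4800, 7000),
    `10`  = c(3000, 3400, 5600, 6600)
  )
  rows <- expand.grid(trial = seq_len(n_trials),
                      orientation_deg = c(-10, -5, 5, 10),
                      speed_mm_s = speeds)
  rows$rotation <- (rows$trial - 1) %/% 5 + 1
  rows$presentation <- (rows$trial - 1) %% 5 + 1
  rows$times_s <- lapply(seq_len(nrow(rows)), function(i) {
    pos <- templates[[as.character(rows$orientation_deg[i])]]
    pos <- sort(pos + rnorm(length(pos), 0, noise_um))
    pos / (rows$speed_mm_s[i] * 1000)
  })
  manual_trial_set(rows)
}
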
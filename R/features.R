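#' Peak firing rate of a trial
#'
#' Reciprocal of the shortest inter-spike interval in the response window.
#' Trials with fewer than two spikes return 0 Hz (and are flagged in the
#' trial metadata) so that downstream classifiers stay total.
#'
#' @param trial A trial element of a `trial_set` (list with `times_s`).
#' @return Peak rate (Hz).
#' @export
peak_rate <- function(trial) {
  t <- trial$times_s
  if (length(t) < 2) return(0)
  1 / min(diff(t))
}

#' Mean firing rate of a trial
#'
#' Spike count in the 8 mm response window divided by the time the stimulus
#' took to traverse the window, measured from the drum trace (not assumed
#' from the speed label).
#'
#' @param trial A trial element (list with `times_s`).
#' @param duration_s Traversal duration of the window (s), from the trace.
#' @return Mean rate (Hz).
#' @export
mean_rate <- function(trial, duration_s) {
  if (duration_s <= 0) stop("window duration must be positive")
  length(trial$times_s) / duration_s
}

#' Instantaneous firing-rate profile of a trial
#'
#' The profile is the reciprocal of each inter-spike interval held constant
#' over that interval (left-closed, right-open), zero before the first and
#' after the last spike, sampled on a uniform grid over the whole response
#' window. In the spatial domain intervals are measured in um and converted
#' to Hz via the trial's traversal speed, so that for a constant-speed trace
#' the spatial profile is an exact reparametrisation of the temporal one.
#'
#' @param trial A trial element (lists `times_s`, `positions_um`).
#' @param domain `"temporal"` or `"spatial"`.
#' @param grid_step Grid step: seconds (default 0.001) or um (default 10).
#' @param duration_s Window traversal duration (s); required for both
#'   domains (grid extent in temporal, Hz conversion in spatial).
#' @param window_um Window length (um), default 8000.
#' @param grid_length Optional number of samples (overrides the extent
#'   implied by `duration_s`; used to put trials of one speed on a shared
#'   grid).
#' @return Numeric vector of rate samples (Hz) with attributes `domain` and
#'   `grid_step`.
#' @export
rate_profile <- function(trial, domain = c("temporal", "spatial"),
                         grid_step = NULL, duration_s, window_um = 8000,
                         grid_length = NULL) {
  domain <- match.arg(domain)
  if (is.null(grid_step)) grid_step <- if (domain == "temporal") 0.001 else 10
  stopifnot(grid_step > 0)
  if (domain == "temporal") {
    knots <- trial$times_s
    extent <- duration_s
    rate <- if (length(knots) >= 2) 1 / diff(knots) else numeric(0)
  } else {
    knots <- trial$positions_um
    extent <- window_um
    v_um_s <- window_um / duration_s
    rate <- if (length(knots) >= 2) v_um_s / diff(knots) else numeric(0)
  }
  n <- if (is.null(grid_length)) floor(extent / grid_step) + 1L else grid_length
  grid <- (seq_len(n) - 1L) * grid_step
  vals <- numeric(n)
  if (length(rate)) {
    idx <- findInterval(grid, knots, left.open = FALSE)
    inside <- idx >= 1 & idx <= length(rate) & grid < knots[length(knots)]
    vals[inside] <- rate[idx[inside]]
  }
  structure(vals, domain = domain, grid_step = grid_step)
}

#' Feature table for a segmented neuron
#'
#' One row per trial with the intensity measures and bookkeeping columns.
#'
#' @param ts A `trial_set` from [segment_trials()].
#' @return Data frame: neuron_id, type, speed_mm_s, orientation_deg,
#'   rotation, presentation, trial_index, duration_s, n_spikes, flagged,
#'   peak_hz, mean_hz.
#' @export
feature_table <- function(ts) {
  m <- ts$meta
  m$peak_hz <- vapply(ts$trials, peak_rate, numeric(1))
  m$mean_hz <- vapply(seq_along(ts$trials), function(i) {
    mean_rate(ts$trials[[i]], m$duration_s[i])
  }, numeric(1))
  cbind(neuron_id = ts$neuron_id, type = ts$type, m)
}

#' Matrix of rate profiles for a set of trials
#'
#' Stacks the rate profiles of the selected trials as columns of a matrix on
#' a shared grid. Spatial-domain profiles share the window grid across all
#' speeds; temporal-domain profiles share a grid within each speed (the
#' extent is the longest trial duration among the selected trials).
#'
#' @param ts A `trial_set`.
#' @param domain `"temporal"` or `"spatial"`.
#' @param grid_step Grid step (s or um); defaults as in [rate_profile()].
#' @param which Integer indices of trials to include (default all).
#' @return Matrix (grid points x trials), with `ts$meta[which, ]` attached
#'   as attribute `meta`.
#' @export
profile_matrix <- function(ts, domain = c("temporal", "spatial"),
                           grid_step = NULL, which = NULL) {
  domain <- match.arg(domain)
  if (is.null(grid_step)) grid_step <- if (domain == "temporal") 0.001 else 10
  if (is.null(which)) which <- seq_along(ts$trials)
  extent <- if (domain == "temporal") max(ts$meta$duration_s[which]) else
    ts$window_um
  n <- floor(extent / grid_step) + 1L
  M <- vapply(which, function(i) {
    rate_profile(ts$trials[[i]], domain, grid_step,
                 duration_s = ts$meta$duration_s[i],
                 window_um = ts$window_um, grid_length = n)
  }, numeric(n))
  attr(M, "meta") <- ts$meta[which, , drop = FALSE]
  attr(M, "grid_step") <- grid_step
  M
}
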
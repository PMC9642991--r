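#' Default generative hyperparameters for an afferent type
#'
#' FA-1 afferents innervate roughly twice as many mechanoreceptive end
#' organs (subfields) as SA-1 afferents and respond with higher rates; both
#' have receptive fields a few millimetres across. Subfield counts are drawn
#' uniformly from type-specific ranges (SA-1: 5-12, FA-1: 10-24, so the
#' FA-1 mean is twice the SA-1 mean). The velocity exponent beta controls
#' how firing rate grows with scanning speed; with 0 < beta < 1 the spike
#' count per passage falls with speed while the rate rises, as observed.
#'
#' @param type `"FA-1"` or `"SA-1"`.
#' @return Named list of hyperparameter ranges and constants:
#'   `n_subfields` (integer range), `ellipse_um` (semi-axes, scan direction
#'   first), `sigma_sub_um` (subfield SD range), `amplitude` (per-subfield
#'   gain range), `gain_hz` (global gain range, Hz per unit drive),
#'   `background_hz`, `refractory_s`, `beta`, `v0_mm_s` (reference speed),
#'   `jitter_um` (trial-to-trial spatial jitter SD).
#' @export
default_hyperparams <- function(type = c("FA-1", "SA-1")) {
  type <- match.arg(type)
  common <- list(
    ellipse_um = c(1500, 1000),
    sigma_sub_um = c(15, 30),
    amplitude = c(0.7, 1),
    background_hz = 0.5,
    refractory_s = 0.001,
    v0_mm_s = 30,
    jitter_um = 30
  )
  if (type == "FA-1") {
    c(list(n_subfields = c(10, 24), gain_hz = c(1200, 2000), beta = 0.6), common)
  } else {
    c(list(n_subfields = c(5, 12), gain_hz = c(1100, 1800), beta = 0.2), common)
  }
}

#' Draw a subfield receptive-field model
#'
#' Samples one afferent model: subfield centres uniformly inside an ellipse
#' (major axis along the scanning direction), per-subfield amplitudes and
#' Gaussian SDs, a global gain, and the rate/jitter parameters. Uses the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param type `"FA-1"` or `"SA-1"`.
#' @param hyper Hyperparameter list as from [default_hyperparams()];
#'   elements override the type default.
#' @return An object of class `subfield_model`.
#' @export
sample_neuron_model <- function(type = c("FA-1", "SA-1"), hyper = list()) {
  type <- match.arg(type)
  hp <- utils::modifyList(default_hyperparams(type), hyper)
  if (any(hp$ellipse_um <= 0)) stop("degenerate receptive-field ellipse")
  n <- if (length(hp$n_subfields) > 1) {
    sample(seq(hp$n_subfields[1], hp$n_subfields[2]), 1)
  } else hp$n_subfields
  # rejection-sample centres uniformly inside the ellipse
  centers <- matrix(NA_real_, 0, 2)
  while (nrow(centers) < n) {
    cand <- cbind(runif(2 * n, -hp$ellipse_um[1], hp$ellipse_um[1]),
                  runif(2 * n, -hp$ellipse_um[2], hp$ellipse_um[2]))
    keep <- (cand[, 1] / hp$ellipse_um[1])^2 +
      (cand[, 2] / hp$ellipse_um[2])^2 <= 1
    centers <- rbind(centers, cand[keep, , drop = FALSE])
  }
  centers <- centers[seq_len(n), , drop = FALSE]
  draw <- function(rng) if (length(rng) > 1) runif(n, rng[1], rng[2]) else rep(rng, n)
  draw1 <- function(rng) if (length(rng) > 1) runif(1, rng[1], rng[2]) else rng
  structure(
    list(type = type,
         centers_um = centers,
         amplitude = draw(hp$amplitude),
         sigma_sub_um = draw(hp$sigma_sub_um),
         gain_hz = draw1(hp$gain_hz),
         background_hz = hp$background_hz,
         refractory_s = hp$refractory_s,
         beta = hp$beta,
         v0_mm_s = hp$v0_mm_s,
         jitter_um = hp$jitter_um),
    class = "subfield_model"
  )
}

#' Drive of an oriented edge on a subfield model
#'
#' The edge is modelled as an infinite zero-width line at orientation
#' `theta_deg` from the axis perpendicular to the scanning direction, whose
#' intercept with the scan axis is at `x_um` (in receptive-field-centred
#' coordinates). The drive is the sum over subfields of Gaussians in the
#' perpendicular distance from each subfield centre to the line.
#'
#' @param model A `subfield_model`.
#' @param theta_deg Edge orientation (degrees).
#' @param x_um Scan-axis intercept(s) of the edge (um); vectorised.
#' @return Dimensionless drive, same length as `x_um`.
#' @export
edge_drive <- function(model, theta_deg, x_um) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  out <- numeric(length(x_um))
  for (i in seq_len(nrow(model$centers_um))) {
    d <- (model$centers_um[i, 1] - x_um) * ct - model$centers_um[i, 2] * st
    out <- out + model$amplitude[i] * exp(-d^2 / (2 * model$sigma_sub_um[i]^2))
  }
  out
}

#' Simulate one edge passage
#'
#' Inhomogeneous Poisson spiking with rate
#' `g * (v/v0)^beta * drive(theta, v*t + delta) + background`, where the
#' per-trial spatial offset `delta ~ N(0, jitter^2)` models trial-to-trial
#' spatial jitter, followed by absolute-refractory thinning. The process is
#' sampled exactly by superposition: the drive is a sum of Gaussians in the
#' edge intercept, so each subfield contributes a Poisson number of spikes
#' with Gaussian-distributed intercepts, plus uniform background spikes.
#' With 0 < beta < 1 the expected spike count scales as `(v/v0)^(beta-1)`
#' (decreasing in v) while rates increase with v.
#'
#' @param model A `subfield_model`.
#' @param theta_deg Edge orientation (degrees).
#' @param v_mm_s Scanning speed (mm/s).
#' @param span_um Half-width of the simulated passage around the line's
#'   crossing of the receptive-field centre (um).
#' @return Spike times (s) relative to the start of the passage (edge
#'   intercept at `-span_um`), strictly increasing.
#' @export
simulate_trial <- function(model, theta_deg, v_mm_s, span_um = 6000) {
  stopifnot(v_mm_s > 0)
  v_um <- v_mm_s * 1000
  t_end <- 2 * span_um / v_um
  speed_gain <- model$gain_hz * (v_mm_s / model$v0_mm_s)^model$beta
  delta <- rnorm(1, 0, model$jitter_um)
  th <- theta_deg * pi / 180
  # component i of the drive is a Gaussian in the intercept x, centred at
  # the intercept whose line passes through the subfield centre, with SD
  # sigma_i / cos(theta)
  x_star <- model$centers_um[, 1] - model$centers_um[, 2] * tan(th)
  sd_x <- model$sigma_sub_um / cos(th)
  mass <- speed_gain * model$amplitude * sd_x * sqrt(2 * pi) / v_um
  x_sp <- numeric(0)
  for (i in seq_along(mass)) {
    n_i <- rpois(1, mass[i])
    if (n_i > 0) x_sp <- c(x_sp, rnorm(n_i, x_star[i], sd_x[i]))
  }
  t_sp <- (x_sp + span_um - delta) / v_um
  n_bg <- rpois(1, model$background_hz * t_end)
  if (n_bg > 0) t_sp <- c(t_sp, runif(n_bg, 0, t_end))
  t_sp <- sort(t_sp[t_sp >= 0 & t_sp <= t_end])
  if (length(t_sp) > 1 && model$refractory_s > 0) {
    out <- t_sp[1]
    for (t in t_sp[-1]) {
      if (t - out[length(out)] >= model$refractory_s) out <- c(out, t)
    }
    t_sp <- out
  }
  t_sp
}

#' Simulation configuration
#'
#' @param n_fa,n_sa Numbers of FA-1 and SA-1 model neurons.
#' @param speeds_mm_s Scanning speeds (mm/s).
#' @param seed RNG seed; recorded in the output.
#' @param hyper_fa,hyper_sa Hyperparameter overrides per type (see
#'   [default_hyperparams()]).
#' @param layout A `stimulus_layout`; its repetitions and rotations set the
#'   trials per condition (5 x 3 = 15 in the full design).
#' @param trace_hz Sampling rate of the synthetic drum traces (Hz).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_fa = 2, n_sa = 2,
                       speeds_mm_s = c(15, 20, 30, 45, 60, 90, 120, 180),
                       seed = 1,
                       hyper_fa = list(), hyper_sa = list(),
                       layout = stimulus_layout(),
                       trace_hz = 200) {
  stopifnot(all(speeds_mm_s > 0),
            layout$repetitions_per_rotation * layout$rotations >= 2)
  structure(list(n_fa = n_fa, n_sa = n_sa, speeds_mm_s = speeds_mm_s,
                 seed = seed, hyper_fa = hyper_fa, hyper_sa = hyper_sa,
                 layout = layout, trace_hz = trace_hz),
            class = "sim_config")
}

#' Generate a synthetic dataset
#'
#' Produces the full factorial design (orientations x speeds x trials, with
#' trials = presentations per rotation x rotations) for every model neuron,
#' fully reproducible from the seed. The spatial structure of each neuron's
#' response is fixed by its subfield layout, so spatial-domain responses are
#' approximately speed invariant up to the configured jitter.
#'
#' @param cfg A `sim_config`.
#' @return List with `records` (list of [neuron_record()]s), `truth` (the
#'   ground-truth `subfield_model`s, keyed by neuron id) and `config`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  layout <- cfg$layout
  lp <- layout$line_positions
  circumference_mm <- pi * layout$drum_diameter_mm
  trace_len_mm <- max(circumference_mm, max(lp$position_mm) + 8)

  types <- c(rep("FA-1", cfg$n_fa), rep("SA-1", cfg$n_sa))
  ids <- sprintf("%s_%02d", ifelse(types == "FA-1", "fa", "sa"),
                 c(seq_len(cfg$n_fa), seq_len(cfg$n_sa)))
  records <- list(); truth <- list()
  for (j in seq_along(types)) {
    type <- types[j]
    hyper <- if (type == "FA-1") cfg$hyper_fa else cfg$hyper_sa
    model <- sample_neuron_model(type, hyper)
    spikes <- list(); k <- 0L
    for (v in cfg$speeds_mm_s) {
      v_um <- v * 1000
      for (rot in seq_len(layout$rotations)) {
        for (i in seq_len(nrow(lp))) {
          t_sp <- simulate_trial(model, lp$orientation_deg[i], v)
          k <- k + 1L
          if (length(t_sp)) {
            t_enter <- (lp$position_mm[i] * 1000 - 6000) / v_um
            spikes[[k]] <- data.frame(
              speed_mm_s = v, rotation = rot,
              presentation = lp$presentation[i],
              orientation_deg = lp$orientation_deg[i],
              spike_time_s = t_enter + t_sp
            )
          }
        }
      }
    }
    spikes <- if (length(spikes)) do.call(rbind, spikes) else
      data.frame(speed_mm_s = numeric(0), rotation = integer(0),
                 presentation = integer(0), orientation_deg = numeric(0),
                 spike_time_s = numeric(0))
    traces <- lapply(cfg$speeds_mm_s, function(v) {
      constant_speed_trace(v, trace_len_mm, cfg$trace_hz)
    })
    names(traces) <- cfg$speeds_mm_s
    records[[ids[j]]] <- neuron_record(ids[j], type, spikes, traces, layout)
    truth[[ids[j]]] <- model
  }
  list(records = records, truth = truth, config = cfg)
}
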
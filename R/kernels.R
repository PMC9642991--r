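#' Default Gaussian kernel sweep
#'
#' Doubling grid of kernel SDs from 5 to 1280 um.
#' @return Numeric vector of kernel SDs (um).
#' @export
default_sigmas <- function() 5 * 2^(0:8)

# grid step for smoothing at kernel SD sigma: sigma/2 resolution guard,
# capped at 10 um (and never below 2 um)
.smooth_step <- function(sigma_um) max(2, min(10, min(sigma_um) / 2))

#' Convolve a spike train with a Gaussian kernel
#'
#' Each spike contributes a unit-mass Gaussian density (1/um) centred at
#' its spatial position, evaluated on a uniform grid over the response
#' window; mass is conserved to within edge truncation.
#'
#' @param positions_um Spike positions (um) within the window.
#' @param sigma_um Kernel SD (um).
#' @param grid_step Grid step (um); must be <= `sigma_um / 2`.
#' @param window_um Window length (um).
#' @return Numeric vector of density samples (1/um) on
#'   `seq(0, window_um, by = grid_step)`.
#' @export
convolve_spike_train <- function(positions_um, sigma_um,
                                 grid_step = .smooth_step(sigma_um),
                                 window_um = 8000) {
  stopifnot(sigma_um > 0)
  if (grid_step > sigma_um / 2 + 1e-9) {
    stop("grid step ", grid_step, " um exceeds sigma/2 = ", sigma_um / 2,
         " um; refine the grid")
  }
  grid <- seq(0, window_um, by = grid_step)
  vals <- numeric(length(grid))
  for (p in positions_um) vals <- vals + dnorm(grid, p, sigma_um)
  vals
}

#' Matrix of smoothed spike trains
#'
#' @param ts A `trial_set`.
#' @param sigma_um Kernel SD (um).
#' @param grid_step Grid step (um); default `min(10, sigma/2)` (floor 2 um).
#' @param which Integer indices of trials (default all).
#' @return Matrix (grid points x trials) with `meta` attribute.
#' @export
smoothed_matrix <- function(ts, sigma_um, grid_step = NULL, which = NULL) {
  if (is.null(grid_step)) grid_step <- .smooth_step(sigma_um)
  if (is.null(which)) which <- seq_along(ts$trials)
  n <- length(seq(0, ts$window_um, by = grid_step))
  M <- vapply(which, function(i) {
    convolve_spike_train(ts$trials[[i]]$positions_um, sigma_um, grid_step,
                         ts$window_um)
  }, numeric(n))
  attr(M, "meta") <- ts$meta[which, , drop = FALSE]
  M
}

#' Same- vs different-orientation correlation across kernel widths
#'
#' For each kernel SD and core speed, all smoothed spike trains of the
#' neuron are pairwise correlated; the mean squared Pearson correlation
#' (R^2) is computed over the cross-speed trial pairs with the same
#' orientation and over those with different orientations (within-speed
#' pairs are excluded), with equal weight per trial pair. The difference
#' between the two means, as a function of kernel SD, is the inverted-U
#' curve whose peak estimates the spatial precision of spiking.
#'
#' @param ts A `trial_set`.
#' @param sigmas_um Kernel SDs to sweep (um).
#' @param squared Use squared correlations (R^2, default); otherwise plain r.
#' @return Data frame: neuron_id, type, core_speed, sigma_um, r2_same,
#'   r2_diff, diff.
#' @export
correlation_curves <- function(ts, sigmas_um = default_sigmas(),
                               squared = TRUE) {
  meta <- ts$meta
  speeds <- sort(unique(meta$speed_mm_s))
  if (length(speeds) < 2) stop("kernel curves need trials at >= 2 speeds")
  out <- list()
  for (sigma in sigmas_um) {
    R <- .safe_cor(smoothed_matrix(ts, sigma))
    if (squared) R <- R^2
    for (v in speeds) {
      core <- meta$speed_mm_s == v
      other <- !core
      same_o <- outer(meta$orientation_deg[core], meta$orientation_deg[other],
                      "==")
      block <- R[core, other, drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        neuron_id = ts$neuron_id, type = ts$type, core_speed = v,
        sigma_um = sigma,
        r2_same = mean(block[same_o]),
        r2_diff = mean(block[!same_o]),
        diff = mean(block[same_o]) - mean(block[!same_o])
      )
    }
  }
  do.call(rbind, out)
}

#' Best kernel (spatial precision) per speed and neuron
#'
#' The best kernel at a core speed is the kernel SD maximising the
#' same-minus-different correlation difference (grid argmax; exact ties go
#' to the smaller SD). Each neuron is summarised by the mean best kernel
#' across speeds. Neurons whose difference curve is entirely flat (e.g. no
#' spikes) are flagged and excluded from the summary value.
#'
#' @param curves Data frame from [correlation_curves()] (one or more
#'   neurons).
#' @param interpolate If `TRUE`, refine interior peaks by a log-parabolic
#'   interpolation through the peak and its two neighbours.
#' @return List with `per_speed` (neuron_id, type, core_speed,
#'   best_sigma_um) and `per_neuron` (neuron_id, type, mean_best_sigma_um,
#'   flagged).
#' @export
best_kernel <- function(curves, interpolate = FALSE) {
  per_speed <- do.call(rbind, lapply(
    split(curves, list(curves$neuron_id, curves$core_speed), drop = TRUE),
    function(df) {
      df <- df[order(df$sigma_um), ]
      if (all(df$diff == df$diff[1])) {
        best <- NA_real_
      } else {
        k <- which.max(df$diff)
        best <- df$sigma_um[k]
        if (interpolate && k > 1 && k < nrow(df)) {
          lx <- log(df$sigma_um[(k - 1):(k + 1)])
          y <- df$diff[(k - 1):(k + 1)]
          denom <- (lx[1] - lx[2]) * (lx[1] - lx[3]) * (lx[2] - lx[3])
          a <- (lx[3] * (y[2] - y[1]) + lx[2] * (y[1] - y[3]) +
                  lx[1] * (y[3] - y[2])) / denom
          b <- (lx[3]^2 * (y[1] - y[2]) + lx[2]^2 * (y[3] - y[1]) +
                  lx[1]^2 * (y[2] - y[3])) / denom
          if (a < 0) best <- exp(-b / (2 * a))
        }
      }
      data.frame(neuron_id = df$neuron_id[1], type = df$type[1],
                 core_speed = df$core_speed[1], best_sigma_um = best)
    }))
  per_neuron <- do.call(rbind, lapply(
    split(per_speed, per_speed$neuron_id), function(df) {
      data.frame(neuron_id = df$neuron_id[1], type = df$type[1],
                 mean_best_sigma_um = mean(df$best_sigma_um, na.rm = TRUE),
                 flagged = anyNA(df$best_sigma_um))
    }))
  rownames(per_speed) <- rownames(per_neuron) <- NULL
  list(per_speed = per_speed, per_neuron = per_neuron)
}

#' Across-speed classification from convolved spike trains
#'
#' Identical decision rule to [profile_classify_across()] but on spike
#' trains smoothed with a fixed (per neuron type) Gaussian kernel, and
#' optionally restricted to a subset of speeds (e.g. the 15-45 mm/s range
#' people use when discriminating fine spatial detail).
#'
#' @param ts A `trial_set`.
#' @param sigma_um Kernel SD (um) for this neuron's type.
#' @param speed_set Speeds to include (default all in `ts`).
#' @param grid_step Smoothing grid step (um).
#' @return Data frame, one row per core speed in `speed_set`, chance 1/4.
#' @export
classify_convolved <- function(ts, sigma_um, speed_set = NULL,
                               grid_step = NULL) {
  speeds <- sort(unique(ts$meta$speed_mm_s))
  if (is.null(speed_set)) speed_set <- speeds
  if (!all(speed_set %in% speeds)) stop("speed_set outside available speeds")
  if (length(speed_set) < 2) stop("across-speed classification needs >= 2 speeds")
  keep <- which(ts$meta$speed_mm_s %in% speed_set)
  M <- smoothed_matrix(ts, sigma_um, grid_step, which = keep)
  R <- .safe_cor(M)
  meta <- ts$meta[keep, ]
  orients <- sort(unique(meta$orientation_deg))
  out <- list()
  for (v in speed_set) {
    core <- which(meta$speed_mm_s == v)
    own <- meta$orientation_deg[core]
    correct <- logical(0)
    for (v2 in setdiff(speed_set, v)) {
      ref <- which(meta$speed_mm_s == v2)
      sc <- .across_scores(meta[ref, ], orients,
                           R_block = R[core, ref, drop = FALSE])
      correct <- c(correct, .decide(sc$scores, orients, own))
    }
    out[[length(out) + 1]] <- .result_row(ts, "convolved", "across", v,
                                          1 / length(orients), correct)
  }
  do.call(rbind, out)
}

#' Equivalent sinusoidal period of a Gaussian spatial kernel
#'
#' A Gaussian bump of SD sigma closely resembles one cycle of a raised
#' cosine. The equivalent period P minimises the integrated squared
#' difference between `exp(-x^2/(2 sigma^2))` and `(1 + cos(2 pi x/P))/2`
#' over one period `x in [-P/2, P/2]`. By scale invariance P is exactly
#' linear in sigma; the proportionality constant is determined once by 1-D
#' numerical minimisation and cached.
#'
#' @param sigma_um Gaussian SD (um); vectorised, must be positive.
#' @return Equivalent sinusoidal period (um).
#' @export
gaussian_to_period <- function(sigma_um) {
  if (any(sigma_um <= 0)) stop("sigma must be positive")
  c0 <- .edgecode_cache$period_constant
  if (is.null(c0)) {
    obj <- function(P) {
      integrate(function(x) {
        (exp(-x^2 / 2) - (1 + cos(2 * pi * x / P)) / 2)^2
      }, -P / 2, P / 2, rel.tol = 1e-12)$value
    }
    c0 <- optimize(obj, c(2, 10), tol = 1e-10)$minimum
    .edgecode_cache$period_constant <- c0
  }
  c0 * sigma_um
}
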
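# Pearson correlation with zero-variance columns defined as r = 0 with
# everything (keeps the decision rule total; together with the strict-argmax
# tie rule, empty trials are always classified incorrect).
.safe_cor <- function(A, B = NULL) {
  if (is.null(B)) B <- A
  sa <- apply(A, 2, sd) > 0
  sb <- apply(B, 2, sd) > 0
  R <- matrix(0, ncol(A), ncol(B))
  if (any(sa) && any(sb)) {
    R[sa, sb] <- cor(A[, sa, drop = FALSE], B[, sb, drop = FALSE])
  }
  R
}

# Hold-out scores for one speed condition. For held-out trial i the
# same-orientation reference is its other n-1 trials; each other
# orientation's reference drops the trial sharing i's trial_index, so every
# reference has the same size and i never enters any reference.
# R: trial x trial correlation matrix (corr schemes) or NULL; x: intensity
# values (dist schemes). Higher score = better match.
.within_scores <- function(meta, orients, R = NULL, x = NULL) {
  n <- nrow(meta)
  scores <- matrix(NA_real_, n, length(orients))
  audit <- vector("list", n)
  for (i in seq_len(n)) {
    refs <- vector("list", length(orients))
    for (jo in seq_along(orients)) {
      pool <- which(meta$orientation_deg == orients[jo])
      ref <- if (orients[jo] == meta$orientation_deg[i]) {
        setdiff(pool, i)
      } else {
        pool[meta$trial_index[pool] != meta$trial_index[i]]
      }
      refs[[jo]] <- ref
      scores[i, jo] <- if (!is.null(R)) mean(R[i, ref]) else
        -abs(x[i] - mean(x[ref]))
    }
    audit[[i]] <- refs
  }
  list(scores = scores, audit = audit)
}

# Across-speed scores: trial i at the core speed scored against the full
# per-orientation reference sets at another speed (the held-out trial is at
# a different speed, so it cannot enter any reference).
.across_scores <- function(meta_ref, orients, R_block = NULL,
                           x_core = NULL, x_ref = NULL) {
  n <- if (!is.null(R_block)) nrow(R_block) else length(x_core)
  scores <- matrix(NA_real_, n, length(orients))
  refs <- lapply(orients, function(o) which(meta_ref$orientation_deg == o))
  for (jo in seq_along(orients)) {
    ref <- refs[[jo]]
    scores[, jo] <- if (!is.null(R_block)) rowMeans(R_block[, ref, drop = FALSE])
      else -abs(x_core - mean(x_ref[ref]))
  }
  list(scores = scores, audit = refs)
}

# strict argmax decision: correct only if the own-orientation score strictly
# exceeds every other score (any tie counts as incorrect)
.decide <- function(scores, orients, own) {
  own_col <- match(own, orients)
  vapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    s[own_col[i]] > max(s[-own_col[i]])
  }, logical(1))
}

# fractional assignment over orientations (ties split uniformly); used for
# confusion matrices
.assign_mass <- function(scores, orients) {
  mass <- matrix(0, nrow(scores), length(orients))
  for (i in seq_len(nrow(scores))) {
    top <- which(scores[i, ] == max(scores[i, ]))
    mass[i, top] <- 1 / length(top)
  }
  colnames(mass) <- orients
  mass
}

.result_row <- function(ts, scheme, scope, core_speed, chance, correct) {
  data.frame(neuron_id = ts$neuron_id, type = ts$type, scheme = scheme,
             scope = scope, core_speed = core_speed, chance = chance,
             accuracy = mean(correct), n_decisions = length(correct))
}

.intensity_values <- function(ts, measure, features = NULL) {
  if (is.null(features)) features <- feature_table(ts)
  if (measure == "peak") features$peak_hz else features$mean_hz
}

#' Within-speed ideal-observer classification from response intensity
#'
#' For each trial at speed `v`, its peak or mean firing rate is compared
#' with the average of the remaining trials of the same orientation and
#' with equally sized (n-1 trial) averages of each other orientation; the
#' trial is correctly classified when the same-orientation average is
#' strictly closest. Chance is 1/4 with the full stimulus set.
#'
#' @param ts A `trial_set`.
#' @param v Speed condition (mm/s).
#' @param measure `"peak"` or `"mean"`.
#' @param audit If `TRUE`, attach per-decision reference trial indices as
#'   attribute `audit` (list: per decision, per orientation, row indices of
#'   `ts$meta` used as reference).
#' @return One-row data frame (neuron_id, type, scheme, scope, core_speed,
#'   chance, accuracy, n_decisions).
#' @export
intensity_classify_within <- function(ts, v, measure = c("peak", "mean"),
                                      audit = FALSE) {
  measure <- match.arg(measure)
  idx <- which(ts$meta$speed_mm_s == v)
  if (!length(idx)) stop("no trials at speed ", v, " mm/s")
  meta <- ts$meta[idx, ]
  orients <- sort(unique(ts$meta$orientation_deg))
  x <- .intensity_values(ts, measure)[idx]
  sc <- .within_scores(meta, orients, x = x)
  correct <- .decide(sc$scores, orients, meta$orientation_deg)
  out <- .result_row(ts, paste0("intensity-", measure), "within", v,
                     1 / length(orients), correct)
  if (audit) attr(out, "audit") <- lapply(sc$audit, lapply, function(r) idx[r])
  out
}

#' Within-speed ideal-observer classification from firing-rate profiles
#'
#' All profiles at speed `v` are pairwise correlated (zero-lag Pearson on
#' registered common-grid profiles); each trial is assigned the orientation
#' with the highest mean correlation over an (n-1)-trial reference set,
#' with the held-out trial excluded from every reference.
#'
#' @inheritParams intensity_classify_within
#' @param domain `"temporal"` or `"spatial"`.
#' @param grid_step Profile grid step (s or um).
#' @return One-row classification data frame, as
#'   [intensity_classify_within()].
#' @export
profile_classify_within <- function(ts, v, domain = c("temporal", "spatial"),
                                    grid_step = NULL, audit = FALSE) {
  domain <- match.arg(domain)
  idx <- which(ts$meta$speed_mm_s == v)
  if (!length(idx)) stop("no trials at speed ", v, " mm/s")
  meta <- ts$meta[idx, ]
  orients <- sort(unique(ts$meta$orientation_deg))
  M <- profile_matrix(ts, domain, grid_step, which = idx)
  R <- .safe_cor(M)
  sc <- .within_scores(meta, orients, R = R)
  correct <- .decide(sc$scores, orients, meta$orientation_deg)
  out <- .result_row(ts, paste0("profile-", substr(domain, 1, 1)), "within",
                     v, 1 / length(orients), correct)
  if (audit) attr(out, "audit") <- lapply(sc$audit, lapply, function(r) idx[r])
  out
}

#' Population speed-intensity relationship
#'
#' Ordinary least-squares fit of the per-speed population mean intensity on
#' scanning speed, per neuron type. Used to normalise intensities before
#' across-speed classification (testing whether knowledge of the population
#' speed-intensity relationship rescues intensity-based invariance).
#'
#' @param features Feature table rows (possibly several neurons), as from
#'   [feature_table()].
#' @param measure `"peak"` or `"mean"`.
#' @return Object of class `speed_intensity_fit`: per type, `slope` (Hz per
#'   mm/s) and `intercept` (Hz). Use [predict_intensity()] to evaluate.
#' @export
fit_population_speed_function <- function(features, measure = c("peak", "mean")) {
  measure <- match.arg(measure)
  col <- if (measure == "peak") "peak_hz" else "mean_hz"
  fits <- lapply(split(features, features$type), function(df) {
    # balance neurons: per-neuron mean at each speed, then across neurons
    per_nv <- aggregate(df[[col]],
                        list(neuron = df$neuron_id, speed = df$speed_mm_s),
                        mean)
    pop <- aggregate(per_nv$x, list(speed = per_nv$speed), mean)
    if (nrow(pop) < 2) stop("need >= 2 speeds to fit the speed-intensity line")
    fit <- lm(x ~ speed, data = pop)
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  })
  structure(list(measure = measure, fits = fits),
            class = "speed_intensity_fit")
}

#' @rdname fit_population_speed_function
#' @param object A `speed_intensity_fit`.
#' @param type Neuron type of the neuron being normalised.
#' @param v Speed(s) (mm/s).
#' @return Fitted population intensity (Hz) at `v`.
#' @export
predict_intensity <- function(object, type, v) {
  f <- object$fits[[type]]
  if (is.null(f)) stop("no speed-intensity fit for type ", type)
  f$intercept + f$slope * v
}

#' Across-speed ideal-observer classification from response intensity
#'
#' Each trial at the core speed is compared against the per-orientation mean
#' intensities at every other speed; one decision per (trial, other speed),
#' pooled. Optionally intensities are first divided by the fitted population
#' speed-intensity value at their own speed.
#'
#' @inheritParams intensity_classify_within
#' @param core_v Core speed (mm/s).
#' @param normalize Divide intensities by the population fit before
#'   comparison.
#' @param fit A `speed_intensity_fit`; required when `normalize = TRUE`.
#' @return One-row classification data frame (decisions pooled over the
#'   other speeds).
#' @export
intensity_classify_across <- function(ts, core_v, measure = c("peak", "mean"),
                                      normalize = FALSE, fit = NULL,
                                      audit = FALSE) {
  measure <- match.arg(measure)
  speeds <- sort(unique(ts$meta$speed_mm_s))
  if (length(speeds) < 2) stop("across-speed classification needs >= 2 speeds")
  if (!core_v %in% speeds) stop("no trials at core speed ", core_v)
  orients <- sort(unique(ts$meta$orientation_deg))
  x <- .intensity_values(ts, measure)
  if (normalize) {
    if (is.null(fit)) stop("normalize = TRUE requires a speed_intensity_fit")
    x <- x / predict_intensity(fit, ts$type, ts$meta$speed_mm_s)
  }
  core <- which(ts$meta$speed_mm_s == core_v)
  own <- ts$meta$orientation_deg[core]
  correct <- logical(0); audit_log <- list()
  for (v2 in setdiff(speeds, core_v)) {
    ref <- which(ts$meta$speed_mm_s == v2)
    sc <- .across_scores(ts$meta[ref, ], orients,
                         x_core = x[core], x_ref = x[ref])
    correct <- c(correct, .decide(sc$scores, orients, own))
    if (audit) audit_log <- c(audit_log, lapply(seq_along(core), function(i) {
      lapply(sc$audit, function(r) ref[r])
    }))
  }
  out <- .result_row(ts, paste0("intensity-", measure,
                                if (normalize) "-norm" else ""),
                     "across", core_v, 1 / length(orients), correct)
  if (audit) attr(out, "audit") <- audit_log
  out
}

# temporal-domain cross-speed correlation: per-speed profile matrices are
# aligned at the window centre (the response window is centred on the
# response's spatial centre of mass, so its temporal centre tracks it at
# every speed) and truncated to the shorter duration before correlating;
# rescaling time would covertly re-create the spatial domain.
.centre_rows <- function(M, L) {
  off <- floor((nrow(M) - L) / 2)
  M[off + seq_len(L), , drop = FALSE]
}

.cross_speed_R <- function(ts, domain, grid_step, idx1, idx2) {
  if (domain == "spatial") {
    M <- profile_matrix(ts, "spatial", grid_step, which = c(idx1, idx2))
    R <- .safe_cor(M)
    R[seq_along(idx1), length(idx1) + seq_along(idx2), drop = FALSE]
  } else {
    M1 <- profile_matrix(ts, "temporal", grid_step, which = idx1)
    M2 <- profile_matrix(ts, "temporal", grid_step, which = idx2)
    L <- min(nrow(M1), nrow(M2))
    .safe_cor(.centre_rows(M1, L), .centre_rows(M2, L))
  }
}

#' Across-speed ideal-observer classification from firing-rate profiles
#'
#' Each trial at the core speed is correlated with the per-orientation
#' reference profiles at every other speed; the orientation with the
#' highest mean correlation wins (strict argmax). In the spatial domain all
#' profiles live on the shared window grid; in the temporal domain profiles
#' are centre-aligned on an absolute time grid and truncated to the shorter
#' window duration, so speed compression/dilation is not compensated.
#'
#' @inheritParams intensity_classify_across
#' @param domain `"temporal"` or `"spatial"`.
#' @param grid_step Profile grid step (s or um).
#' @return One-row classification data frame (decisions pooled over the
#'   other speeds).
#' @export
profile_classify_across <- function(ts, core_v,
                                    domain = c("temporal", "spatial"),
                                    grid_step = NULL, audit = FALSE) {
  domain <- match.arg(domain)
  speeds <- sort(unique(ts$meta$speed_mm_s))
  if (length(speeds) < 2) stop("across-speed classification needs >= 2 speeds")
  if (!core_v %in% speeds) stop("no trials at core speed ", core_v)
  orients <- sort(unique(ts$meta$orientation_deg))
  core <- which(ts$meta$speed_mm_s == core_v)
  own <- ts$meta$orientation_deg[core]
  correct <- logical(0); audit_log <- list()
  for (v2 in setdiff(speeds, core_v)) {
    ref <- which(ts$meta$speed_mm_s == v2)
    Rb <- .cross_speed_R(ts, domain, grid_step, core, ref)
    sc <- .across_scores(ts$meta[ref, ], orients, R_block = Rb)
    correct <- c(correct, .decide(sc$scores, orients, own))
    if (audit) audit_log <- c(audit_log, lapply(seq_along(core), function(i) {
      lapply(sc$audit, function(r) ref[r])
    }))
  }
  out <- .result_row(ts, paste0("profile-", substr(domain, 1, 1)), "across",
                     core_v, 1 / length(orients), correct)
  if (audit) attr(out, "audit") <- audit_log
  out
}

# map an orientation pair to its angular difference
.pair_table <- function(orients) {
  pairs <- utils::combn(sort(orients), 2)
  data.frame(o1 = pairs[1, ], o2 = pairs[2, ],
             dtheta = abs(pairs[2, ] - pairs[1, ]))
}

#' Pairwise orientation discrimination as a function of angular difference
#'
#' Restricts the across-speed decision rule to the two orientations of each
#' available pair and pools decisions over the pairs sharing an angular
#' difference. With the +/-5 and +/-10 degree stimulus set the differences
#' are 5 (two pairs), 10, 15 (two pairs) and 20 degrees; chance is 1/2.
#'
#' @param ts A `trial_set`.
#' @param R Precomputed trial x trial correlation matrix over `ts$meta`
#'   rows (e.g. from [smoothed_matrix()] + `.safe_cor`, or a profile
#'   matrix); if `NULL`, computed from `scheme`.
#' @param scheme `"convolved"` or `"profile-spatial"` (used when `R` is
#'   `NULL`).
#' @param sigma_um Kernel SD for `scheme = "convolved"`.
#' @param grid_step Grid step passed to the signal construction.
#' @param dtheta Angular differences (deg) to report; default all available.
#' @return Data frame, one row per (dtheta, core speed): accuracy pooled
#'   over the pairs with that angular difference and the other speeds.
#' @export
pairwise_accuracy <- function(ts, R = NULL, scheme = c("convolved",
                                                       "profile-spatial"),
                              sigma_um = 70, grid_step = NULL,
                              dtheta = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(R)) {
    M <- if (scheme == "convolved") {
      smoothed_matrix(ts, sigma_um, grid_step)
    } else {
      profile_matrix(ts, "spatial", grid_step)
    }
    R <- .safe_cor(M)
  }
  speeds <- sort(unique(ts$meta$speed_mm_s))
  if (length(speeds) < 2) stop("across-speed classification needs >= 2 speeds")
  pt <- .pair_table(unique(ts$meta$orientation_deg))
  if (is.null(dtheta)) dtheta <- sort(unique(pt$dtheta))
  if (!all(dtheta %in% pt$dtheta)) {
    stop("angular difference(s) not available: ",
         paste(setdiff(dtheta, pt$dtheta), collapse = ", "))
  }
  out <- list()
  for (dt in dtheta) {
    prs <- pt[pt$dtheta == dt, ]
    for (v in speeds) {
      correct <- logical(0)
      for (p in seq_len(nrow(prs))) {
        orients <- c(prs$o1[p], prs$o2[p])
        core <- which(ts$meta$speed_mm_s == v &
                      ts$meta$orientation_deg %in% orients)
        own <- ts$meta$orientation_deg[core]
        for (v2 in setdiff(speeds, v)) {
          ref <- which(ts$meta$speed_mm_s == v2 &
                       ts$meta$orientation_deg %in% orients)
          sc <- .across_scores(ts$meta[ref, ], orients,
                               R_block = R[core, ref, drop = FALSE])
          correct <- c(correct, .decide(sc$scores, orients, own))
        }
      }
      row <- .result_row(ts, scheme, "pairwise-across", v, 0.5, correct)
      row$dtheta <- dt
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Orientation x speed confusion matrix
#'
#' Probability that a trial of condition (orientation, speed) classified
#' against the references of another (or the same) speed is assigned each
#' orientation. Within-speed blocks use the hold-out rule; across-speed
#' blocks use the full reference sets. Ties split assignment mass
#' uniformly, so each 4-column block of every row sums to 1.
#'
#' @param ts A `trial_set`.
#' @param R Trial x trial correlation matrix over `ts$meta` rows.
#' @return Square matrix (orientations x speeds on both axes, speed-major;
#'   32 x 32 for the full design), with dimnames like `"v30_th-5"`.
#' @export
confusion_matrix <- function(ts, R) {
  speeds <- sort(unique(ts$meta$speed_mm_s))
  orients <- sort(unique(ts$meta$orientation_deg))
  lab <- as.vector(t(outer(speeds, orients, function(v, o)
    sprintf("v%g_th%g", v, o))))
  CM <- matrix(0, length(lab), length(lab), dimnames = list(lab, lab))
  for (v in speeds) {
    for (o in orients) {
      core <- which(ts$meta$speed_mm_s == v & ts$meta$orientation_deg == o)
      ri <- sprintf("v%g_th%g", v, o)
      for (v2 in speeds) {
        if (v2 == v) {
          all_v <- which(ts$meta$speed_mm_s == v)
          sc <- .within_scores(ts$meta[all_v, ], orients,
                               R = R[all_v, all_v, drop = FALSE])
          mass <- .assign_mass(sc$scores, orients)[match(core, all_v), ,
                                                   drop = FALSE]
        } else {
          ref <- which(ts$meta$speed_mm_s == v2)
          sc <- .across_scores(ts$meta[ref, ], orients,
                               R_block = R[core, ref, drop = FALSE])
          mass <- .assign_mass(sc$scores, orients)
        }
        CM[ri, sprintf("v%g_th%g", v2, orients)] <- colMeans(mass)
      }
    }
  }
  CM
}
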
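#' Shuffle orientation labels (null calibration)
#'
#' Permutes the orientation labels among the trials of each speed condition
#' of a segmented neuron, preserving the per-orientation trial counts, and
#' renumbers trial indices within each condition. Destroys any genuine
#' orientation signal while keeping the response signals untouched, so
#' every classifier should fall to its chance level. Uses the current RNG
#' state.
#'
#' @param ts A `trial_set`.
#' @return A `trial_set` with permuted orientation labels.
#' @export
shuffle_orientations <- function(ts) {
  meta <- ts$meta
  for (v in unique(meta$speed_mm_s)) {
    idx <- which(meta$speed_mm_s == v)
    meta$orientation_deg[idx] <- sample(meta$orientation_deg[idx])
  }
  meta$trial_index <- stats::ave(seq_len(nrow(meta)),
                                 meta$speed_mm_s, meta$orientation_deg,
                                 FUN = seq_along)
  ts$meta <- meta
  ts
}

#' Aggregate per-neuron classification results
#'
#' Group means with SEM across neurons, plus optional chance-subtracted and
#' arcsine-square-root-transformed accuracy columns.
#'
#' @param results Data frame of classification rows (one or more per
#'   neuron), with an `accuracy` and a `chance` column.
#' @param by Character vector of grouping columns (e.g.
#'   `c("type", "scheme", "core_speed")`).
#' @param transform Add `acc_minus_chance` and `asin_sqrt` columns.
#' @return Data frame: grouping columns, `mean_accuracy`, `sem` (SD across
#'   contributing rows / sqrt(n)), `n`, `chance`.
#' @export
aggregate_results <- function(results, by = c("type", "scheme", "core_speed"),
                              transform = FALSE) {
  groups <- split(results, results[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(df) {
    row <- df[1, by, drop = FALSE]
    row$mean_accuracy <- mean(df$accuracy)
    row$sem <- if (nrow(df) > 1) sd(df$accuracy) / sqrt(nrow(df)) else 0
    row$n <- nrow(df)
    row$chance <- df$chance[1]
    row
  }))
  rownames(out) <- NULL
  if (transform) {
    out$acc_minus_chance <- out$mean_accuracy - out$chance
    out$asin_sqrt <- asin(sqrt(out$mean_accuracy))
  }
  out
}

#' One-tailed above-chance tests with Bonferroni correction
#'
#' Per group (typically neuron type x speed), a one-tailed one-sample
#' t-test of the per-neuron accuracies against chance, with Bonferroni
#' correction over the number of speeds tested. Zero-variance groups are
#' flagged and decided by the sign of the mean difference.
#'
#' @param results Per-neuron classification rows with `accuracy`.
#' @param chance Chance level tested against (0.5 for pairwise).
#' @param by Grouping columns (default `c("type", "core_speed")`).
#' @param n_comparisons Bonferroni factor (default: number of distinct core
#'   speeds in `results`).
#' @param alpha Significance level after correction.
#' @return Data frame: grouping columns, n, mean_accuracy, t, p, p_bonf,
#'   significant, degenerate.
#' @export
above_chance_test <- function(results, chance = 0.5,
                              by = c("type", "core_speed"),
                              n_comparisons = NULL, alpha = 0.05) {
  if (is.null(n_comparisons)) {
    n_comparisons <- length(unique(results$core_speed))
  }
  groups <- split(results, results[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(df) {
    row <- df[1, by, drop = FALSE]
    x <- df$accuracy
    if (length(x) < 2) stop("above-chance test needs >= 2 neurons per group")
    row$n <- length(x)
    row$mean_accuracy <- mean(x)
    if (sd(x) == 0) {
      row$t <- NA_real_; row$p <- NA_real_; row$p_bonf <- NA_real_
      row$significant <- mean(x) > chance
      row$degenerate <- TRUE
    } else {
      tt <- t.test(x, mu = chance, alternative = "greater")
      row$t <- unname(tt$statistic)
      row$p <- tt$p.value
      row$p_bonf <- min(1, tt$p.value * n_comparisons)
      row$significant <- row$p_bonf < alpha
      row$degenerate <- FALSE
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Classify one neuron under every scheme
#'
#' Convenience wrapper running the within- and across-speed classifiers
#' (intensity and profile based) for every core speed of one segmented
#' neuron.
#'
#' @param ts A `trial_set`.
#' @param fit Optional `speed_intensity_fit` enabling the speed-normalised
#'   intensity schemes.
#' @param grid_step_t,grid_step_s Temporal / spatial profile grid steps.
#' @return Data frame of classification rows.
#' @export
classify_neuron <- function(ts, fit = NULL, grid_step_t = NULL,
                            grid_step_s = NULL) {
  speeds <- sort(unique(ts$meta$speed_mm_s))
  out <- list()
  for (v in speeds) {
    out[[length(out) + 1]] <- intensity_classify_within(ts, v, "peak")
    out[[length(out) + 1]] <- intensity_classify_within(ts, v, "mean")
    out[[length(out) + 1]] <- profile_classify_within(ts, v, "temporal",
                                                      grid_step_t)
    out[[length(out) + 1]] <- profile_classify_within(ts, v, "spatial",
                                                      grid_step_s)
    out[[length(out) + 1]] <- intensity_classify_across(ts, v, "peak")
    out[[length(out) + 1]] <- intensity_classify_across(ts, v, "mean")
    if (!is.null(fit)) {
      out[[length(out) + 1]] <- intensity_classify_across(
        ts, v, fit$measure, normalize = TRUE, fit = fit)
    }
    out[[length(out) + 1]] <- profile_classify_across(ts, v, "temporal",
                                                      grid_step_t)
    out[[length(out) + 1]] <- profile_classify_across(ts, v, "spatial",
                                                      grid_step_s)
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Segments every neuron, computes feature tables, within- and across-speed
#' classification under all schemes, kernel correlation curves and best
#' kernels, convolved-train classification with the type-level mean best
#' kernel (full speed set and the 15-45 mm/s subset), pairwise
#' discrimination by angular difference, a confusion matrix per neuron
#' type, summary tables and above-chance tests. Deterministic given the
#' dataset.
#'
#' @param records List of `neuron_record`s (e.g. from [generate_dataset()]
#'   or [load_dataset()]).
#' @param sigmas_um Kernel sweep (um).
#' @param common_speeds Speed subset for the "commonly used speeds"
#'   analysis.
#' @param out_dir Optional directory; when given, tables are written as CSV
#'   and a `manifest.json` records what was run.
#' @return List: `features`, `classification`, `kernel_curves`,
#'   `best_kernels` (list per_speed / per_neuron), `type_kernels` (named
#'   vector of type-level mean best kernels, um), `convolved`,
#'   `convolved_common`, `pairwise`, `confusion` (list per type),
#'   `summary`, `above_chance`.
#' @export
run_pipeline <- function(records, sigmas_um = default_sigmas(),
                         common_speeds = c(15, 20, 30, 45),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tss <- stage("segment", lapply(records, segment_trials))
  features <- stage("features", do.call(rbind, lapply(tss, feature_table)))
  fit_peak <- stage("speed_fit", fit_population_speed_function(features, "peak"))
  classification <- stage("classify",
                          do.call(rbind, lapply(tss, classify_neuron,
                                                fit = fit_peak)))
  curves <- stage("kernels",
                  do.call(rbind, lapply(tss, correlation_curves, sigmas_um)))
  bk <- stage("best_kernel", best_kernel(curves))
  ok <- !bk$per_neuron$flagged
  type_kernels <- tapply(bk$per_neuron$mean_best_sigma_um[ok],
                         bk$per_neuron$type[ok], mean)
  conv <- list(); conv_common <- list(); pw <- list(); confusion <- list()
  for (id in names(tss)) {
    ts <- tss[[id]]
    sig <- unname(type_kernels[ts$type])
    if (is.na(sig)) next
    conv[[id]] <- stage("convolved", classify_convolved(ts, sig))
    avail <- intersect(common_speeds, unique(ts$meta$speed_mm_s))
    if (length(avail) >= 2) {
      conv_common[[id]] <- classify_convolved(ts, sig, speed_set = avail)
    }
    R <- .safe_cor(smoothed_matrix(ts, sig))
    pw[[id]] <- stage("pairwise", pairwise_accuracy(ts, R = R,
                                                    scheme = "convolved",
                                                    sigma_um = sig))
    cm <- stage("confusion", confusion_matrix(ts, R))
    confusion[[ts$type]] <- if (is.null(confusion[[ts$type]])) cm else
      confusion[[ts$type]] + cm
  }
  n_type <- table(vapply(tss, function(ts) ts$type, character(1)))
  for (tp in names(confusion)) confusion[[tp]] <- confusion[[tp]] / n_type[[tp]]
  conv <- do.call(rbind, conv); conv_common <- do.call(rbind, conv_common)
  pw <- do.call(rbind, pw)
  summary_tab <- stage("summary", aggregate_results(
    rbind(classification, conv),
    by = c("type", "scheme", "scope", "core_speed"), transform = TRUE))
  ac <- stage("above_chance", {
    d5 <- pw[pw$dtheta == 5, ]
    enough <- names(n_type)[n_type >= 2]
    if (length(enough)) {
      above_chance_test(d5[d5$type %in% enough, ], chance = 0.5)
    } else {
      warning("above-chance test skipped: fewer than 2 neurons per type")
      NULL
    }
  })
  res <- list(features = features, classification = classification,
              kernel_curves = curves, best_kernels = bk,
              type_kernels = type_kernels, convolved = conv,
              convolved_common = conv_common, pairwise = pw,
              confusion = confusion, summary = summary_tab,
              above_chance = ac)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(classification, file.path(out_dir, "classification.csv"),
              row.names = FALSE)
    write.csv(curves, file.path(out_dir, "kernel_curves.csv"),
              row.names = FALSE)
    write.csv(bk$per_neuron, file.path(out_dir, "best_kernels.csv"),
              row.names = FALSE)
    write.csv(rbind(conv, conv_common), file.path(out_dir, "convolved.csv"),
              row.names = FALSE)
    write.csv(pw, file.path(out_dir, "pairwise.csv"), row.names = FALSE)
    write.csv(summary_tab, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    if (!is.null(ac)) {
      write.csv(ac, file.path(out_dir, "above_chance.csv"), row.names = FALSE)
    }
    jsonlite::write_json(
      list(n_neurons = length(records), sigmas_um = sigmas_um,
           common_speeds = common_speeds,
           type_kernels = as.list(type_kernels),
           timestamp = format(Sys.time(), tz = "UTC")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
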
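#' Stimulus drum layout
#'
#' Describes the raised-line stimulus pattern embossed on the rotating drum:
#' four edge orientations relative to the axis perpendicular to the scanning
#' direction, each presented five times per drum rotation, with lines spaced
#' far enough apart that only one line is ever inside a receptive field.
#'
#' @param orientations_deg Edge orientations in degrees.
#' @param repetitions_per_rotation Presentations of each orientation per
#'   drum rotation.
#' @param rotations Number of drum rotations per speed condition.
#' @param min_line_spacing_mm Minimum spacing between adjacent lines (mm);
#'   also the length of the response window.
#' @param drum_diameter_mm Drum diameter (mm).
#' @param first_line_mm Drum position of the first line (mm).
#' @param line_spacing_mm Actual spacing used between consecutive lines (mm).
#' @return An object of class `stimulus_layout`: a list with the layout
#'   constants and a `line_positions` data frame (orientation_deg,
#'   presentation, position_mm) giving the nominal drum position at which
#'   each line crosses the scan axis.
#' @export
stimulus_layout <- function(orientations_deg = c(-10, -5, 5, 10),
                            repetitions_per_rotation = 5,
                            rotations = 3,
                            min_line_spacing_mm = 8,
                            drum_diameter_mm = 59,
                            first_line_mm = 6,
                            line_spacing_mm = 9.2) {
  n_or <- length(orientations_deg)
  n_lines <- n_or * repetitions_per_rotation
  # interleave orientations: each presentation block holds all orientations
  ord <- rep(orientations_deg, times = repetitions_per_rotation)
  pres <- rep(seq_len(repetitions_per_rotation), each = n_or)
  pos <- first_line_mm + (seq_len(n_lines) - 1) * line_spacing_mm
  layout <- list(
    orientations_deg = orientations_deg,
    repetitions_per_rotation = repetitions_per_rotation,
    rotations = rotations,
    line_span_mm = 12,
    line_height_mm = 0.5,
    line_width_top_mm = 0.5,
    line_width_base_mm = 0.8,
    min_line_spacing_mm = min_line_spacing_mm,
    drum_diameter_mm = drum_diameter_mm,
    line_positions = data.frame(
      orientation_deg = ord,
      presentation = pres,
      position_mm = pos
    )
  )
  class(layout) <- "stimulus_layout"
  validate_layout(layout)
  layout
}

#' @rdname stimulus_layout
#' @param layout A `stimulus_layout` object.
#' @export
validate_layout <- function(layout) {
  lp <- layout$line_positions
  gaps <- diff(sort(lp$position_mm))
  if (any(gaps < layout$min_line_spacing_mm - 1e-9)) {
    stop("layout invalid: adjacent lines closer than min_line_spacing_mm")
  }
  counts <- table(lp$orientation_deg)
  if (any(counts != layout$repetitions_per_rotation)) {
    stop("layout invalid: each orientation must appear ",
         layout$repetitions_per_rotation, " times per rotation")
  }
  invisible(layout)
}

#' Constant-speed drum position trace
#'
#' Builds the position trace of the rotating drum for one rotation at a
#' constant scanning speed, sampled on a uniform time grid. Real traces come
#' from a shaft encoder; synthetic traces are exactly linear so that linear
#' interpolation reproduces position without error.
#'
#' @param speed_mm_s Scanning speed label (mm/s).
#' @param length_mm Drum travel covered by the trace (mm).
#' @param sample_hz Sampling rate of the trace (Hz).
#' @return Data frame with columns `time_s` and `position_um`.
#' @export
constant_speed_trace <- function(speed_mm_s, length_mm, sample_hz = 200) {
  t_end <- length_mm / speed_mm_s
  times <- seq(0, t_end, by = 1 / sample_hz)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  data.frame(time_s = times, position_um = times * speed_mm_s * 1000)
}

#' Single-afferent record
#'
#' Bundles everything recorded from one afferent: its spikes over all trials
#' (one row per spike, with trial metadata), one drum trace per speed, and
#' the stimulus layout.
#'
#' @param id Neuron identifier (character).
#' @param type `"FA-1"` or `"SA-1"`.
#' @param spikes Data frame with columns `speed_mm_s`, `rotation`,
#'   `presentation`, `orientation_deg`, `spike_time_s`. Spike times are
#'   relative to the start of the rotation they belong to.
#' @param traces Named list (names = speed labels) of drum trace data frames
#'   (`time_s`, `position_um`), one rotation each.
#' @param layout A `stimulus_layout`.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `neuron_record`.
#' @export
neuron_record <- function(id, type, spikes, traces, layout, validate = TRUE) {
  type <- match.arg(type, c("FA-1", "SA-1"))
  rec <- structure(
    list(id = as.character(id), type = type, spikes = spikes,
         traces = traces, layout = layout),
    class = "neuron_record"
  )
  if (validate) validate_record(rec)
  rec
}

#' @rdname neuron_record
#' @param rec A `neuron_record`.
#' @export
validate_record <- function(rec) {
  req <- c("speed_mm_s", "rotation", "presentation", "orientation_deg",
           "spike_time_s")
  missing_cols <- setdiff(req, names(rec$spikes))
  if (length(missing_cols)) {
    stop("record ", rec$id, ": spikes table missing field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sp <- rec$spikes
  if (nrow(sp)) {
    key <- interaction(sp$speed_mm_s, sp$rotation, sp$presentation,
                       sp$orientation_deg, drop = TRUE)
    bad <- vapply(split(sp$spike_time_s, key),
                  function(t) any(diff(sort(t)) <= 0) || is.unsorted(t),
                  logical(1))
    if (any(bad)) {
      stop("record ", rec$id,
           ": non-monotone or duplicated spike times in trial(s) ",
           paste(names(bad)[bad], collapse = ", "))
    }
  }
  for (v in names(rec$traces)) {
    tr <- rec$traces[[v]]
    if (is.unsorted(tr$position_um)) {
      stop("record ", rec$id, ": drum trace at ", v,
           " mm/s has non-monotone position")
    }
    dt <- diff(tr$time_s); dx <- diff(tr$position_um)
    med_v <- median(dx / dt) / 1000
    if (abs(med_v - as.numeric(v)) > 0.05 * as.numeric(v)) {
      stop("record ", rec$id, ": drum trace median speed ",
           signif(med_v, 4), " mm/s deviates >5% from label ", v)
    }
  }
  invisible(rec)
}

#' Speeds available in a record
#' @param rec A `neuron_record`.
#' @return Numeric vector of speed labels (mm/s).
#' @export
record_speeds <- function(rec) as.numeric(names(rec$traces))

#' Convert spike times to drum positions
#'
#' References each action potential to the position of the stimulus surface
#' relative to the skin by linear interpolation of the drum position trace.
#'
#' @param spike_times_s Spike times (s), within the trace's time support.
#' @param trace Drum trace data frame (`time_s`, `position_um`).
#' @return Positions (um), same length and order as the input.
#' @export
spikes_to_positions <- function(spike_times_s, trace) {
  if (!length(spike_times_s)) return(numeric(0))
  rng <- range(trace$time_s)
  if (any(spike_times_s < rng[1] - 1e-12 | spike_times_s > rng[2] + 1e-12)) {
    stop("spike time(s) outside the drum trace time support [",
         rng[1], ", ", rng[2], "] s")
  }
  approx(trace$time_s, trace$position_um, xout = spike_times_s,
         rule = 2, ties = "ordered")$y
}

# inverse map: drum position -> time (positions strictly increasing for
# constant-speed traces; flat segments resolved to the earliest time)
.position_to_time <- function(position_um, trace) {
  approx(trace$position_um, trace$time_s, xout = position_um,
         rule = 2, ties = min)$y
}

#' Segment a record into per-passage response windows
#'
#' Cuts each line passage into an 8 mm response window (the minimum spacing
#' between lines on the drum) and expresses spikes in both temporal and
#' spatial coordinates relative to the window. For each line (orientation x
#' presentation slot) the window is centred on the spike-density centre of
#' mass of the pooled response to that line (all speeds, rotations), falling
#' back to the nominal line position when fewer than `min_pooled_spikes`
#' spikes are available; the centre is clamped so adjacent windows cannot
#' overlap. The same centre is used at every speed so that spatial-domain
#' responses are registered across speeds.
#'
#' @param rec A `neuron_record`.
#' @param window_um Window length (um), default 8000.
#' @param min_pooled_spikes Minimum pooled spike count for centre-of-mass
#'   alignment (default 10).
#' @return An object of class `trial_set`: list with `neuron_id`, `type`,
#'   `meta` (data frame: one row per trial with speed, orientation,
#'   rotation, presentation, trial_index 1..n within its condition,
#'   duration_s, n_spikes, flagged) and `trials` (list of lists with
#'   `times_s` and `positions_um` relative to window start; window closed at
#'   both ends).
#' @export
segment_trials <- function(rec, window_um = 8000, min_pooled_spikes = 10) {
  layout <- rec$layout
  lp <- layout$line_positions
  speeds <- record_speeds(rec)
  sp <- rec$spikes

  # absolute spike positions per (speed, rotation)
  sp$position_um <- NA_real_
  for (v in speeds) {
    sel <- sp$speed_mm_s == v
    if (any(sel)) {
      sp$position_um[sel] <- spikes_to_positions(sp$spike_time_s[sel],
                                                 rec$traces[[as.character(v)]])
    }
  }

  # window centre per line, clamped so adjacent windows never overlap
  gap_um <- min(diff(sort(lp$position_mm))) * 1000
  clamp <- max(0, (gap_um - window_um) / 2)
  centers <- numeric(nrow(lp))
  for (i in seq_len(nrow(lp))) {
    nominal <- lp$position_mm[i] * 1000
    pooled <- sp$position_um[sp$orientation_deg == lp$orientation_deg[i] &
                             sp$presentation == lp$presentation[i]]
    pooled <- pooled[abs(pooled - nominal) <= gap_um / 2]
    if (length(pooled) >= min_pooled_spikes) {
      com <- mean(pooled)
      centers[i] <- nominal + max(-clamp, min(clamp, com - nominal))
    } else {
      centers[i] <- nominal
    }
  }

  meta <- list(); trials <- list(); k <- 0L
  for (v in speeds) {
    trace <- rec$traces[[as.character(v)]]
    for (i in seq_len(nrow(lp))) {
      w0 <- centers[i] - window_um / 2
      w1 <- centers[i] + window_um / 2
      t0 <- .position_to_time(w0, trace)
      t1 <- .position_to_time(w1, trace)
      for (rot in seq_len(layout$rotations)) {
        sel <- sp$speed_mm_s == v & sp$rotation == rot &
          sp$presentation == lp$presentation[i] &
          sp$orientation_deg == lp$orientation_deg[i] &
          sp$position_um >= w0 - 1e-6 & sp$position_um <= w1 + 1e-6
        pos <- sp$position_um[sel] - w0
        tim <- sp$spike_time_s[sel] - t0
        o <- order(tim)
        k <- k + 1L
        trials[[k]] <- list(times_s = tim[o], positions_um = pos[o])
        meta[[k]] <- data.frame(
          speed_mm_s = v,
          orientation_deg = lp$orientation_deg[i],
          rotation = rot,
          presentation = lp$presentation[i],
          duration_s = t1 - t0,
          n_spikes = length(pos),
          flagged = length(pos) < 2
        )
      }
    }
  }
  meta <- do.call(rbind, meta)
  # stable trial index 1..n within each (speed, orientation)
  meta$trial_index <- stats::ave(seq_len(nrow(meta)),
                                 meta$speed_mm_s, meta$orientation_deg,
                                 FUN = seq_along)
  structure(
    list(neuron_id = rec$id, type = rec$type, window_um = window_um,
         meta = meta, trials = trials),
    class = "trial_set"
  )
}

#' Save / load datasets in the canonical on-disk format
#'
#' One directory per neuron, containing `meta.json` (id, type, speeds,
#' layout constants including line positions), `spikes.csv` (neuron_id,
#' speed_mm_s, rotation, presentation, orientation_deg, spike_time_s) and
#' `drum.csv` (speed_mm_s, time_s, position_um). UTF-8 CSV, comma separator,
#' `.` decimal, header row.
#'
#' @param records List of `neuron_record`s.
#' @param path Target directory (created if needed).
#' @param truth Optional list of ground-truth generative models, written to
#'   `truth.json` at the top level.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(records, path, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (rec in records) {
    d <- file.path(path, rec$id)
    dir.create(d, showWarnings = FALSE)
    meta <- list(
      neuron_id = rec$id, type = rec$type,
      speeds_mm_s = record_speeds(rec),
      layout = unclass(rec$layout)
    )
    jsonlite::write_json(meta, file.path(d, "meta.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    # %.17g guarantees exact double round-trip through the text format
    spikes <- cbind(neuron_id = rec$id, rec$spikes)
    spikes$spike_time_s <- sprintf("%.17g", spikes$spike_time_s)
    write.csv(spikes, file.path(d, "spikes.csv"), row.names = FALSE,
              quote = FALSE)
    drum <- do.call(rbind, lapply(names(rec$traces), function(v) {
      data.frame(speed_mm_s = as.numeric(v),
                 time_s = sprintf("%.17g", rec$traces[[v]]$time_s),
                 position_um = sprintf("%.17g", rec$traces[[v]]$position_um))
    }))
    write.csv(drum, file.path(d, "drum.csv"), row.names = FALSE,
              quote = FALSE)
  }
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_dataset
#' @param strict If `TRUE` (default), a record failing validation aborts the
#'   load with an error naming the record; if `FALSE`, failing records are
#'   dropped with a warning listing them.
#' @return `load_dataset`: list of `neuron_record`s.
#' @export
load_dataset <- function(path, strict = TRUE) {
  if (!dir.exists(path)) stop("dataset path does not exist: ", path)
  dirs <- list.dirs(path, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (!length(dirs)) {
    warning("no neuron directories found in ", path)
    return(list())
  }
  records <- list(); failed <- character(0)
  for (d in dirs) {
    res <- tryCatch({
      meta <- jsonlite::read_json(file.path(d, "meta.json"),
                                  simplifyVector = TRUE)
      lay <- meta$layout
      layout <- structure(
        list(
          orientations_deg = lay$orientations_deg,
          repetitions_per_rotation = lay$repetitions_per_rotation,
          rotations = lay$rotations,
          line_span_mm = lay$line_span_mm,
          line_height_mm = lay$line_height_mm,
          line_width_top_mm = lay$line_width_top_mm,
          line_width_base_mm = lay$line_width_base_mm,
          min_line_spacing_mm = lay$min_line_spacing_mm,
          drum_diameter_mm = lay$drum_diameter_mm,
          line_positions = as.data.frame(lay$line_positions)
        ),
        class = "stimulus_layout"
      )
      spikes <- read.csv(file.path(d, "spikes.csv"))
      spikes$neuron_id <- NULL
      for (cl in c("speed_mm_s", "orientation_deg", "spike_time_s")) {
        spikes[[cl]] <- as.numeric(spikes[[cl]])
      }
      for (cl in c("rotation", "presentation")) {
        spikes[[cl]] <- as.integer(spikes[[cl]])
      }
      drum <- read.csv(file.path(d, "drum.csv"))
      traces <- lapply(split(drum, drum$speed_mm_s),
                       function(x) data.frame(time_s = x$time_s,
                                              position_um = x$position_um))
      names(traces) <- names(split(drum, drum$speed_mm_s))
      neuron_record(meta$neuron_id, meta$type, spikes, traces, layout)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop("failed to load ", basename(d), ": ",
                       conditionMessage(res))
      failed <- c(failed, basename(d))
    } else {
      records[[res$id]] <- res
    }
  }
  if (length(failed)) {
    warning("dropped record(s) failing validation: ",
            paste(failed, collapse = ", "))
  }
  records
}
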
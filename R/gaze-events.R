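# Low-level gaze signal processing: dispersion-threshold (I-DT) fixation
# detection, saccade extraction between fixations, and the two quality
# control indices (drift-check accuracy, sample-to-sample precision RMS).

stream_samples <- function(stream) {
  if (inherits(stream, "gaze_stream")) stream$samples
  else if (is.data.frame(stream)) stream
  else stop("expected a gaze_stream or a samples data.frame", call. = FALSE)
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Scans the stream left to right and emits maximal runs of samples whose
#' dispersion — (max - min of x) + (max - min of y) — stays within
#' `dispersion_deg` and whose time span is at least `min_duration_ms`
#' (inclusive). Runs are greedy and non-overlapping: from each candidate
#' start the run is extended as far as the dispersion constraint allows; if
#' it is long enough it becomes a fixation and scanning resumes after it,
#' otherwise scanning advances one sample.
#'
#' Invalid samples whose enclosing valid-to-valid gap is at most `max_gap_ms`
#' (blinks, dropped frames) are bridged by linear interpolation; longer
#' invalid gaps break runs, as do recording gaps longer than `max_gap_ms`.
#'
#' @param stream A [gaze_stream()] or samples data.frame (columns `time_ms`,
#'   `x_deg`, `y_deg`, `valid`).
#' @param dispersion_deg Maximum dispersion of a fixation (degrees).
#' @param min_duration_ms Minimum fixation time span (ms, inclusive).
#' @param max_gap_ms Longest invalid/recording gap that may be bridged.
#' @return data.frame with one row per fixation: `start_ms`, `end_ms`,
#'   `duration_ms`, `centroid_x_deg`, `centroid_y_deg`, `n_samples`.
#' @export
detect_fixations <- function(stream, dispersion_deg = 1.0,
                             min_duration_ms = 100, max_gap_ms = 75) {
  stopifnot(dispersion_deg > 0, min_duration_ms > 0)
  s <- stream_samples(stream)
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      duration_ms = numeric(0), centroid_x_deg = numeric(0),
                      centroid_y_deg = numeric(0), n_samples = integer(0))
  if (nrow(s) == 0) return(empty)
  if (any(diff(s$time_ms) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  s <- bridge_invalid(s, max_gap_ms)
  segs <- split(seq_len(nrow(s)), s$segment)
  out <- lapply(segs, function(idx) {
    idt_scan(s$time_ms[idx], s$x_deg[idx], s$y_deg[idx],
             dispersion_deg, min_duration_ms)
  })
  out <- do.call(rbind, out[order(vapply(segs, min, 1L))])
  if (is.null(out) || nrow(out) == 0) return(empty)
  rownames(out) <- NULL
  out
}

# Interpolate short invalid gaps; label hard-break segments. Returns the
# samples restricted to usable rows plus a `segment` column.
bridge_invalid <- function(s, max_gap_ms) {
  n <- nrow(s)
  usable <- s$valid
  x <- s$x_deg; y <- s$y_deg
  if (any(!s$valid)) {
    r <- rle(s$valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(!r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i0 == 1L || i1 == n) next            # leading/trailing: drop
      gap <- s$time_ms[i1 + 1L] - s$time_ms[i0 - 1L]
      if (gap <= max_gap_ms) {
        idx <- i0:i1
        f <- (s$time_ms[idx] - s$time_ms[i0 - 1L]) / gap
        x[idx] <- x[i0 - 1L] + f * (x[i1 + 1L] - x[i0 - 1L])
        y[idx] <- y[i0 - 1L] + f * (y[i1 + 1L] - y[i0 - 1L])
        usable[idx] <- TRUE
      }
    }
  }
  s$x_deg <- x; s$y_deg <- y
  s <- s[usable, , drop = FALSE]
  if (nrow(s) == 0) return(cbind(s, segment = integer(0)))
  brk <- c(FALSE, diff(s$time_ms) > max_gap_ms)
  s$segment <- cumsum(brk) + 1L
  s
}

# Greedy maximal-run I-DT over one gap-free segment.
idt_scan <- function(tt, x, y, dispersion, min_dur) {
  n <- length(tt)
  rows <- list()
  i <- 1L
  while (i <= n) {
    xmin <- xmax <- x[i]; ymin <- ymax <- y[i]
    j <- i
    while (j < n) {
      nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
      nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
      if ((nxmax - nxmin) + (nymax - nymin) > dispersion) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    if (tt[j] - tt[i] >= min_dur) {
      rows[[length(rows) + 1L]] <-
        data.frame(start_ms = tt[i], end_ms = tt[j],
                   duration_ms = tt[j] - tt[i],
                   centroid_x_deg = mean(x[i:j]),
                   centroid_y_deg = mean(y[i:j]),
                   n_samples = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(rows) == 0) NULL else do.call(rbind, rows)
}

#' Extract saccades between adjacent fixations
#'
#' One saccade per adjacent fixation pair whose intervening interval
#' contains no unbridgeable invalid gap: amplitude is the Euclidean distance
#' between the two fixation centroids, duration the time between the end of
#' the first fixation and the start of the next.
#'
#' @inheritParams detect_fixations
#' @param fixations Output of [detect_fixations()] on the same stream.
#' @return data.frame with columns `start_ms`, `end_ms`, `duration_ms`,
#'   `amplitude_deg`.
#' @export
detect_saccades <- function(stream, fixations, max_gap_ms = 75) {
  empty <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      duration_ms = numeric(0), amplitude_deg = numeric(0))
  if (is.null(fixations) || nrow(fixations) < 2) return(empty)
  s <- stream_samples(stream)
  out <- list()
  for (k in seq_len(nrow(fixations) - 1L)) {
    t0 <- fixations$end_ms[k]
    t1 <- fixations$start_ms[k + 1L]
    between <- s[s$time_ms > t0 & s$time_ms < t1, , drop = FALSE]
    # an unbridgeable gap between the two fixations disqualifies the pair
    tt <- c(t0, between$time_ms[between$valid], t1)
    if (any(diff(tt) > max_gap_ms) && t1 - t0 > max_gap_ms) next
    out[[length(out) + 1L]] <- data.frame(
      start_ms = t0, end_ms = t1, duration_ms = t1 - t0,
      amplitude_deg = sqrt(
        (fixations$centroid_x_deg[k + 1L] - fixations$centroid_x_deg[k])^2 +
          (fixations$centroid_y_deg[k + 1L] - fixations$centroid_y_deg[k])^2))
  }
  if (length(out) == 0) empty else do.call(rbind, out)
}

#' Drift-check accuracy
#'
#' Calibration accuracy at one drift check: the displacement, in degrees of
#' visual angle, between the centroid of the valid gaze samples and the
#' known target location.
#'
#' @param check_samples A [gaze_stream()] or samples data.frame recorded
#'   while the child fixated the drift target.
#' @param target_x_deg,target_y_deg Target location (degrees).
#' @return Offset in degrees, or `NA` if no valid sample exists.
#' @export
drift_accuracy <- function(check_samples, target_x_deg = 0,
                           target_y_deg = 0) {
  s <- stream_samples(check_samples)
  s <- s[s$valid, , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  sqrt((mean(s$x_deg) - target_x_deg)^2 + (mean(s$y_deg) - target_y_deg)^2)
}

#' Precision as the RMS of successive sample distances
#'
#' Measurement precision within a fixation: the root mean square of the
#' Euclidean distances between successive valid samples (the default), or of
#' distances to the fixation centroid (`method = "centroid"`).
#'
#' @param fixation_samples A [gaze_stream()] or samples data.frame restricted
#'   to one fixation.
#' @param method `"successive"` (default) or `"centroid"`.
#' @return RMS in degrees, or `NA` with fewer than two valid samples.
#' @export
precision_rms <- function(fixation_samples,
                          method = c("successive", "centroid")) {
  method <- match.arg(method)
  s <- stream_samples(fixation_samples)
  s <- s[s$valid, , drop = FALSE]
  if (nrow(s) < 2) return(NA_real_)
  if (method == "successive") {
    d2 <- diff(s$x_deg)^2 + diff(s$y_deg)^2
  } else {
    d2 <- (s$x_deg - mean(s$x_deg))^2 + (s$y_deg - mean(s$y_deg))^2
  }
  sqrt(mean(d2))
}

#' Per-child precision pooled over all fixations
#'
#' RMS of successive sample-to-sample distances pooled (in the squared
#' domain) over every detected fixation of a stream.
#'
#' @inheritParams detect_fixations
#' @param fixations Output of [detect_fixations()]; detected from `stream`
#'   if omitted.
#' @param ... Passed to [detect_fixations()] when `fixations` is NULL.
#' @return Pooled RMS in degrees (`NA` if no fixation has two valid samples).
#' @export
precision_rms_pooled <- function(stream, fixations = NULL, ...) {
  s <- stream_samples(stream)
  if (is.null(fixations)) fixations <- detect_fixations(stream, ...)
  d2 <- numeric(0)
  for (k in seq_len(nrow(fixations))) {
    f <- s[s$time_ms >= fixations$start_ms[k] &
             s$time_ms <= fixations$end_ms[k] & s$valid, , drop = FALSE]
    if (nrow(f) >= 2) d2 <- c(d2, diff(f$x_deg)^2 + diff(f$y_deg)^2)
  }
  if (length(d2) == 0) return(NA_real_)
  sqrt(mean(d2))
}

#' Assemble a per-child quality-control record
#'
#' @param drift_errors_deg Offsets from each drift check (degrees), NA
#'   entries dropped.
#' @param precision_rms_deg Pooled precision RMS for the child.
#' @return List of class `qc_record`: `drift_errors_deg`,
#'   `mean_drift_error_deg`, `intraindividual_sd_deg`, `precision_rms_deg`,
#'   `n_drift_checks`.
#' @export
qc_record <- function(drift_errors_deg, precision_rms_deg = NA_real_) {
  e <- drift_errors_deg[!is.na(drift_errors_deg)]
  stopifnot(all(e >= 0), is.na(precision_rms_deg) || precision_rms_deg >= 0)
  structure(list(drift_errors_deg = e,
                 mean_drift_error_deg = if (length(e)) mean(e) else NA_real_,
                 intraindividual_sd_deg = if (length(e) > 1) stats::sd(e)
                                          else NA_real_,
                 precision_rms_deg = precision_rms_deg,
                 n_drift_checks = length(e)),
            class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat(sprintf(
    "QC: %d drift checks, mean error %.2f deg (SD %.2f), precision RMS %.2f deg\n",
    x$n_drift_checks, x$mean_drift_error_deg, x$intraindividual_sd_deg,
    x$precision_rms_deg))
  invisible(x)
}
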
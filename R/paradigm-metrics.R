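# Paradigm-level biomarker computation: nonsocial preference (GeoPref),
# gap-overlap disengagement metrics, pupillary light reflex latency and
# amplitude, oculomotor/pupil summaries, and the usable-data gate.

point_in_aoi <- function(x, y, aoi) {
  x >= aoi[["xmin"]] & x <= aoi[["xmax"]] &
    y >= aoi[["ymin"]] & y <= aoi[["ymax"]]
}

#' Nonsocial preference percentage (GeoPref)
#'
#' Percentage of AOI looking time spent on the nonsocial (geometric) video:
#' `100 * dwell(nonsocial) / (dwell(nonsocial) + dwell(social))`, where
#' dwell is counted over valid samples inside either AOI; samples outside
#' both AOIs do not enter the denominator.
#'
#' @param stream A [gaze_stream()] or samples data.frame.
#' @param aois Named list with rectangles `nonsocial` and `social`
#'   (`c(xmin, xmax, ymin, ymax)` in degrees); taken from the stream's
#'   annotations when omitted.
#' @return Percentage in `[0, 100]`, or `NA` if total AOI dwell is zero.
#' @export
nonsocial_preference <- function(stream, aois = NULL) {
  s <- stream_samples(stream)
  if (is.null(aois) && inherits(stream, "gaze_stream"))
    aois <- stream$annotations$aois
  if (is.null(aois$nonsocial) || is.null(aois$social))
    stop("both `nonsocial` and `social` AOIs must be defined", call. = FALSE)
  s <- s[s$valid, , drop = FALSE]
  n_non <- sum(point_in_aoi(s$x_deg, s$y_deg, aois$nonsocial))
  n_soc <- sum(point_in_aoi(s$x_deg, s$y_deg, aois$social))
  if (n_non + n_soc == 0) return(NA_real_)
  100 * n_non / (n_non + n_soc)
}

#' Shift latency of one gap-overlap trial
#'
#' Latency of the first gaze shift into the peripheral target AOI after
#' target onset. Shifts faster than `min_rt_ms` are anticipatory and
#' disqualify the trial; absence of a qualifying shift within `max_rt_ms`
#' makes it a no-shift trial.
#'
#' @param trial_samples Samples of one trial.
#' @param target_onset_ms Target onset time (same clock as `time_ms`).
#' @param target_aoi Target rectangle (`c(xmin, xmax, ymin, ymax)`).
#' @param min_rt_ms,max_rt_ms Response validity window (ms, inclusive).
#' @return List with `status` (`"shift"`, `"no_shift"`, `"anticipatory"`)
#'   and `rt_ms` (`NA` unless `status == "shift"`).
#' @export
extract_shift_latency <- function(trial_samples, target_onset_ms,
                                  target_aoi, min_rt_ms = 100,
                                  max_rt_ms = 1000) {
  s <- stream_samples(trial_samples)
  s <- s[s$valid & s$time_ms >= target_onset_ms, , drop = FALSE]
  hit <- which(point_in_aoi(s$x_deg, s$y_deg, target_aoi))
  if (length(hit) == 0)
    return(list(status = "no_shift", rt_ms = NA_real_))
  rt <- s$time_ms[hit[1L]] - target_onset_ms
  if (rt < min_rt_ms) return(list(status = "anticipatory", rt_ms = NA_real_))
  if (rt > max_rt_ms) return(list(status = "no_shift", rt_ms = NA_real_))
  list(status = "shift", rt_ms = rt)
}

#' Gap-overlap disengagement metrics from per-trial outcomes
#'
#' Computes the two condition-contrast metrics from trial-level outcomes:
#' * `overlap_gap_rt_ms`: mean shift latency in overlap trials minus mean
#'   shift latency in gap trials;
#' * `no_shift_gap_effect_pct`: percentage of no-shift trials in overlap
#'   minus percentage in gap (signed; negative when gap exceeds overlap).
#'
#' Anticipatory trials are discarded entirely; no-shift percentages are
#' computed over shift + no-shift trials.
#'
#' @param trials data.frame with columns `condition` (`"gap"`/`"overlap"`)
#'   and `rt_ms` (`NA` for no-shift trials); an optional `status` column
#'   marks `"anticipatory"` trials for exclusion.
#' @return List with `overlap_gap_rt_ms`, `no_shift_gap_effect_pct`,
#'   per-condition means and no-shift percentages, and trial counts. A
#'   metric whose conditions lack valid trials is `NA`.
#' @export
gap_overlap_metrics <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("condition", "rt_ms") %in% names(trials)),
            all(trials$condition %in% c("gap", "overlap")))
  if ("status" %in% names(trials))
    trials <- trials[trials$status != "anticipatory", , drop = FALSE]
  stat <- function(cond) {
    tr <- trials[trials$condition == cond, , drop = FALSE]
    list(n = nrow(tr),
         mean_rt = if (any(!is.na(tr$rt_ms))) mean(tr$rt_ms, na.rm = TRUE)
                   else NA_real_,
         noshift_pct = if (nrow(tr)) 100 * mean(is.na(tr$rt_ms))
                       else NA_real_)
  }
  g <- stat("gap"); o <- stat("overlap")
  list(overlap_gap_rt_ms = o$mean_rt - g$mean_rt,
       no_shift_gap_effect_pct = o$noshift_pct - g$noshift_pct,
       gap_mean_rt_ms = g$mean_rt, overlap_mean_rt_ms = o$mean_rt,
       gap_noshift_pct = g$noshift_pct, overlap_noshift_pct = o$noshift_pct,
       n_gap = g$n, n_overlap = o$n)
}

#' Gap-overlap metrics straight from an annotated stream
#'
#' Runs [extract_shift_latency()] on every annotated trial and feeds the
#' outcomes to [gap_overlap_metrics()].
#'
#' @param stream A multi-trial [gaze_stream()] with `trials` annotations
#'   (columns `trial_id`, `condition`, `target_onset_ms`) and a `target`
#'   AOI.
#' @inheritParams extract_shift_latency
#' @return As [gap_overlap_metrics()], plus the per-trial outcome table as
#'   attribute `"trials"`.
#' @export
gap_overlap_from_stream <- function(stream, min_rt_ms = 100,
                                    max_rt_ms = 1000) {
  stopifnot(inherits(stream, "gaze_stream"))
  ann <- stream$annotations
  if (is.null(ann$trials) || is.null(ann$aois$target))
    stop("stream lacks gap-overlap trial annotations", call. = FALSE)
  s <- stream$samples
  rows <- lapply(seq_len(nrow(ann$trials)), function(i) {
    tr <- ann$trials[i, ]
    res <- extract_shift_latency(s[s$trial_id == tr$trial_id, , drop = FALSE],
                                 tr$target_onset_ms, ann$aois$target,
                                 min_rt_ms, max_rt_ms)
    data.frame(trial_id = tr$trial_id, condition = tr$condition,
               rt_ms = res$rt_ms, status = res$status)
  })
  trials <- do.call(rbind, rows)
  out <- gap_overlap_metrics(trials)
  attr(out, "trials") <- trials
  out
}

#' Pupillary light reflex latency and amplitude from one trial
#'
#' Baseline is the mean valid pupil diameter over the `baseline_ms` window
#' before flash onset. The pupil trace is smoothed with a causal moving
#' average of width `smooth_ms`; constriction onset is the sample preceding
#' the first run of `sustain_samples` consecutive post-flash samples whose
#' backward-difference velocity falls below `velocity_criterion` (mm/s).
#' Latency is onset minus flash onset; amplitude is
#' `100 * (baseline - minimum pupil) / baseline` over the post-flash window.
#'
#' @param trace data.frame with `time_ms`, `pupil_mm`, `valid` (or a
#'   single-trial [gaze_stream()]).
#' @param flash_onset_ms Flash onset time.
#' @param baseline_ms Pre-flash baseline window length.
#' @param smooth_ms Causal moving-average width.
#' @param velocity_criterion Constriction velocity threshold (mm/s,
#'   negative).
#' @param sustain_samples Consecutive samples the criterion must hold.
#' @return List with `latency_ms`, `amplitude_pct`, `baseline_mm`; latency
#'   and amplitude are both `NA` when no constriction is detected.
#' @export
plr_metrics <- function(trace, flash_onset_ms, baseline_ms = 200,
                        smooth_ms = 50, velocity_criterion = -0.3,
                        sustain_samples = 3L) {
  s <- stream_samples(trace)
  s <- s[s$valid & !is.na(s$pupil_mm), , drop = FALSE]
  none <- list(latency_ms = NA_real_, amplitude_pct = NA_real_,
               baseline_mm = NA_real_)
  if (nrow(s) < 2) return(none)
  base_idx <- s$time_ms >= flash_onset_ms - baseline_ms &
    s$time_ms < flash_onset_ms
  if (!any(base_idx)) stop("no valid samples in the baseline window",
                           call. = FALSE)
  baseline <- mean(s$pupil_mm[base_idx])
  none$baseline_mm <- baseline

  dt_s <- median(diff(s$time_ms)) / 1000
  w <- max(1L, round(smooth_ms / (1000 * dt_s)))
  ps <- stats::filter(s$pupil_mm, rep(1 / w, w), sides = 1)
  ps[seq_len(min(w - 1L, length(ps)))] <-
    cumsum(s$pupil_mm)[seq_len(min(w - 1L, length(ps)))] /
    seq_len(min(w - 1L, length(ps)))
  v <- c(NA, diff(as.numeric(ps)) / diff(s$time_ms) * 1000)  # mm/s

  below <- !is.na(v) & v < velocity_criterion & s$time_ms > flash_onset_ms
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  k <- which(run$values & run$lengths >= sustain_samples)
  if (length(k) == 0) return(none)
  i0 <- starts[k[1L]]
  onset_ms <- s$time_ms[i0 - 1L]
  if (i0 == 1L || onset_ms < flash_onset_ms) onset_ms <- s$time_ms[i0]
  post <- s$pupil_mm[s$time_ms >= flash_onset_ms]
  list(latency_ms = onset_ms - flash_onset_ms,
       amplitude_pct = 100 * (baseline - min(post)) / baseline,
       baseline_mm = baseline)
}

#' PLR metrics from a multi-trial stream (per-trial median)
#'
#' @param stream A [gaze_stream()] with `trials` annotations carrying
#'   `flash_onset_ms`.
#' @param ... Passed to [plr_metrics()].
#' @return List with `latency_ms` and `amplitude_pct` (medians over trials
#'   with a detected constriction; `NA` when none).
#' @export
plr_from_stream <- function(stream, ...) {
  stopifnot(inherits(stream, "gaze_stream"))
  ann <- stream$annotations
  if (is.null(ann$trials) || is.null(ann$trials$flash_onset_ms))
    stop("stream lacks PLR trial annotations", call. = FALSE)
  s <- stream$samples
  res <- lapply(seq_len(nrow(ann$trials)), function(i) {
    tr <- ann$trials[i, ]
    plr_metrics(s[s$trial_id == tr$trial_id, , drop = FALSE],
                tr$flash_onset_ms, ...)
  })
  lat <- vapply(res, `[[`, 1.0, "latency_ms")
  amp <- vapply(res, `[[`, 1.0, "amplitude_pct")
  ok <- !is.na(lat)
  list(latency_ms = if (any(ok)) stats::median(lat[ok]) else NA_real_,
       amplitude_pct = if (any(ok)) stats::median(amp[ok]) else NA_real_,
       n_trials_detected = sum(ok))
}

#' Oculomotor and pupil summaries for a paradigm
#'
#' Arithmetic means over the events and valid samples of one paradigm:
#' mean fixation duration, mean saccade amplitude and duration, and tonic
#' pupil size (mean valid pupil diameter).
#'
#' @param fixations Output of [detect_fixations()].
#' @param saccades Output of [detect_saccades()] (optional).
#' @param stream The underlying stream (needed for tonic pupil).
#' @return List with `mean_fixation_duration_ms`,
#'   `mean_saccade_amplitude_deg`, `mean_saccade_duration_ms`,
#'   `tonic_pupil_mm`, `n_fixations`, `n_saccades`; `NA` where no events or
#'   samples are available.
#' @export
fixation_and_pupil_summaries <- function(fixations, saccades = NULL,
                                         stream = NULL) {
  out <- list(mean_fixation_duration_ms = NA_real_,
              mean_saccade_amplitude_deg = NA_real_,
              mean_saccade_duration_ms = NA_real_,
              tonic_pupil_mm = NA_real_,
              n_fixations = 0L, n_saccades = 0L)
  if (!is.null(fixations) && nrow(fixations) > 0) {
    out$mean_fixation_duration_ms <- mean(fixations$duration_ms)
    out$n_fixations <- nrow(fixations)
  }
  if (!is.null(saccades) && nrow(saccades) > 0) {
    out$mean_saccade_amplitude_deg <- mean(saccades$amplitude_deg)
    out$mean_saccade_duration_ms <- mean(saccades$duration_ms)
    out$n_saccades <- nrow(saccades)
  }
  if (!is.null(stream)) {
    s <- stream_samples(stream)
    p <- s$pupil_mm[s$valid & !is.na(s$pupil_mm)]
    if (length(p)) out$tonic_pupil_mm <- mean(p)
  }
  out
}

#' Usable-data gate for a task
#'
#' A task contributes metrics only when its valid-sample fraction and its
#' count of trials with at least one valid sample reach the thresholds
#' (inclusive at the boundary).
#'
#' @param stream A [gaze_stream()] or samples data.frame.
#' @param min_valid_fraction Minimum fraction of valid samples.
#' @param min_valid_trials Minimum number of trials with valid data (1 for
#'   single-trial paradigms).
#' @return TRUE if the task is usable.
#' @export
usable_task_gate <- function(stream, min_valid_fraction = 0.5,
                             min_valid_trials = 1L) {
  s <- stream_samples(stream)
  if (nrow(s) == 0) return(FALSE)
  frac <- mean(s$valid)
  tid <- if ("trial_id" %in% names(s)) s$trial_id else rep(1L, nrow(s))
  n_valid_trials <- length(unique(tid[s$valid]))
  frac >= min_valid_fraction && n_valid_trials >= min_valid_trials
}

#' Extract the full biomarker vector of one child from their streams
#'
#' Applies the per-paradigm pipeline (usable-data gate, event detection,
#' paradigm metrics) to a named list of streams and assembles the one-row
#' biomarker record. Paradigms that are absent or fail the gate yield `NA`
#' metrics (missing data are never imputed).
#'
#' @param streams Named list of [gaze_stream()] objects; names among
#'   `geopref`, `gap_overlap`, `plr`, `resting`, `exploration`.
#' @param dispersion_deg,min_duration_ms Fixation-detector settings.
#' @param min_valid_fraction Usable-data gate threshold.
#' @param ... Passed to [plr_metrics()] via [plr_from_stream()].
#' @return One-row data.frame with the six biomarkers and auxiliary metrics.
#' @export
extract_biomarkers <- function(streams, dispersion_deg = 1.0,
                               min_duration_ms = 100,
                               min_valid_fraction = 0.5, ...) {
  metrics <- c(biomarker_names(), auxiliary_metric_names())
  out <- as.list(rep(NA_real_, length(metrics)))
  names(out) <- metrics
  usable <- function(p) !is.null(streams[[p]]) &&
    usable_task_gate(streams[[p]], min_valid_fraction)

  if (usable("geopref"))
    out$nonsocial_preference_pct <- nonsocial_preference(streams$geopref)
  if (usable("gap_overlap")) {
    go <- gap_overlap_from_stream(streams$gap_overlap)
    out$no_shift_gap_effect_pct <- go$no_shift_gap_effect_pct
    out$overlap_gap_rt_ms <- go$overlap_gap_rt_ms
  }
  if (usable("plr")) {
    pl <- plr_from_stream(streams$plr, ...)
    out$plr_latency_ms <- pl$latency_ms
    out$plr_amplitude_pct <- pl$amplitude_pct
  }
  if (usable("resting")) {
    st <- streams$resting
    fx <- detect_fixations(st, dispersion_deg, min_duration_ms)
    sc <- detect_saccades(st, fx)
    sm <- fixation_and_pupil_summaries(fx, sc, st)
    out$resting_fixation_duration_ms <- sm$mean_fixation_duration_ms
    out$tonic_pupil_mm <- sm$tonic_pupil_mm
    out$saccade_amplitude_deg <- sm$mean_saccade_amplitude_deg
    out$saccade_duration_ms <- sm$mean_saccade_duration_ms
  }
  if (usable("exploration")) {
    fx <- detect_fixations(streams$exploration, dispersion_deg,
                           min_duration_ms)
    sm <- fixation_and_pupil_summaries(fx)
    out$exploration_fixation_duration_ms <- sm$mean_fixation_duration_ms
  }
  as.data.frame(out)
}
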
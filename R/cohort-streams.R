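# Rendering a simulated cohort to raw streams and extracting biomarkers
# back out of them: the end-to-end parameter-recovery path.

#' Render one child's latent metrics to per-paradigm streams
#'
#' Builds the paradigm-level ground truth from a child's latent metric
#' values and renders each (non-missing) paradigm with
#' [simulate_gaze_stream()].
#'
#' @param latent Named list or one-row data.frame of latent metric values
#'   (see [biomarker_names()], [auxiliary_metric_names()]).
#' @param missing Optional character vector of paradigms to skip (the
#'   child's unusable tasks).
#' @param sampling_rate,noise_sd,pupil_noise_mm,seed Passed to
#'   [simulate_gaze_stream()].
#' @param gap_rt_baseline_ms,noshift_gap_baseline_pct Gap-condition
#'   baselines from which the condition contrasts are rendered.
#' @return Named list of [gaze_stream()] objects.
#' @export
render_child_streams <- function(latent, missing = character(0),
                                 sampling_rate = 100, noise_sd = 0.08,
                                 pupil_noise_mm = 0.002, seed = NULL,
                                 gap_rt_baseline_ms = 280,
                                 noshift_gap_baseline_pct = 30) {
  lat <- as.list(latent)
  gts <- list(
    geopref = list(preference_pct = lat$nonsocial_preference_pct,
                   tonic_pupil_mm = lat$tonic_pupil_mm %||% 4.3),
    gap_overlap = list(gap_rt_ms = gap_rt_baseline_ms,
                       overlap_rt_ms = gap_rt_baseline_ms +
                         lat$overlap_gap_rt_ms,
                       noshift_gap_pct = noshift_gap_baseline_pct,
                       noshift_overlap_pct = noshift_gap_baseline_pct +
                         lat$no_shift_gap_effect_pct),
    plr = list(latency_ms = lat$plr_latency_ms,
               amplitude_pct = lat$plr_amplitude_pct,
               baseline_mm = lat$tonic_pupil_mm %||% 5.0),
    resting = list(fixation_duration_ms = lat$resting_fixation_duration_ms,
                   tonic_pupil_mm = lat$tonic_pupil_mm %||% 4.3,
                   saccade_amplitude_deg = lat$saccade_amplitude_deg %||% 5.5),
    exploration = list(
      fixation_duration_ms = lat$exploration_fixation_duration_ms,
      tonic_pupil_mm = lat$tonic_pupil_mm %||% 4.3,
      saccade_amplitude_deg = lat$saccade_amplitude_deg %||% 5.5))
  keep <- setdiff(paradigm_names(), missing)
  run <- function() {
    out <- list()
    for (p in keep)
      out[[p]] <- simulate_gaze_stream(p, gts[[p]], sampling_rate,
                                       noise_sd, pupil_noise_mm)
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Render a whole simulated cohort to streams and extract biomarkers back
#'
#' The round-trip used to validate the extraction stages: every child's
#' latent metrics are rendered to raw streams (their unusable paradigms
#' skipped) and the full event-detection + paradigm-metric pipeline is run
#' on the streams.
#'
#' @param cohort A `gazedx_cohort` from [simulate_biomarker_table()].
#' @param sampling_rate,noise_sd,pupil_noise_mm Rendering settings.
#' @param seed Base seed; child i is rendered under `seed + i`.
#' @param ... Passed to [extract_biomarkers()].
#' @return data.frame: `id`, `group`, plus one column per extracted metric.
#' @export
extract_cohort_biomarkers <- function(cohort, sampling_rate = 100,
                                      noise_sd = 0.08,
                                      pupil_noise_mm = 0.002,
                                      seed = 1L, ...) {
  latent <- cohort_latent(cohort)
  miss <- attr(cohort, "missing_tasks")
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    missing_i <- if (is.null(miss)) character(0) else
      colnames(miss)[miss[i, ]]
    streams <- render_child_streams(latent[i, ], missing_i, sampling_rate,
                                    noise_sd, pupil_noise_mm,
                                    seed = seed + i)
    extract_biomarkers(streams, ...)
  })
  cbind(cohort[, c("id", "group")], do.call(rbind, rows))
}
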
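# Rendering of raw gaze/pupil streams from latent ground truth, one of the
# five paradigms at a time. Streams are the input contract of the event
# detection and paradigm-metric stages; returning the ground truth alongside
# makes parameter-recovery testing possible.

#' Construct a gaze stream object
#'
#' @param samples data.frame with columns `time_ms`, `x_deg`, `y_deg`,
#'   `pupil_mm`, `valid` (and optionally `trial_id`); times strictly
#'   increasing within a trial.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param paradigm Paradigm id or `NA`.
#' @param annotations List of trial/AOI annotations (AOIs are named vectors
#'   `c(xmin, xmax, ymin, ymax)` in degrees).
#' @param ground_truth Latent parameters the stream was rendered from, if
#'   known.
#' @return Object of class `gaze_stream`.
#' @export
gaze_stream <- function(samples, sampling_rate, paradigm = NA_character_,
                        annotations = list(), ground_truth = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("time_ms", "x_deg", "y_deg", "pupil_mm", "valid") %in%
                  names(samples)))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  tid <- if ("trial_id" %in% names(samples)) samples$trial_id else
    rep(1L, nrow(samples))
  for (id in unique(tid)) {
    tt <- samples$time_ms[tid == id]
    if (any(diff(tt) <= 0))
      stop("sample times must be strictly increasing within a trial",
           call. = FALSE)
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 paradigm = paradigm, annotations = annotations,
                 ground_truth = ground_truth),
            class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("Gaze stream [%s]: %d samples @ %g Hz, %.0f ms, %.1f%% valid\n",
              x$paradigm, nrow(x$samples), x$sampling_rate,
              max(x$samples$time_ms) - min(x$samples$time_ms),
              100 * mean(x$samples$valid)))
  invisible(x)
}

# Standard screen layout (degrees of visual angle, screen-centred origin).
geopref_aois <- function() {
  list(nonsocial = c(xmin = -13, xmax = -2, ymin = -5, ymax = 5),
       social = c(xmin = 2, xmax = 13, ymin = -5, ymax = 5))
}

gap_overlap_aois <- function() {
  list(center = c(xmin = -2, xmax = 2, ymin = -2, ymax = 2),
       target = c(xmin = 8, xmax = 12, ymin = -2, ymax = 2))
}

#' Build a deterministic gap-overlap trial plan from summary ground truth
#'
#' Expands condition-level targets (mean response time per condition and
#' no-shift percentage per condition) into per-trial ground truth: every
#' responding trial gets the condition's mean latency, and the number of
#' no-shift trials is the nearest realizable count. The realized (count
#' quantized) summary values are attached, since they — not the continuous
#' inputs — are what a perfect extraction recovers.
#'
#' @param gap_rt_ms,overlap_rt_ms Mean shift latency per condition (ms from
#'   target onset).
#' @param noshift_gap_pct,noshift_overlap_pct Percentage of trials with no
#'   qualifying shift, per condition.
#' @param trials_per_condition Trials per condition.
#' @return data.frame with columns `condition`, `shift_latency_ms` (NA for
#'   no-shift trials); attribute `realized` holds the realized summary
#'   metrics.
#' @export
gap_overlap_trial_plan <- function(gap_rt_ms = 280,
                                   overlap_rt_ms = 280 + 100,
                                   noshift_gap_pct = 30,
                                   noshift_overlap_pct = 40,
                                   trials_per_condition = 40L) {
  n <- as.integer(trials_per_condition)
  stopifnot(n >= 1L)
  mk <- function(cond, rt, ns_pct) {
    k <- round(ns_pct / 100 * n)
    k <- max(0L, min(n, k))
    data.frame(condition = cond,
               shift_latency_ms = c(rep(rt, n - k), rep(NA_real_, k)))
  }
  plan <- rbind(mk("gap", gap_rt_ms, noshift_gap_pct),
                mk("overlap", overlap_rt_ms, noshift_overlap_pct))
  ns <- function(cond) 100 * mean(is.na(
    plan$shift_latency_ms[plan$condition == cond]))
  attr(plan, "realized") <- list(
    overlap_gap_rt_ms = overlap_rt_ms - gap_rt_ms,
    noshift_gap_pct = ns("gap"),
    noshift_overlap_pct = ns("overlap"),
    no_shift_gap_effect_pct = ns("overlap") - ns("gap"))
  plan
}

#' Render a synthetic gaze/pupil stream for one paradigm
#'
#' Produces a raw stream whose signal content is fully determined by
#' `ground_truth`, with Gaussian positional jitter of SD `noise_sd` degrees
#' around the true fixation points and Gaussian pupil noise of SD
#' `pupil_noise_mm`. With both noise terms at zero the stream is an exact
#' rendering, so paradigm metrics must recover the latent parameters up to
#' sample-period quantization.
#'
#' Ground-truth fields by paradigm (all optional fields have defaults):
#' * `geopref`: `preference_pct`, `duration_ms` (30000).
#' * `gap_overlap`: either `trials` (from [gap_overlap_trial_plan()]) or the
#'   summary fields that plan accepts; `target_onset_ms` (400),
#'   `trial_duration_ms` (1500).
#' * `plr`: `latency_ms`, `amplitude_pct`, `baseline_mm` (5), `n_trials` (3),
#'   `flash_onset_ms` (500), `constriction_time_ms` (400),
#'   `trial_duration_ms` (2500).
#' * `resting` / `exploration`: `fixation_duration_ms`, `tonic_pupil_mm`
#'   (4.3), `saccade_amplitude_deg` (5.5), `duration_ms` (20000); or an
#'   explicit `fixations` data.frame with columns `x`, `y`, `duration_ms`.
#'
#' @param paradigm One of `"geopref"`, `"gap_overlap"`, `"plr"`,
#'   `"resting"`, `"exploration"`.
#' @param ground_truth Named list of latent parameters (see Details).
#' @param sampling_rate Samples per second (default 100 Hz).
#' @param noise_sd Positional jitter SD in degrees.
#' @param pupil_noise_mm Pupil noise SD in mm.
#' @param seed Optional seed for the jitter (uses current RNG if NULL).
#' @return A [gaze_stream()] carrying annotations and the (realized) ground
#'   truth.
#' @export
simulate_gaze_stream <- function(paradigm, ground_truth,
                                 sampling_rate = 100, noise_sd = 0.08,
                                 pupil_noise_mm = 0.002, seed = NULL) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be > 0", call. = FALSE)
  render <- switch(paradigm,
                   geopref = render_geopref,
                   gap_overlap = render_gap_overlap,
                   plr = render_plr,
                   resting = render_fixation_paradigm,
                   exploration = render_fixation_paradigm,
                   stop("unknown paradigm id: ", paradigm, call. = FALSE))
  body <- function() render(paradigm, ground_truth, sampling_rate,
                            noise_sd, pupil_noise_mm)
  if (is.null(seed)) body() else with_seed(seed, body())
}

jitter2 <- function(n, sd) {
  if (sd == 0) matrix(0, n, 2) else matrix(stats::rnorm(2 * n, 0, sd), n, 2)
}

render_geopref <- function(paradigm, gt, rate, noise_sd, pupil_noise_mm) {
  pref <- gt$preference_pct
  stopifnot(is.numeric(pref), pref >= 0, pref <= 100)
  dur <- gt$duration_ms %||% 30000
  tonic <- gt$tonic_pupil_mm %||% 4.3
  dt <- 1000 / rate
  tt <- seq(0, dur - dt, by = dt)
  n <- length(tt)
  n_non <- round(pref / 100 * n)
  side <- rep(c("nonsocial", "social"), c(n_non, n - n_non))
  # fixation-like structure: re-fixate every ~500 ms within the active AOI
  centers <- list(nonsocial = c(-7, 0), social = c(7, 0))
  seg <- ceiling(seq_len(n) / max(1, round(500 / dt)))
  segs <- interaction(side, seg, drop = TRUE)
  fx <- fy <- numeric(n)
  for (s in levels(segs)) {
    i <- which(segs == s)
    ctr <- centers[[side[i[1]]]]
    pt <- ctr + stats::runif(2, -3, 3)
    fx[i] <- pt[1]; fy[i] <- pt[2]
  }
  jit <- jitter2(n, noise_sd)
  samples <- data.frame(time_ms = tt, x_deg = fx + jit[, 1],
                        y_deg = fy + jit[, 2],
                        pupil_mm = tonic + stats::rnorm(n, 0, pupil_noise_mm),
                        valid = TRUE)
  gt$realized <- list(nonsocial_preference_pct = 100 * n_non / n)
  gaze_stream(samples, rate, paradigm,
              annotations = list(aois = geopref_aois()), ground_truth = gt)
}

render_gap_overlap <- function(paradigm, gt, rate, noise_sd, pupil_noise_mm) {
  trials <- gt[["trials"]]          # [[ avoids partial matching against
  if (is.null(trials)) {            # trials_per_condition
    base_rt <- gt[["gap_rt_ms"]] %||% 280
    ov_rt <- gt[["overlap_rt_ms"]] %||%
      (base_rt + (gt[["overlap_gap_rt_ms"]] %||% 100))
    ns_gap <- gt[["noshift_gap_pct"]] %||% 30
    ns_ov <- gt[["noshift_overlap_pct"]] %||%
      (ns_gap + (gt[["no_shift_gap_effect_pct"]] %||% 10))
    trials <- gap_overlap_trial_plan(base_rt, ov_rt, ns_gap, ns_ov,
                                     gt[["trials_per_condition"]] %||% 40L)
  }
  onset <- gt$target_onset_ms %||% 400
  trial_dur <- gt$trial_duration_ms %||% 1500
  dt <- 1000 / rate
  tt <- seq(0, trial_dur - dt, by = dt)
  target <- c(10, 0)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    lat <- trials$shift_latency_ms[i]
    shifted <- !is.na(lat) & tt >= onset + ifelse(is.na(lat), Inf, lat)
    fx <- ifelse(shifted, target[1], 0)
    fy <- ifelse(shifted, target[2], 0)
    jit <- jitter2(length(tt), noise_sd)
    out[[i]] <- data.frame(time_ms = tt, x_deg = fx + jit[, 1],
                           y_deg = fy + jit[, 2],
                           pupil_mm = 4.3 + stats::rnorm(length(tt), 0,
                                                         pupil_noise_mm),
                           valid = TRUE, trial_id = i)
  }
  samples <- do.call(rbind, out)
  ann <- list(aois = gap_overlap_aois(),
              trials = data.frame(trial_id = seq_len(nrow(trials)),
                                  condition = trials$condition,
                                  target_onset_ms = onset))
  gt$trials <- trials
  gt$realized <- attr(trials, "realized")
  gaze_stream(samples, rate, paradigm, annotations = ann, ground_truth = gt)
}

render_plr <- function(paradigm, gt, rate, noise_sd, pupil_noise_mm) {
  lat <- gt$latency_ms
  amp <- gt$amplitude_pct
  stopifnot(is.numeric(lat), lat > 0, is.numeric(amp), amp >= 0, amp <= 100)
  base <- gt$baseline_mm %||% 5.0
  n_trials <- gt$n_trials %||% 3L
  flash <- gt$flash_onset_ms %||% 500
  ctime <- gt$constriction_time_ms %||% 400
  trial_dur <- gt$trial_duration_ms %||% 2500
  dt <- 1000 / rate
  tt <- seq(0, trial_dur - dt, by = dt)
  pmin_mm <- base * (1 - amp / 100)
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    onset <- flash + lat
    p <- ifelse(tt <= onset, base,
                ifelse(tt >= onset + ctime, pmin_mm,
                       base - (base - pmin_mm) * (tt - onset) / ctime))
    jit <- jitter2(length(tt), noise_sd)
    out[[i]] <- data.frame(time_ms = tt, x_deg = jit[, 1], y_deg = jit[, 2],
                           pupil_mm = p + stats::rnorm(length(tt), 0,
                                                       pupil_noise_mm),
                           valid = TRUE, trial_id = i)
  }
  ann <- list(trials = data.frame(trial_id = seq_len(n_trials),
                                  flash_onset_ms = flash))
  gaze_stream(do.call(rbind, out), rate, paradigm, annotations = ann,
              ground_truth = gt)
}

render_fixation_paradigm <- function(paradigm, gt, rate, noise_sd,
                                     pupil_noise_mm) {
  dt <- 1000 / rate
  tonic <- gt$tonic_pupil_mm %||% 4.3
  fixes <- gt$fixations
  if (is.null(fixes)) {
    fdur <- gt$fixation_duration_ms
    stopifnot(is.numeric(fdur), fdur > 0)
    amp <- gt$saccade_amplitude_deg %||% 5.5
    total <- gt$duration_ms %||% 20000
    per_fix <- round(fdur / dt) + 1L      # samples per fixation
    n_fix <- floor((total / dt) / per_fix)
    x <- y <- numeric(n_fix)
    pt <- c(0, 0)
    for (i in seq_len(n_fix)) {
      repeat {
        th <- stats::runif(1, 0, 2 * pi)
        cand <- pt + amp * c(cos(th), sin(th))
        if (all(abs(cand) <= 10)) break
      }
      pt <- cand
      x[i] <- pt[1]; y[i] <- pt[2]
    }
    fixes <- data.frame(x = x, y = y, duration_ms = fdur)
  }
  per_fix <- round(fixes$duration_ms / dt) + 1L
  fx <- rep(fixes$x, per_fix)
  fy <- rep(fixes$y, per_fix)
  n <- length(fx)
  tt <- seq(0, by = dt, length.out = n)
  jit <- jitter2(n, noise_sd)
  samples <- data.frame(time_ms = tt, x_deg = fx + jit[, 1],
                        y_deg = fy + jit[, 2],
                        pupil_mm = tonic + stats::rnorm(n, 0, pupil_noise_mm),
                        valid = TRUE)
  gt$fixations <- fixes
  gaze_stream(samples, rate, paradigm, ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a gaze stream as CSV plus JSON sidecar
#'
#' The samples go to `<prefix>.csv` (columns `time_ms`, `x_deg`, `y_deg`,
#' `pupil_mm`, `valid`, and `trial_id` when present); annotations, ground
#' truth, paradigm and sampling rate go to `<prefix>.json`.
#'
#' @param stream A [gaze_stream()].
#' @param prefix Path prefix (without extension).
#' @return `write_gaze_stream` returns the two paths invisibly;
#'   `read_gaze_stream` returns the reconstructed [gaze_stream()].
#' @export
write_gaze_stream <- function(stream, prefix) {
  stopifnot(inherits(stream, "gaze_stream"))
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  utils::write.csv(stream$samples, csv, row.names = FALSE)
  side <- list(paradigm = stream$paradigm,
               sampling_rate = stream$sampling_rate,
               annotations = stream$annotations,
               ground_truth = stream$ground_truth)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(c(csv = csv, json = js))
}

#' @rdname write_gaze_stream
#' @export
read_gaze_stream <- function(prefix) {
  samples <- utils::read.csv(paste0(prefix, ".csv"))
  samples$valid <- as.logical(samples$valid)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ann <- side$annotations
  if (!is.null(ann$aois)) ann$aois <- lapply(ann$aois, unlist)
  gaze_stream(samples, side$sampling_rate, side$paradigm %||% NA_character_,
              annotations = ann %||% list(),
              ground_truth = side$ground_truth)
}
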
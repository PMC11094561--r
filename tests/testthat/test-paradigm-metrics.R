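# Paradigm-level biomarkers: dwell preference, gap-overlap contrasts, PLR
# onset/amplitude, summaries, usable-data gating, and stream round-trips.

aois <- list(nonsocial = c(xmin = -13, xmax = -2, ymin = -5, ymax = 5),
             social = c(xmin = 2, xmax = 13, ymin = -5, ymax = 5))

test_that("nonsocial preference is the AOI dwell percentage", {
  s <- make_samples(c(rep(-7, 30), rep(7, 70)), rep(0, 100))
  expect_equal(nonsocial_preference(s, aois), 30)
  s2 <- make_samples(rep(-7, 50), rep(0, 50))
  expect_equal(nonsocial_preference(s2, aois), 100)
  # off-AOI samples drop out of the denominator
  s3 <- make_samples(c(rep(-7, 25), rep(0, 50), rep(7, 25)), rep(0, 100))
  expect_equal(nonsocial_preference(s3, aois), 50)
  s4 <- make_samples(rep(0, 20), rep(0, 20))
  expect_true(is.na(nonsocial_preference(s4, aois)))
  expect_error(nonsocial_preference(s4, list(social = aois$social)),
               "AOIs")
})

test_that("a noiseless GeoPref rendering recovers the latent preference", {
  st <- simulate_gaze_stream("geopref", list(preference_pct = 46.2),
                             noise_sd = 0, pupil_noise_mm = 0, seed = 1)
  expect_equal(nonsocial_preference(st), 46.2, tolerance = 1e-6)
  st100 <- simulate_gaze_stream("geopref", list(preference_pct = 100),
                                noise_sd = 0, pupil_noise_mm = 0, seed = 1)
  s <- st100$samples
  expect_true(all(s$x_deg >= -13 & s$x_deg <= -2))
  expect_equal(nonsocial_preference(st100), 100)
})

test_that("gap-overlap contrasts follow their definitions and signs", {
  trials <- data.frame(
    condition = rep(c("gap", "overlap"), each = 10),
    rt_ms = c(rep(300, 9), NA, rep(400, 8), NA, NA))
  m <- gap_overlap_metrics(trials)
  expect_equal(m$overlap_gap_rt_ms, 100)
  expect_equal(m$no_shift_gap_effect_pct, 10)
  # equal rates -> 0; reversed rates -> negative
  eq <- data.frame(condition = rep(c("gap", "overlap"), each = 4),
                   rt_ms = c(250, 250, NA, NA, 350, 350, NA, NA))
  expect_equal(gap_overlap_metrics(eq)$no_shift_gap_effect_pct, 0)
  rev <- data.frame(condition = rep(c("gap", "overlap"), each = 4),
                    rt_ms = c(250, NA, NA, NA, 350, 350, 350, 350))
  expect_equal(gap_overlap_metrics(rev)$no_shift_gap_effect_pct, -75)
  # a condition with no trials leaves the metrics missing
  solo <- data.frame(condition = rep("gap", 4), rt_ms = c(250, 260, NA, NA))
  expect_true(is.na(gap_overlap_metrics(solo)$overlap_gap_rt_ms))
})

test_that("anticipatory shifts are discarded, late shifts are no-shift", {
  tgt <- c(xmin = 8, xmax = 12, ymin = -2, ymax = 2)
  mk <- function(shift_ms) {
    tt <- seq(0, 1490, by = 10)
    x <- ifelse(tt >= 400 + shift_ms, 10, 0)
    make_samples(x, rep(0, length(tt)))
  }
  expect_equal(extract_shift_latency(mk(200), 400, tgt)$rt_ms, 200)
  expect_equal(extract_shift_latency(mk(50), 400, tgt)$status,
               "anticipatory")
  expect_equal(extract_shift_latency(mk(1050), 400, tgt)$status, "no_shift")
  none <- make_samples(rep(0, 150), rep(0, 150))
  expect_equal(extract_shift_latency(none, 400, tgt)$status, "no_shift")
})

test_that("a rendered gap trial round-trips its latency within one sample", {
  st <- simulate_gaze_stream("gap_overlap",
                             list(gap_rt_ms = 200, overlap_rt_ms = 333,
                                  noshift_gap_pct = 0,
                                  noshift_overlap_pct = 0,
                                  trials_per_condition = 5L),
                             noise_sd = 0, pupil_noise_mm = 0, seed = 1)
  m <- gap_overlap_from_stream(st)
  tr <- attr(m, "trials")
  expect_true(all(abs(tr$rt_ms[tr$condition == "gap"] - 200) <= 10))
  expect_true(all(abs(tr$rt_ms[tr$condition == "overlap"] - 333) <= 10))
  expect_lt(abs(m$overlap_gap_rt_ms - 133), 10 + 1e-9)
})

test_that("PLR amplitude and latency follow their definitions", {
  # trivial amplitude: baseline 5.0, minimum 3.5 -> 30%
  tt <- seq(0, 2490, by = 10)
  p <- ifelse(tt <= 770, 5, pmax(3.5, 5 - (tt - 770) * 0.00375))
  s <- make_samples(rep(0, length(tt)), rep(0, length(tt)))
  s$pupil_mm <- p
  m <- plr_metrics(s, flash_onset_ms = 500)
  expect_equal(m$amplitude_pct, 30)
  expect_equal(m$latency_ms, 270)
  # flat trace: no constriction detected
  s$pupil_mm <- 5
  flat <- plr_metrics(s, flash_onset_ms = 500)
  expect_true(is.na(flat$latency_ms) && is.na(flat$amplitude_pct))
})

test_that("noiseless PLR rendering recovers latency to one sample period", {
  for (lat in c(270, 268.51, 291.44)) {
    st <- simulate_gaze_stream("plr",
                               list(latency_ms = lat, amplitude_pct = 30,
                                    baseline_mm = 5),
                               noise_sd = 0, pupil_noise_mm = 0, seed = 1)
    m <- plr_from_stream(st)
    expect_lte(abs(m$latency_ms - lat), 10, label = paste("latency", lat))
    expect_equal(m$amplitude_pct, 30, tolerance = 0.2)
  }
})

test_that("summaries are arithmetic means; tonic pupil is the valid mean", {
  fx <- data.frame(duration_ms = c(400, 600))
  sm <- fixation_and_pupil_summaries(fx)
  expect_equal(sm$mean_fixation_duration_ms, 500)
  s <- make_samples(rep(0, 50), rep(0, 50), pupil = 4.2)
  sm2 <- fixation_and_pupil_summaries(fx, NULL, s)
  expect_equal(sm2$tonic_pupil_mm, 4.2)
  none <- fixation_and_pupil_summaries(fx[0, , drop = FALSE])
  expect_true(is.na(none$mean_fixation_duration_ms))
})

test_that("the usable-data gate is inclusive at the boundary", {
  s <- make_samples(rep(0, 100), rep(0, 100))
  expect_true(usable_task_gate(s, min_valid_fraction = 0.5))
  s$valid <- FALSE
  expect_false(usable_task_gate(s, min_valid_fraction = 0.5))
  s$valid[1:50] <- TRUE                      # exactly at the threshold
  expect_true(usable_task_gate(s, min_valid_fraction = 0.5))
  s$valid[50] <- FALSE                       # just below
  expect_false(usable_task_gate(s, min_valid_fraction = 0.5))
})

test_that("percentages respect their declared ranges on noisy inputs", {
  set.seed(9)
  for (rep in 1:5) {
    s <- make_samples(runif(400, -14, 14), runif(400, -6, 6))
    p <- nonsocial_preference(s, aois)
    if (!is.na(p)) expect_true(p >= 0 && p <= 100)
    tr <- data.frame(condition = sample(c("gap", "overlap"), 30, TRUE),
                     rt_ms = ifelse(runif(30) < 0.4, NA, runif(30, 100, 900)))
    m <- gap_overlap_metrics(tr)
    if (!is.na(m$no_shift_gap_effect_pct))
      expect_true(abs(m$no_shift_gap_effect_pct) <= 100)
  }
})

test_that("metrics are invariant to uniform time translation", {
  st <- simulate_gaze_stream("plr", list(latency_ms = 280,
                                         amplitude_pct = 25),
                             noise_sd = 0, pupil_noise_mm = 0, seed = 2)
  tr <- st$samples[st$samples$trial_id == 1, ]
  m0 <- plr_metrics(tr, 500)
  tr$time_ms <- tr$time_ms + 12345
  m1 <- plr_metrics(tr, 500 + 12345)
  expect_equal(m0$latency_ms, m1$latency_ms)
  expect_equal(m0$amplitude_pct, m1$amplitude_pct)
})

test_that("extract_biomarkers recovers one child's latent values", {
  latent <- list(nonsocial_preference_pct = 46.2,
                 no_shift_gap_effect_pct = 10,
                 overlap_gap_rt_ms = 100,
                 plr_latency_ms = 270, plr_amplitude_pct = 30,
                 resting_fixation_duration_ms = 530,
                 exploration_fixation_duration_ms = 340,
                 tonic_pupil_mm = 4.4, saccade_amplitude_deg = 5,
                 saccade_duration_ms = 40)
  streams <- render_child_streams(latent, noise_sd = 0, pupil_noise_mm = 0,
                                  seed = 5)
  bm <- extract_biomarkers(streams)
  expect_equal(bm$nonsocial_preference_pct, 46.2, tolerance = 0.05)
  expect_equal(bm$no_shift_gap_effect_pct, 10)
  expect_lte(abs(bm$plr_latency_ms - 270), 10)
  expect_equal(bm$plr_amplitude_pct, 30, tolerance = 0.2)
  expect_equal(bm$resting_fixation_duration_ms, 530, tolerance = 5)
  expect_equal(bm$exploration_fixation_duration_ms, 340, tolerance = 5)
  expect_equal(bm$tonic_pupil_mm, 4.4, tolerance = 1e-6)
  # a skipped paradigm leaves its metrics missing
  bm2 <- extract_biomarkers(streams[c("geopref", "plr")])
  expect_true(is.na(bm2$resting_fixation_duration_ms))
  expect_true(is.na(bm2$no_shift_gap_effect_pct))
  expect_false(is.na(bm2$plr_latency_ms))
})
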
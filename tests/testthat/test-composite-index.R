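# Fixed-specificity cutoffs, the any-positive composite, and the
# diagnostic-accuracy statistics.

test_that("cutoff on uniform 1..100 lands at 95 with specificity 0.95", {
  rule <- derive_cutoff(values_autism = 200,
                        values_nonautism = 1:100,
                        direction = "high_is_positive")
  expect_equal(rule$threshold, 95)
  expect_equal(rule$achieved_specificity, 0.95)
  # target 1.0: threshold at the maximum, zero nonautism positives
  r1 <- derive_cutoff(200, 1:100, "high_is_positive",
                      target_specificity = 1)
  expect_equal(r1$threshold, 100)
  expect_equal(sum(apply_cutoff(r1, 1:100)), 0L)
})

test_that("low_is_positive mirrors the high direction exactly", {
  set.seed(2)
  non <- rnorm(200, 10, 3)
  hi <- derive_cutoff(100, non, "high_is_positive")
  lo <- derive_cutoff(-100, -non, "low_is_positive")
  expect_equal(lo$threshold, -hi$threshold)
  expect_equal(lo$achieved_specificity, hi$achieved_specificity)
})

test_that("derived thresholds equal the brute-force least-extreme search", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(20:500, 1)
    non <- switch(1 + rep %% 3,
                  rnorm(n, 50, 12),
                  round(runif(n, 0, 100)),        # heavy ties
                  rexp(n, 0.1))
    dir <- if (rep %% 2) "high_is_positive" else "low_is_positive"
    tgt <- sample(c(0.8, 0.9, 0.95, 0.99), 1)
    rule <- derive_cutoff(numeric(5), non, dir, tgt)
    expect_equal(rule$threshold, oracle_cutoff(non, dir, tgt),
                 label = sprintf("rep %d (%s, target %.2f)", rep, dir, tgt))
    expect_gte(rule$achieved_specificity, tgt)
  }
})

test_that("degenerate and undersized derivation samples are handled", {
  expect_error(derive_cutoff(1:10, c(1, 2, 3, 4), "high_is_positive"),
               "at least 5")
  r <- derive_cutoff(1:10, rep(7, 8), "high_is_positive")
  expect_true(r$degenerate)
})

test_that("binarize_and_compose applies the published missing/tie rules", {
  co <- simulate_biomarker_table(simulation_spec(seed = 23))
  rules <- derive_cutoffs(co)
  bm <- co[1, biomarker_names()]
  # all six missing -> frequency 0, negative
  allna <- bm; allna[1, ] <- NA_real_
  res <- binarize_and_compose(allna, rules)
  expect_equal(res$frequency, 0L)
  expect_false(res$positive)
  # exactly one marker beyond threshold -> frequency 1, positive
  one <- allna
  one$nonsocial_preference_pct <-
    rules$nonsocial_preference_pct$threshold + 1
  res1 <- binarize_and_compose(one, rules)
  expect_equal(res1$frequency, 1L)
  expect_true(res1$positive)
  # a value exactly at the threshold does not exceed it
  tie <- allna
  tie$nonsocial_preference_pct <- rules$nonsocial_preference_pct$threshold
  expect_equal(binarize_and_compose(tie, rules)$frequency, 0L)
  tie2 <- allna
  tie2$plr_latency_ms <- rules$plr_latency_ms$threshold
  expect_equal(binarize_and_compose(tie2, rules)$frequency, 0L)
  # frequency is always the flag sum; positive iff frequency >= 1
  full <- binarize_and_compose(co, rules)
  flags <- as.matrix(full[, grep("^flag_", names(full))])
  expect_equal(full$frequency, as.integer(rowSums(flags)))
  expect_equal(full$positive, full$frequency >= 1L)
})

test_that("every derived rule achieves its target specificity in-sample", {
  for (seed in c(7, 8, 9)) {
    co <- simulate_biomarker_table(simulation_spec(seed = seed))
    rules <- derive_cutoffs(co)
    non <- co[co$group == "nonautism", ]
    for (r in rules) {
      flags <- apply_cutoff(r, non[[r$biomarker_name]])
      obs <- !is.na(non[[r$biomarker_name]])
      expect_gte(mean(1 - flags[obs]), 0.95)
      expect_gte(r$achieved_specificity, 0.95)
    }
  }
})

test_that("composite union bounds individual-marker accuracy", {
  co <- simulate_biomarker_table(simulation_spec(seed = 37))
  res <- composite_accuracy(co)
  aut <- co$group == "autism"
  flags <- as.matrix(res$composite[, grep("^flag_",
                                          names(res$composite))])
  sens_marker <- colMeans(flags[aut, , drop = FALSE])
  spec_marker <- colMeans(1 - flags[!aut, , drop = FALSE])
  expect_gte(res$stats$sensitivity, max(sens_marker))
  expect_lte(res$stats$specificity, min(spec_marker))
})

test_that("composite specificity on a large cohort matches independence", {
  # six independent markers cut at ~95% specificity with missingness m:
  # expected composite specificity ~ (1 - 0.05 (1 - m))^6
  m <- 0.2
  co <- simulate_biomarker_table(simulation_spec(
    n_autism = 200, n_nonautism = 4000, missingness_rate_per_task = m,
    seed = 41))
  res <- composite_accuracy(co)
  expected <- (1 - 0.05 * (1 - m))^6
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(res$stats$specificity - expected), 4 * se + 0.01)
  # and the all-in no-missingness version brackets 0.95^6 ~ 0.735,
  # consistent with the observed 77.3%
  co2 <- simulate_biomarker_table(simulation_spec(
    n_autism = 200, n_nonautism = 4000, missingness_rate_per_task = 0,
    seed = 43))
  res2 <- composite_accuracy(co2)
  expect_lt(abs(res2$stats$specificity - 0.95^6), 0.03)
})

test_that("accuracy_stats equals a brute-force recount from labels", {
  set.seed(3)
  pred <- runif(300) < 0.4
  ref <- runif(300) < 0.6
  st <- accuracy_stats(confusion_2x2(pred, ref))
  expect_equal(st$table$tp, sum(pred & ref))
  expect_equal(st$sensitivity, sum(pred & ref) / sum(ref))
  expect_equal(st$specificity, sum(!pred & !ref) / sum(!ref))
  expect_equal(st$ppv, sum(pred & ref) / sum(pred))
  expect_equal(st$npv, sum(!pred & !ref) / sum(!pred))
  expect_equal(st$concordant, sum(pred == ref))
})

test_that("kappa is 1 for perfect tables and 0 at independence", {
  perfect <- accuracy_stats(tp = 30, fp = 0, fn = 0, tn = 20)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$sensitivity, 1)
  # independence with matching margins: counts n p q etc.
  indep <- accuracy_stats(tp = 24, fp = 16, fn = 36, tn = 24)
  expect_equal(indep$kappa, 0)
})

test_that("Wilson intervals match prop.test and the degenerate corner", {
  for (case in list(c(79, 102), c(34, 44), c(5, 10), c(199, 200))) {
    w <- wilson_ci(case[1], case[2])
    pt <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(w, as.numeric(pt), tolerance = 1e-9,
                 label = paste(case, collapse = "/"))
  }
  expect_equal(wilson_ci(0, 10)[1], 0)
  expect_equal(wilson_ci(10, 10)[2], 1)
  # Clopper-Pearson alternative differs and is available by flag
  cp <- accuracy_stats(tp = 79, fp = 10, fn = 23, tn = 34,
                       ci_method = "clopper-pearson")
  expect_false(isTRUE(all.equal(cp$sensitivity_ci,
                                wilson_ci(79, 102))))
})
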
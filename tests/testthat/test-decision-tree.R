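# CART fitting, the published tree, three-way evaluation, cross-validation.

# Deterministic generative data: labels assigned BY a known 3-split tree
# over (positive, frequency, eae_dx).
make_generative_cases <- function(n = 400, noise = 0, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    positive = runif(n) < 0.55,
    frequency = sample(0:6, n, replace = TRUE),
    eae_dx = sample(c("autism", "nonautism"), n, TRUE),
    certainty = sample(c("certain", "uncertain"), n, TRUE))
  truth <- ifelse(!d$positive, "nonautism",
                  ifelse(d$frequency > 1, "autism",
                         ifelse(d$eae_dx == "autism", "autism",
                                "nonautism")))
  flip <- runif(n) < noise
  d$group <- ifelse(flip, ifelse(truth == "autism", "nonautism", "autism"),
                    truth)
  d
}

features <- c("positive", "frequency", "eae_dx", "certainty")

test_that("fit_cart recovers the exact generative 3-split structure", {
  d <- make_generative_cases(400)
  fit <- fit_cart(d, "group", features, max_splits = 5)
  expect_equal(fit$n_splits, 3L)
  splits <- Filter(Negate(is.null),
                   lapply(fit$nodes, function(nd) nd$split$label))
  expect_setequal(unlist(splits),
                  c("positive<=0", "frequency<=1", "eae_dx=autism"))
  # root split is on the composite, and leaves are pure
  expect_equal(fit$nodes[[1]]$split$variable, "positive")
  for (nd in fit$nodes) if (nd$terminal)
    expect_true(min(nd$counts) == 0)
})

test_that("a useless feature yields a root-only tree", {
  set.seed(6)
  d <- data.frame(group = sample(c("autism", "nonautism"), 1000, TRUE),
                  x = rnorm(1000))
  fit <- fit_cart(d, "group", "x", max_splits = 5)
  expect_equal(fit$n_splits, 0L)
  expect_true(fit$nodes[[1]]$terminal)
  # degenerate single-class input also gives a root-only tree
  d1 <- data.frame(group = rep("autism", 50), x = rnorm(50))
  expect_equal(fit_cart(d1, "group", "x")$n_splits, 0L)
})

test_that("accepted splits have positive gain and leaves = splits + 1", {
  d <- make_generative_cases(300, noise = 0.15, seed = 3)
  fit <- fit_cart(d, "group", features, max_splits = 5)
  n_term <- sum(vapply(fit$nodes, `[[`, TRUE, "terminal"))
  expect_equal(n_term, fit$n_splits + 1L)
  for (nd in fit$nodes) if (!nd$terminal) {
    kids <- nd$children
    expect_equal(nd$counts,
                 fit$nodes[[kids[1]]]$counts + fit$nodes[[kids[2]]]$counts)
    expect_gt(nd$split$gain, 0)
  }
})

test_that("fit_cart agrees with rpart on clean generative data", {
  skip_if_not_installed("rpart")
  d <- make_generative_cases(600, noise = 0.05, seed = 9)
  fit <- fit_cart(d, "group", features, max_splits = 5)
  rp <- rpart::rpart(group ~ positive + frequency + eae_dx + certainty,
                     data = d, method = "class",
                     control = rpart::rpart.control(minsplit = 10,
                                                    cp = 0.01))
  # both select the composite indicator as the first split variable
  expect_equal(fit$nodes[[1]]$split$variable,
               as.character(rp$frame$var[1]))
})

test_that("the published tree stores the printed node counts", {
  pt <- published_tree()
  expect_equal(pt$nodes[[1]]$counts, c(autism = 102L, nonautism = 44L))
  expect_equal(pt$nodes[[6]]$counts, c(autism = 57L, nonautism = 0L))
  expect_equal(pt$nodes[[12]]$counts, c(autism = 9L, nonautism = 1L))
  expect_equal(pt$nodes[[13]]$counts, c(autism = 3L, nonautism = 9L))
  expect_equal(pt$nodes[[5]]$counts, c(autism = 9L, nonautism = 26L))
  # parent counts are the sum of their children's
  for (nd in pt$nodes) if (!nd$terminal)
    expect_equal(nd$counts, pt$nodes[[nd$children[1]]]$counts +
                   pt$nodes[[nd$children[2]]]$counts)
  # policy: diagnose 6, 9, 10, 12; rule out 5; refer 8, 13
  expect_equal(sort(names(pt$policy[pt$policy == "autism"])),
               c("10", "12", "6", "9"))
  expect_equal(names(pt$policy[pt$policy == "nonautism"]), "5")
  expect_equal(sort(names(pt$policy[pt$policy == "refer"])), c("13", "8"))
})

test_that("the published decision mapping reproduces all accuracy indices", {
  ev <- evaluate_decided(published_tree())
  expect_equal(ev$table$tp, 88L)
  expect_equal(ev$table$fp, 4L)
  expect_equal(ev$table$fn, 9L)
  expect_equal(ev$table$tn, 26L)
  expect_equal(ev$referred, 19L)
  expect_equal(ev$n, 127L)
  expect_equal(round(100 * ev$sensitivity, 1), 90.7)
  expect_equal(round(100 * ev$specificity, 1), 86.7)
  expect_equal(round(100 * ev$ppv, 1), 95.7)
  expect_equal(round(100 * ev$npv, 1), 74.3)
  expect_equal(ev$concordant, 114L)
  expect_equal(round(ev$kappa, 2), 0.73)
  # cross-check PPV/NPV as printed fractions 88/92 and 26/35
  expect_equal(ev$ppv, 88 / 92)
  expect_equal(ev$npv, 26 / 35)
})

test_that("routing sends each case to exactly one terminal", {
  pt <- published_tree()
  d <- make_generative_cases(200, noise = 0.2, seed = 5)
  pred <- predict(pt, d)
  term <- which(vapply(pt$nodes, `[[`, TRUE, "terminal"))
  expect_true(all(pred$node_id %in% term))
  expect_equal(length(pred$node_id), 200L)
  # decided + referred = total
  ev <- evaluate_decided(pt, d)
  expect_equal(ev$n + ev$referred, 200L)
  # hand-routed case: biomarker-positive, EAE autism -> node 6, diagnose
  case <- data.frame(positive = TRUE, frequency = 2, eae_dx = "autism",
                     certainty = "certain", group = "autism")
  expect_equal(predict(pt, case)$node_id, 6L)
  expect_equal(predict(pt, case)$decision, "autism")
  # biomarker-negative, EAE nonautism -> node 5, rule out
  case$positive <- FALSE; case$eae_dx <- "nonautism"
  expect_equal(predict(pt, case)$node_id, 5L)
})

test_that("policies are total and degenerate policies are handled", {
  d <- make_generative_cases(100, seed = 11)
  fit <- fit_cart(d, "group", features)
  term <- which(vapply(fit$nodes, `[[`, TRUE, "terminal"))
  expect_error(set_decision_policy(fit, c(`1` = "autism")), "terminal")
  all_refer <- stats::setNames(rep("refer", length(term)), term)
  fit2 <- set_decision_policy(fit, all_refer)
  expect_null(evaluate_decided(fit2, d))
  majority <- stats::setNames(rep("autism", length(term)), term)
  ev <- evaluate_decided(set_decision_policy(fit, majority), d)
  expect_equal(ev$n, 100L)
  expect_equal(ev$referred, 0L)
})

test_that("the composite is the first split on study-condition cohorts", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_biomarker_table(simulation_spec(seed = 5000 + s))
    res <- composite_accuracy(co)
    cases <- data.frame(group = co$group, eae_dx = co$eae_dx,
                        certainty = co$certainty,
                        positive = res$composite$positive,
                        frequency = res$composite$frequency)
    fit <- fit_cart(cases, "group", features)
    fit$n_splits >= 1 && fit$nodes[[1]]$split$variable == "positive"
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("cross-validation is stable on noiseless generative data", {
  d <- make_generative_cases(500, noise = 0, seed = 13)
  cv <- cross_validate(d, "group", features, k = 5, seed = 2)
  expect_equal(cv$modal_count, 5L)
  expect_equal(cv$mean_valid_auc, 1)
  expect_true(all(cv$per_fold$train_auc == 1))
})

test_that("cross-validated AUC tracks training AUC on noisy cohorts", {
  d <- make_generative_cases(400, noise = 0.15, seed = 17)
  cv <- cross_validate(d, "group", features, k = 5, seed = 3)
  expect_lt(abs(cv$mean_train_auc - cv$mean_valid_auc), 0.08)
  expect_true(all(cv$per_fold$valid_auc > 0.5))
})

test_that("shuffled labels give chance-level validation AUC", {
  d <- make_generative_cases(400, noise = 0.1, seed = 19)
  set.seed(23)
  d$group <- sample(d$group)
  cv <- cross_validate(d, "group", features, k = 5, seed = 4)
  expect_lt(abs(cv$mean_valid_auc - 0.5), 0.12)
})

test_that("tree JSON serialization round-trips node structure", {
  pt <- published_tree()
  path <- tempfile(fileext = ".json")
  write_tree_json(pt, path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(length(js$nodes), 13L)
  expect_equal(js$nodes[[6]]$counts$autism, 57L)
  expect_equal(js$nodes[[6]]$decision, "autism")
  expect_equal(js$nodes[[1]]$split$variable, "positive")
})
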
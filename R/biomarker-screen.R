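# Stage-1 statistics: univariate / covariate-adjusted logistic screening of
# each biomarker against the reference diagnosis, ROC/AUC, and
# Bonferroni-corrected correlations with standardized clinical measures.

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' AUC computed as the Mann-Whitney concordance probability: the probability
#' that a randomly chosen case scores higher than a randomly chosen control,
#' with half credit for ties. Pairs with a missing score are dropped.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Case indicator (logical, or coercible 0/1).
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary logistic screening of a biomarker
#'
#' Maximum-likelihood logistic regression of the reference diagnosis on one
#' biomarker, optionally adjusted for covariates (age in years, sex).
#' Reports, per predictor: the coefficient, odds ratio per unit of the
#' biomarker's native scale with Wald 95% CI, Wald chi-square
#' `(slope / SE)^2` and its two-sided p value, and the AUC of the fitted
#' scores. Complete-case: rows with a missing predictor or outcome are
#' dropped. Non-convergence or (quasi-)complete separation is flagged, never
#' silently returned.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome Name of the binary outcome column (logical, 0/1, or a
#'   factor/character whose `positive` level is the event).
#' @param predictor Name of the biomarker column.
#' @param covariates Optional character vector of covariate columns.
#' @param positive Level of `outcome` treated as the event (default
#'   `"autism"` for character/factor outcomes).
#' @return Object of class `logistic_fit`: `coefficients` table (one row per
#'   term with `estimate`, `se`, `or`, `or_lo`, `or_hi`, `wald_chi2`,
#'   `p_value`), `auc`, `n`, `converged`, `separation`, `flagged`.
#' @export
fit_logistic <- function(data, outcome, predictor,
                         covariates = character(0), positive = "autism") {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            predictor %in% names(data), all(covariates %in% names(data)))
  vars <- c(outcome, predictor, covariates)
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  y <- d[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.character(y) == positive
  y <- as.logical(y)
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need at least 2 observations in each outcome class", call. = FALSE)
  for (v in c(predictor, covariates)) {
    col <- d[[v]]
    if (is.numeric(col) && stats::var(col) == 0)
      stop("predictor `", v, "` is constant", call. = FALSE)
  }
  d$.y <- y
  form <- stats::reformulate(c(predictor, covariates), response = ".y")
  warn_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warn_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  wald <- (est / se)^2
  coefs <- data.frame(term = rownames(sm), estimate = est, se = se,
                      or = exp(est),
                      or_lo = exp(est - 1.96 * se),
                      or_hi = exp(est + 1.96 * se),
                      wald_chi2 = wald,
                      p_value = stats::pchisq(wald, 1, lower.tail = FALSE),
                      row.names = NULL)
  separation <- warn_sep || any(abs(est[-1]) > 15)
  structure(list(coefficients = coefs,
                 auc = roc_auc(stats::fitted(fit), y),
                 n = nrow(d), n_cases = sum(y),
                 converged = fit$converged,
                 separation = separation,
                 flagged = separation || !fit$converged,
                 outcome = outcome, predictor = predictor,
                 covariates = covariates),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic screen: %s ~ %s%s  (n = %d, %d cases)\n",
              x$outcome, x$predictor,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + ")) else "",
              x$n, x$n_cases))
  if (x$flagged)
    cat("  ** flagged:", if (!x$converged) "non-convergence"
        else "possible separation", "**\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat(sprintf("  model AUC = %.3f\n", x$auc))
  invisible(x)
}

#' Screen every biomarker against the reference diagnosis
#'
#' Runs [fit_logistic()] for each biomarker, unadjusted and adjusted for the
#' given covariates, and assembles a screening table (one row per biomarker)
#' with group means/SDs, odds ratios, Wald statistics, p values and AUCs.
#'
#' @param cohort Cohort data.frame with a `group` column and biomarker
#'   columns.
#' @param markers Biomarker columns to screen.
#' @param covariates Covariates for the adjusted models (default age and
#'   sex when present).
#' @return data.frame of class `screen_table`, one row per biomarker, with
#'   the per-fit list stored in attribute `"fits"`.
#' @export
screen_biomarkers <- function(cohort, markers = biomarker_names(),
                              covariates = intersect(c("age_months", "sex"),
                                                     names(cohort))) {
  stopifnot("group" %in% names(cohort))
  fits <- list()
  rows <- lapply(markers, function(m) {
    un <- fit_logistic(cohort, "group", m)
    ad <- tryCatch(fit_logistic(cohort, "group", m, covariates),
                   error = function(e) NULL)
    fits[[m]] <<- list(unadjusted = un, adjusted = ad)
    a <- cohort[cohort$group == "autism", m]
    nn <- cohort[cohort$group == "nonautism", m]
    cu <- un$coefficients[un$coefficients$term == m, ]
    ca <- if (!is.null(ad)) ad$coefficients[ad$coefficients$term == m, ]
    data.frame(biomarker = m,
               autism_mean = mean(a, na.rm = TRUE),
               autism_sd = stats::sd(a, na.rm = TRUE),
               nonautism_mean = mean(nn, na.rm = TRUE),
               nonautism_sd = stats::sd(nn, na.rm = TRUE),
               or = cu$or, or_lo = cu$or_lo, or_hi = cu$or_hi,
               wald_chi2 = cu$wald_chi2, p_value = cu$p_value,
               auc = roc_auc(if (biomarker_directions()[m] ==
                                   "low_is_positive") -cohort[[m]]
                             else cohort[[m]],
                             cohort$group == "autism"),
               adj_or = if (is.null(ca)) NA_real_ else ca$or,
               adj_p_value = if (is.null(ca)) NA_real_ else ca$p_value,
               n = un$n, flagged = un$flagged)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Pearson correlations between biomarkers and clinical measures
#'
#' Pearson r with Fisher-z 95% CI for each (biomarker, clinical measure)
#' pair, flagged for significance at the Bonferroni-adjusted threshold
#' alpha / (number of clinical measures) — .05 / 3 = .0167 for the standard
#' three measures (autism symptom severity, adaptive behavior composite,
#' early learning composite). The n used is reported alongside every r.
#'
#' @param data data.frame containing the columns.
#' @param biomarkers Character vector of biomarker columns.
#' @param clinical Character vector of clinical-score columns.
#' @param alpha Familywise error rate before Bonferroni division.
#' @return data.frame with one row per pair: `biomarker`, `clinical`, `n`,
#'   `r`, `ci_lo`, `ci_hi`, `p_value`, `significant_after_bonferroni`,
#'   `alpha_adjusted`. Pairs with fewer than 4 complete observations get NA
#'   statistics.
#' @export
clinical_correlations <- function(data, biomarkers, clinical,
                                  alpha = 0.05) {
  stopifnot(all(c(biomarkers, clinical) %in% names(data)))
  alpha_adj <- alpha / length(clinical)
  rows <- list()
  for (b in biomarkers) for (cl in clinical) {
    ok <- stats::complete.cases(data[c(b, cl)])
    n <- sum(ok)
    if (n < 4) {
      rows[[length(rows) + 1L]] <- data.frame(
        biomarker = b, clinical = cl, n = n, r = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, p_value = NA_real_,
        significant_after_bonferroni = NA, alpha_adjusted = alpha_adj)
      next
    }
    ct <- stats::cor.test(data[[b]][ok], data[[cl]][ok], method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      biomarker = b, clinical = cl, n = n, r = unname(ct$estimate),
      ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
      p_value = ct$p.value,
      significant_after_bonferroni = ct$p.value < alpha_adj,
      alpha_adjusted = alpha_adj)
  }
  do.call(rbind, rows)
}
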
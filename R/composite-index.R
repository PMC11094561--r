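# Stage-2: direction-aware cut points at fixed 95% specificity, per-marker
# binarization, the any-positive composite index with biomarker frequency,
# and diagnostic-accuracy statistics (Wilson intervals, Cohen's kappa).

#' Derive a fixed-specificity cutoff for one biomarker
#'
#' The threshold is the least extreme value such that the fraction of
#' nonautism (derivation-sample) values strictly on the positive side is at
#' most `1 - target_specificity`; equivalently the
#' `ceiling(n * target_specificity)`-th order statistic from the negative
#' side. Exceedance is strict, so the achieved specificity on the
#' derivation sample is always at least the target.
#'
#' @param values_autism,values_nonautism Biomarker values per group (NAs
#'   dropped); the nonautism values are the derivation sample.
#' @param direction `"high_is_positive"` or `"low_is_positive"`.
#' @param target_specificity Target specificity in (0, 1].
#' @param biomarker_name Optional label carried in the rule.
#' @return Object of class `cutoff_rule`: `biomarker_name`, `direction`,
#'   `threshold`, `achieved_specificity`, `n_nonautism`, `degenerate`
#'   (TRUE when every nonautism value is identical).
#' @export
derive_cutoff <- function(values_autism, values_nonautism,
                          direction = c("high_is_positive",
                                        "low_is_positive"),
                          target_specificity = 0.95,
                          biomarker_name = NA_character_) {
  direction <- match.arg(direction)
  stopifnot(target_specificity > 0, target_specificity <= 1)
  non <- values_nonautism[!is.na(values_nonautism)]
  if (length(non) < 5)
    stop("need at least 5 nonautism values to derive a cutoff",
         call. = FALSE)
  n <- length(non)
  k <- ceiling(n * target_specificity)
  srt <- sort(non)
  if (direction == "high_is_positive") {
    threshold <- srt[k]
    achieved <- mean(non <= threshold)
  } else {
    threshold <- srt[n - k + 1L]
    achieved <- mean(non >= threshold)
  }
  structure(list(biomarker_name = biomarker_name, direction = direction,
                 threshold = threshold, achieved_specificity = achieved,
                 target_specificity = target_specificity,
                 n_nonautism = n,
                 degenerate = length(unique(non)) == 1L),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("Cutoff [%s]: positive if %s %.4g (achieved specificity %.3f, n = %d)%s\n",
              x$biomarker_name,
              if (x$direction == "high_is_positive") ">" else "<",
              x$threshold, x$achieved_specificity, x$n_nonautism,
              if (x$degenerate) "  ** degenerate **" else ""))
  invisible(x)
}

#' Apply a cutoff rule to values
#' @param rule A [derive_cutoff()] rule.
#' @param values Numeric values (NA allowed).
#' @return Integer flags: 1 = strictly beyond threshold, 0 otherwise
#'   (missing values are 0: a child without usable data is assumed not to
#'   have exceeded the cutoff).
#' @export
apply_cutoff <- function(rule, values) {
  stopifnot(inherits(rule, "cutoff_rule"))
  pos <- if (rule$direction == "high_is_positive") values > rule$threshold
         else values < rule$threshold
  as.integer(ifelse(is.na(pos), FALSE, pos))
}

#' Derive cutoffs for all six biomarkers of a cohort
#'
#' @param cohort Cohort data.frame with a `group` column.
#' @param markers Biomarker columns.
#' @param directions Named direction vector (see [biomarker_directions()]).
#' @param target_specificity Target specificity.
#' @return Named list of [derive_cutoff()] rules, class `cutoff_rules`.
#' @export
derive_cutoffs <- function(cohort, markers = biomarker_names(),
                           directions = biomarker_directions(),
                           target_specificity = 0.95) {
  stopifnot("group" %in% names(cohort), all(markers %in% names(cohort)))
  rules <- lapply(markers, function(m) {
    derive_cutoff(cohort[cohort$group == "autism", m],
                  cohort[cohort$group == "nonautism", m],
                  directions[[m]], target_specificity, biomarker_name = m)
  })
  names(rules) <- markers
  structure(rules, class = c("cutoff_rules", "list"))
}

#' @export
print.cutoff_rules <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Binarize biomarkers and build the any-positive composite index
#'
#' Applies each rule to its biomarker, producing per-marker binary flags, the
#' biomarker frequency (sum of flags, 0-6), and the composite index:
#' positive if and only if any marker strictly exceeds its cutoff. Missing
#' markers contribute 0 (missing data are not imputed; a child with no
#' usable data for a task is assumed not to have exceeded that cutoff).
#'
#' @param biomarkers data.frame of biomarker values (one row per child).
#' @param rules A `cutoff_rules` list covering the biomarker columns.
#' @return data.frame with one row per child: `flag_<marker>` columns,
#'   `frequency`, and logical `positive`.
#' @export
binarize_and_compose <- function(biomarkers, rules) {
  stopifnot(is.data.frame(biomarkers))
  nm <- vapply(rules, `[[`, "", "biomarker_name")
  if (anyNA(nm) || !all(nm %in% names(biomarkers)))
    stop("every rule must name a biomarker column present in the data",
         call. = FALSE)
  flags <- sapply(rules, function(r)
    apply_cutoff(r, biomarkers[[r$biomarker_name]]))
  flags <- matrix(flags, nrow = nrow(biomarkers),
                  dimnames = list(NULL, paste0("flag_", nm)))
  frequency <- as.integer(rowSums(flags))
  out <- data.frame(flags, frequency = frequency,
                    positive = frequency >= 1L)
  out
}

#' 2x2 confusion table from index and reference labels
#'
#' @param predicted_positive Logical index-positive indicator.
#' @param reference_positive Logical reference (autism) indicator.
#' @return Object of class `confusion_2x2` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_2x2 <- function(predicted_positive, reference_positive) {
  p <- as.logical(predicted_positive); r <- as.logical(reference_positive)
  stopifnot(length(p) == length(r), !anyNA(p), !anyNA(r))
  structure(list(tp = sum(p & r), fp = sum(p & !r),
                 fn = sum(!p & r), tn = sum(!p & !r)),
            class = "confusion_2x2")
}

#' Wilson score confidence interval for a proportion
#'
#' @param successes,n Counts, `0 <= successes <= n`.
#' @param level Confidence level.
#' @return Numeric `c(lo, hi)` (fractions), or NAs when `n = 0`.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(successes >= 0, successes <= n)
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

clopper_pearson_ci <- function(successes, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(successes, n,
                               conf.level = level)$conf.int)
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement for a 2x2 table, with the large-sample CI
#' `kappa +/- z * sqrt(p0 (1 - p0) / (n (1 - pe)^2))`.
#'
#' @param table A [confusion_2x2()].
#' @param level Confidence level.
#' @return List with `kappa`, `ci_lo`, `ci_hi`, `p0`, `pe`.
#' @export
cohen_kappa <- function(table, level = 0.95) {
  stopifnot(inherits(table, "confusion_2x2"))
  n <- with(table, tp + fp + fn + tn)
  if (n == 0) return(list(kappa = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, p0 = NA_real_, pe = NA_real_))
  p0 <- with(table, (tp + tn) / n)
  pe <- with(table, ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2)
  kappa <- (p0 - pe) / (1 - pe)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p0 * (1 - p0) / (n * (1 - pe)^2))
  list(kappa = kappa, ci_lo = kappa - z * se, ci_hi = kappa + z * se,
       p0 = p0, pe = pe)
}

#' Diagnostic-accuracy statistics for a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, each with a Wilson score 95% CI (Clopper-Pearson
#' available via `ci_method`), plus Cohen's kappa with its asymptotic CI,
#' the concordant count `tp + tn`, total `n`, and the number of referred
#' (undecided) cases excluded from the table.
#'
#' @param table A [confusion_2x2()] (or `tp`, `fp`, `fn`, `tn` given
#'   directly).
#' @param tp,fp,fn,tn Counts, used when `table` is missing.
#' @param referred Cases excluded from the table by a "refer" decision.
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @param level Confidence level.
#' @return Object of class `accuracy_stats`: a list with `sensitivity`,
#'   `specificity`, `ppv`, `npv` (fractions, each with `*_ci` bounds),
#'   `kappa`, `kappa_ci`, `concordant`, `n`, `referred`, and the table.
#' @export
accuracy_stats <- function(table = NULL, tp = NULL, fp = NULL, fn = NULL,
                           tn = NULL, referred = 0L,
                           ci_method = c("wilson", "clopper-pearson"),
                           level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (is.null(table)) {
    stopifnot(!is.null(tp), !is.null(fp), !is.null(fn), !is.null(tn))
    table <- structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
                       class = "confusion_2x2")
  }
  stopifnot(inherits(table, "confusion_2x2"))
  ci_fun <- if (ci_method == "wilson") wilson_ci else clopper_pearson_ci
  idx <- function(x, m) {
    if (m == 0) return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    list(est = x / m, ci = ci_fun(x, m, level))
  }
  sens <- with(table, idx(tp, tp + fn))
  spec <- with(table, idx(tn, tn + fp))
  ppv <- with(table, idx(tp, tp + fp))
  npv <- with(table, idx(tn, tn + fn))
  kap <- cohen_kappa(table, level)
  n <- with(table, tp + fp + fn + tn)
  structure(list(table = table,
                 sensitivity = sens$est, sensitivity_ci = sens$ci,
                 specificity = spec$est, specificity_ci = spec$ci,
                 ppv = ppv$est, ppv_ci = ppv$ci,
                 npv = npv$est, npv_ci = npv$ci,
                 kappa = kap$kappa, kappa_ci = c(kap$ci_lo, kap$ci_hi),
                 concordant = with(table, tp + tn), n = n,
                 referred = as.integer(referred),
                 ci_method = ci_method, level = level),
            class = "accuracy_stats")
}

#' @export
print.accuracy_stats <- function(x, ...) {
  pct <- function(est, ci) sprintf("%.1f%% (%.1f%%-%.1f%%)", 100 * est,
                                   100 * ci[1], 100 * ci[2])
  with(x$table, cat(sprintf(
    "Confusion: TP=%d FP=%d FN=%d TN=%d (n=%d decided, %d referred)\n",
    tp, fp, fn, tn, x$n, x$referred)))
  cat("  Sensitivity:", pct(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  Specificity:", pct(x$specificity, x$specificity_ci), "\n")
  cat("  PPV:        ", pct(x$ppv, x$ppv_ci), "\n")
  cat("  NPV:        ", pct(x$npv, x$npv_ci), "\n")
  cat(sprintf("  Kappa:       %.2f (%.2f-%.2f)\n", x$kappa, x$kappa_ci[1],
              x$kappa_ci[2]))
  cat(sprintf("  Concordant:  %d of %d (%.0f%%)\n", x$concordant, x$n,
              100 * x$concordant / x$n))
  invisible(x)
}

#' Evaluate the composite index of a cohort against reference diagnosis
#'
#' Convenience wrapper: derive cutoffs on the cohort, binarize and compose,
#' and compute accuracy statistics of the composite index against the
#' reference group label.
#'
#' @param cohort Cohort data.frame (`group` plus biomarker columns).
#' @param rules Optional pre-derived `cutoff_rules` (derived on `cohort`
#'   when omitted — the full-sample derivation used in the primary
#'   analysis).
#' @param target_specificity Target specificity for derived rules.
#' @return List with `rules`, `composite` (per-child flags/frequency/
#'   positive), and `stats` (an [accuracy_stats()]).
#' @export
composite_accuracy <- function(cohort, rules = NULL,
                               target_specificity = 0.95) {
  if (is.null(rules)) rules <- derive_cutoffs(
    cohort, target_specificity = target_specificity)
  comp <- binarize_and_compose(cohort, rules)
  stats <- accuracy_stats(confusion_2x2(comp$positive,
                                        cohort$group == "autism"))
  list(rules = rules, composite = comp, stats = stats)
}
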
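# Synthetic cohort generation: biomarker tables, practitioner labels and raw
# gaze/pupil streams with known ground truth, so that every downstream stage
# (event detection, paradigm metrics, screening, composite index, decision
# tree) can be exercised and validated without access to participant data.

#' Names of the six candidate diagnostic biomarkers
#'
#' The six gaze/pupil indices carried through cutoff derivation and the
#' composite index: nonsocial preference (% looking to the nonsocial video),
#' no-shift gap effect (overlap minus gap difference in no-shift trial
#' percentage), resting and exploration mean fixation durations (ms),
#' pupillary light reflex latency (ms) and amplitude (%).
#'
#' @return Character vector of length six.
#' @export
biomarker_names <- function() {
  c("nonsocial_preference_pct",
    "no_shift_gap_effect_pct",
    "resting_fixation_duration_ms",
    "plr_latency_ms",
    "plr_amplitude_pct",
    "exploration_fixation_duration_ms")
}

#' Auxiliary oculomotor/pupil metrics carried alongside the six biomarkers
#' @return Character vector.
#' @export
auxiliary_metric_names <- function() {
  c("overlap_gap_rt_ms", "tonic_pupil_mm",
    "saccade_amplitude_deg", "saccade_duration_ms")
}

#' Positive direction of each biomarker
#'
#' Direction in which a value counts toward autism: `"high_is_positive"` for
#' all markers except pupillary light reflex latency, which is shorter in the
#' autism group (`"low_is_positive"`).
#'
#' @return Named character vector over [biomarker_names()].
#' @export
biomarker_directions <- function() {
  d <- rep("high_is_positive", 6L)
  names(d) <- biomarker_names()
  d["plr_latency_ms"] <- "low_is_positive"
  d
}

#' Paradigm that produces each metric
#' @return Named character vector mapping metric name to one of
#'   `"geopref"`, `"gap_overlap"`, `"plr"`, `"resting"`, `"exploration"`.
#' @export
metric_paradigms <- function() {
  c(nonsocial_preference_pct = "geopref",
    no_shift_gap_effect_pct = "gap_overlap",
    overlap_gap_rt_ms = "gap_overlap",
    plr_latency_ms = "plr",
    plr_amplitude_pct = "plr",
    resting_fixation_duration_ms = "resting",
    tonic_pupil_mm = "resting",
    saccade_amplitude_deg = "resting",
    saccade_duration_ms = "resting",
    exploration_fixation_duration_ms = "exploration")
}

paradigm_names <- function() {
  c("geopref", "gap_overlap", "plr", "resting", "exploration")
}

#' Default group-conditional biomarker distributions
#'
#' One row per (biomarker, group) giving the mean, SD and truncation range of
#' the group-conditional distribution used by [simulate_biomarker_table()].
#' The six diagnostic biomarkers use the published cohort statistics for the
#' autism (n = 102) and nonautism (n = 44) groups; the auxiliary metrics
#' (overlap-gap RT, tonic pupil, saccade amplitude/duration), which were
#' measured but not diagnostic, use plausible values consistent with the
#' developmental eye-tracking literature and are documented as assumptions.
#'
#' @return A data.frame with columns `biomarker`, `group`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
group_distributions <- function() {
  tab <- rbind(
    # six diagnostic biomarkers, cohort values
    data.frame(biomarker = "nonsocial_preference_pct",
               group = c("autism", "nonautism"),
               mean = c(46.20, 21.50), sd = c(22.33, 12.48),
               min = c(3.35, 0.62), max = c(86.80, 56.72)),
    data.frame(biomarker = "no_shift_gap_effect_pct",
               group = c("autism", "nonautism"),
               mean = c(8.65, 0.83), sd = c(13.42, 10.45),
               min = c(-25, -16.67), max = c(50, 40)),
    data.frame(biomarker = "resting_fixation_duration_ms",
               group = c("autism", "nonautism"),
               mean = c(527.84, 460.93), sd = c(135.71, 110.47),
               min = c(300, 239), max = c(966, 686)),
    data.frame(biomarker = "plr_latency_ms",
               group = c("autism", "nonautism"),
               mean = c(268.51, 291.44), sd = c(25.88, 23.62),
               min = c(207, 254), max = c(338, 353)),
    data.frame(biomarker = "plr_amplitude_pct",
               group = c("autism", "nonautism"),
               mean = c(32.69, 24.70), sd = c(10.26, 8.23),
               min = c(10.17, 11.39), max = c(57.60, 40.55)),
    data.frame(biomarker = "exploration_fixation_duration_ms",
               group = c("autism", "nonautism"),
               mean = c(344.58, 320.80), sd = c(63.10, 42.13),
               min = c(236, 232), max = c(600, 402)),
    # auxiliary metrics (assumed, not diagnostic)
    data.frame(biomarker = "overlap_gap_rt_ms",
               group = c("autism", "nonautism"),
               mean = c(120, 70), sd = c(60, 50),
               min = c(-50, -50), max = c(400, 300)),
    data.frame(biomarker = "tonic_pupil_mm",
               group = c("autism", "nonautism"),
               mean = c(4.45, 4.20), sd = c(0.55, 0.50),
               min = c(3.0, 3.0), max = c(6.5, 6.0)),
    data.frame(biomarker = "saccade_amplitude_deg",
               group = c("autism", "nonautism"),
               mean = c(5.3, 5.6), sd = c(1.1, 1.1),
               min = c(2, 2), max = c(10, 10)),
    data.frame(biomarker = "saccade_duration_ms",
               group = c("autism", "nonautism"),
               mean = c(42, 40), sd = c(8, 8),
               min = c(20, 20), max = c(80, 80))
  )
  rownames(tab) <- NULL
  tab
}

#' Construct and validate a simulation specification
#'
#' Bundles every parameter of the synthetic-cohort generator: group sizes,
#' group-conditional biomarker distributions, per-paradigm missingness, the
#' accuracy of the simulated primary-care practitioner (PCP) diagnosis and
#' the dependence of diagnostic certainty on correctness, and the seed.
#'
#' Defaults mirror the study conditions: 102 autism / 44 nonautism children,
#' published group distributions, PCP sensitivity 0.70 and specificity 0.82
#' (implied by the published decision-tree node counts), certainty more
#' likely when the PCP is correct.
#'
#' @param n_autism,n_nonautism Group sizes (non-negative integers).
#' @param distributions Distribution table as from [group_distributions()].
#' @param missingness_rate_per_task Probability that a child contributes no
#'   usable data for a given paradigm (independent across paradigms and
#'   children).
#' @param pcp_sensitivity,pcp_specificity Probability that the simulated PCP
#'   diagnosis agrees with the reference group for autism / nonautism
#'   children respectively.
#' @param p_certain_given_correct,p_certain_given_incorrect Probability of a
#'   "certain" PCP rating conditional on the PCP diagnosis being correct /
#'   incorrect.
#' @param seed Integer seed; all randomness in [simulate_biomarker_table()]
#'   flows from it.
#' @return An object of class `simulation_spec` (a validated list).
#' @export
simulation_spec <- function(n_autism = 102L,
                            n_nonautism = 44L,
                            distributions = group_distributions(),
                            missingness_rate_per_task = 0.2,
                            pcp_sensitivity = 0.70,
                            pcp_specificity = 0.82,
                            p_certain_given_correct = 0.75,
                            p_certain_given_incorrect = 0.35,
                            seed = 20240514L) {
  spec <- list(n_autism = as.integer(n_autism),
               n_nonautism = as.integer(n_nonautism),
               distributions = distributions,
               missingness_rate_per_task = missingness_rate_per_task,
               pcp_sensitivity = pcp_sensitivity,
               pcp_specificity = pcp_specificity,
               p_certain_given_correct = p_certain_given_correct,
               p_certain_given_incorrect = p_certain_given_incorrect,
               seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  validate_simulation_spec(spec)
  spec
}

validate_simulation_spec <- function(spec) {
  stopifnot(is.list(spec))
  if (length(spec$n_autism) != 1L || is.na(spec$n_autism) || spec$n_autism < 0L)
    stop("`n_autism` must be a single non-negative integer", call. = FALSE)
  if (length(spec$n_nonautism) != 1L || is.na(spec$n_nonautism) ||
      spec$n_nonautism < 0L)
    stop("`n_nonautism` must be a single non-negative integer", call. = FALSE)
  probs <- c("missingness_rate_per_task", "pcp_sensitivity", "pcp_specificity",
             "p_certain_given_correct", "p_certain_given_incorrect")
  for (p in probs) {
    v <- spec[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", p), call. = FALSE)
  }
  d <- spec$distributions
  need <- c("biomarker", "group", "mean", "sd", "min", "max")
  if (!is.data.frame(d) || !all(need %in% names(d)))
    stop("`distributions` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(d$sd < 0)) stop("distribution `sd` must be >= 0", call. = FALSE)
  if (any(d$min >= d$max)) stop("distribution `min` must be < `max`",
                                call. = FALSE)
  if (any(d$mean < d$min | d$mean > d$max))
    stop("distribution `mean` must lie within [min, max]", call. = FALSE)
  invisible(spec)
}

#' Truncated-normal random draws (rejection sampling)
#'
#' Draws from a normal distribution truncated to `[min, max]` by rejection:
#' simple and exact for the mild truncations used here (bounds bracket the
#' mean). `sd = 0` degenerates to the point mass at `mean`.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent normal.
#' @param min,max Truncation bounds.
#' @return Numeric vector of length `n`, all values in `[min, max]`.
#' @export
rtrunc_normal <- function(n, mean, sd, min = -Inf, max = Inf) {
  stopifnot(length(n) == 1L, n >= 0, sd >= 0, min < max,
            mean >= min || is.infinite(min), mean <= max || is.infinite(max))
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= min & draw <= max])
  }
  out[seq_len(n)]
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and SD of a normal(`mean`, `sd`) truncated to
#' `[min, max]`; used to state the truncation-adjusted targets that the
#' rejection sampler must reproduce.
#'
#' @inheritParams rtrunc_normal
#' @return List with elements `mean` and `sd`.
#' @export
truncnorm_moments <- function(mean, sd, min = -Inf, max = Inf) {
  if (sd == 0) return(list(mean = mean, sd = 0))
  a <- (min - mean) / sd
  b <- (max - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mean + sd * (pa - pb) / z
  aa <- if (is.infinite(a)) 0 else a * pa
  bb <- if (is.infinite(b)) 0 else b * pb
  v <- sd^2 * (1 + (aa - bb) / z - ((pa - pb) / z)^2)
  list(mean = m, sd = sqrt(v))
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a cohort biomarker table
#'
#' Draws a cohort of synthetic children: per-group biomarker values from
#' truncated normal distributions, age uniform on 14-48 months, sex with the
#' cohort's 71%/29% male/female split, PCP diagnosis and dichotomized
#' certainty via [simulate_pcp_labels()], and per-paradigm missingness
#' (missing paradigms blank every metric from that paradigm; missing data are
#' never imputed downstream). The complete latent (pre-missingness) values
#' are kept in the `"latent"` attribute so stream-rendering and round-trip
#' recovery tests have access to ground truth.
#'
#' @param spec A [simulation_spec()].
#' @return A data.frame of class `gazedx_cohort` with one row per child:
#'   `id`, `group`, `age_months`, `sex`, `eae_dx`, `certainty`, the six
#'   biomarkers and the auxiliary metrics (NA where the paradigm is missing).
#'   Attributes: `latent` (complete metric values), `missing_tasks` (logical
#'   child x paradigm matrix), `spec`.
#' @export
simulate_biomarker_table <- function(spec) {
  validate_simulation_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_autism + spec$n_nonautism
    group <- rep(c("autism", "nonautism"),
                 c(spec$n_autism, spec$n_nonautism))
    child <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      group = group,
      age_months = stats::runif(n, 14, 48),
      sex = ifelse(stats::runif(n) < 0.71, "male", "female"),
      stringsAsFactors = FALSE)

    metrics <- c(biomarker_names(), auxiliary_metric_names())
    latent <- matrix(NA_real_, n, length(metrics),
                     dimnames = list(NULL, metrics))
    d <- spec$distributions
    for (m in metrics) {
      for (g in c("autism", "nonautism")) {
        row <- d[d$biomarker == m & d$group == g, , drop = FALSE]
        if (nrow(row) != 1L)
          stop("distributions must contain exactly one row for ",
               m, " / ", g, call. = FALSE)
        idx <- which(group == g)
        latent[idx, m] <- rtrunc_normal(length(idx), row$mean, row$sd,
                                        row$min, row$max)
      }
    }

    labels <- simulate_pcp_labels(group, spec)
    child$eae_dx <- labels$eae_dx
    child$certainty <- labels$certainty

    pars <- paradigm_names()
    miss <- matrix(stats::runif(n * length(pars)) <
                     spec$missingness_rate_per_task,
                   n, length(pars), dimnames = list(NULL, pars))
    observed <- latent
    mp <- metric_paradigms()
    for (m in metrics) observed[miss[, mp[[m]]], m] <- NA_real_

    cohort <- cbind(child, as.data.frame(observed))
    class(cohort) <- c("gazedx_cohort", "data.frame")
    attr(cohort, "latent") <- as.data.frame(latent)
    attr(cohort, "missing_tasks") <- miss
    attr(cohort, "spec") <- spec
    cohort
  })
}

#' Latent (pre-missingness) metric values of a simulated cohort
#' @param cohort A `gazedx_cohort` from [simulate_biomarker_table()].
#' @return data.frame of complete metric values, one row per child.
#' @export
cohort_latent <- function(cohort) {
  lat <- attr(cohort, "latent")
  if (is.null(lat)) stop("cohort carries no latent ground truth",
                         call. = FALSE)
  lat
}

#' Simulate primary-care diagnoses and certainty ratings
#'
#' The PCP diagnosis agrees with the reference group with probability
#' `pcp_sensitivity` for autism children and `pcp_specificity` for nonautism
#' children; the dichotomized certainty rating ("certain" vs "uncertain") is
#' drawn conditional on whether the diagnosis is correct.
#'
#' Uses the current RNG state (seed it, or call from
#' [simulate_biomarker_table()], for reproducibility).
#'
#' @param groups Character vector of `"autism"` / `"nonautism"`.
#' @param spec A [simulation_spec()].
#' @return data.frame with columns `eae_dx` and `certainty`.
#' @export
simulate_pcp_labels <- function(groups, spec) {
  validate_simulation_spec(spec)
  stopifnot(all(groups %in% c("autism", "nonautism")))
  n <- length(groups)
  p_correct <- ifelse(groups == "autism", spec$pcp_sensitivity,
                      spec$pcp_specificity)
  correct <- stats::runif(n) < p_correct
  other <- ifelse(groups == "autism", "nonautism", "autism")
  eae_dx <- ifelse(correct, groups, other)
  p_cert <- ifelse(correct, spec$p_certain_given_correct,
                   spec$p_certain_given_incorrect)
  certainty <- ifelse(stats::runif(n) < p_cert, "certain", "uncertain")
  data.frame(eae_dx = eae_dx, certainty = certainty,
             stringsAsFactors = FALSE)
}

#' @export
print.gazedx_cohort <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Synthetic cohort: %d children (%d autism, %d nonautism)\n",
              n, sum(x$group == "autism"), sum(x$group == "nonautism")))
  miss <- attr(x, "missing_tasks")
  if (!is.null(miss))
    cat("Missing paradigms per task: ",
        paste(sprintf("%s %d", colnames(miss), colSums(miss)),
              collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (n > 6) cat("... ", n - 6, " more children\n", sep = "")
  invisible(x)
}
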
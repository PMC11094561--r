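# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately use the slowest,
# most literal formulation of each definition.

# AUC by exhaustive case-control pair counting with half credit for ties.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  cases <- scores[labels]
  ctrls <- scores[!labels]
  if (length(cases) == 0 || length(ctrls) == 0) return(NA_real_)
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cases) * length(ctrls))
}

# Exhaustive maximal-run I-DT: from each start, find by direct range
# recomputation the longest run satisfying the dispersion bound; emit it if
# long enough, else advance one sample. Assumes an all-valid, gap-free
# stream.
oracle_fixations <- function(tt, x, y, dispersion, min_dur) {
  n <- length(tt)
  rows <- list()
  i <- 1
  while (i <= n) {
    j_best <- i
    for (j in i:n) {
      disp <- (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
      if (disp > dispersion) break
      j_best <- j
    }
    if (tt[j_best] - tt[i] >= min_dur) {
      rows[[length(rows) + 1]] <- c(start = tt[i], end = tt[j_best],
                                    cx = mean(x[i:j_best]),
                                    cy = mean(y[i:j_best]))
      i <- j_best + 1
    } else i <- i + 1
  }
  if (length(rows) == 0) NULL else do.call(rbind, rows)
}

# Least-extreme threshold achieving the target specificity, by trying every
# candidate data value.
oracle_cutoff <- function(non, direction, target) {
  cand <- sort(unique(non))
  ok <- function(t) {
    frac_pos <- if (direction == "high_is_positive") mean(non > t)
    else mean(non < t)
    frac_pos <= 1 - target + 1e-12   # guard binary representation of 1-target
  }
  sat <- cand[vapply(cand, ok, TRUE)]
  if (direction == "high_is_positive") min(sat) else max(sat)
}

# Two-stage grid search for the logistic MLE of y ~ 1 + x (brute force over
# (intercept, slope), refined around the best cell).
oracle_logistic_mle <- function(x, y, b0_range = c(-10, 10),
                                b1_range = c(-10, 10), steps = 81L,
                                refinements = 6L) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  for (r in seq_len(refinements)) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = steps)
    b1s <- seq(b1_range[1], b1_range[2], length.out = steps)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    w0 <- diff(b0_range) / (steps - 1)
    w1 <- diff(b1_range) / (steps - 1)
    b0_range <- b0s[best[1]] + c(-2, 2) * w0
    b1_range <- b1s[best[2]] + c(-2, 2) * w1
  }
  c(intercept = mean(b0_range), slope = mean(b1_range))
}

with_seed_for_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# A fully valid gaze samples data.frame at a fixed rate.
make_samples <- function(x, y, rate = 100, pupil = 4, valid = TRUE) {
  n <- length(x)
  data.frame(time_ms = seq(0, by = 1000 / rate, length.out = n),
             x_deg = x, y_deg = y, pupil_mm = rep_len(pupil, n),
             valid = rep_len(valid, n))
}
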
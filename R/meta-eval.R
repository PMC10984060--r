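# Meta-evaluation statistics: correlations (with confidence intervals),
# the paired Wilcoxon signed-rank test, comparison of dependent
# correlations, and interrater agreement.  These are authored here in the
# exact dialects the meta-evaluation needs (tie-corrected tau-b from
# contingency counts, exact signed-rank p by a generating-function DP over
# midranks, rank-correlation CIs by seeded percentile bootstrap or
# adjusted Fisher z) and cross-checked in the test suite against
# independent oracles.

check_series <- function(x, y, min_n) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("series must have equal length")
  if (anyNA(x) || anyNA(y)) stop("series must not contain missing values")
  if (length(x) < min_n) stop("need at least ", min_n, " paired observations")
  length(x)
}

cor_result <- function(method, estimate, lo, hi, p, n, ci_method) {
  tibble::tibble(method = method, estimate = estimate,
                 ci_lower = lo, ci_upper = hi, p_value = p,
                 n = as.integer(n), ci_method = ci_method)
}

pearson_estimate <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

cor_p_from_t <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

fisher_ci <- function(r, se_z, conf_level) {
  if (is.na(r) || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tanh(c(z - q * se_z, z + q * se_z))
}

bootstrap_ci <- function(x, y, stat, n_boot, seed, conf_level) {
  n <- length(x)
  with_seed(seed, {
    vals <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      stat(x[idx], y[idx])
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2) return(c(NA_real_, NA_real_))
    a <- (1 - conf_level) / 2
    unname(stats::quantile(vals, c(a, 1 - a)))
  })
}

#' Pearson product-moment correlation with Fisher-z interval
#'
#' @param x,y Equal-length numeric series (the human score and the metric
#'   score, aligned by record).
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble: `method`, `estimate`, `ci_lower`, `ci_upper`,
#'   `p_value` (t test on `n - 2` df), `n`, `ci_method`.  Constant series
#'   yield `NA` estimates with a warning.
#' @export
pearson_r <- function(x, y, conf_level = 0.95) {
  n <- check_series(x, y, 4)
  r <- pearson_estimate(x, y)
  if (is.na(r)) {
    warning("constant series: Pearson correlation undefined")
    return(cor_result("pearson", NA_real_, NA_real_, NA_real_, NA_real_, n,
                      "fisher_z"))
  }
  ci <- fisher_ci(r, 1 / sqrt(n - 3), conf_level)
  cor_result("pearson", r, ci[1], ci[2], cor_p_from_t(r, n), n, "fisher_z")
}

spearman_estimate <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  tie_term <- function(r) {
    t <- table(r)
    sum(t^3 - t)
  }
  sx <- (n^3 - n - tie_term(rx)) / 12
  sy <- (n^3 - n - tie_term(ry)) / 12
  if (sx == 0 || sy == 0) return(NA_real_)
  (sx + sy - sum((rx - ry)^2)) / (2 * sqrt(sx * sy))
}

#' Spearman rank correlation
#'
#' Estimated by the tie-corrected closed form (equivalent to Pearson on
#' midranks).  The p-value uses the t approximation on `n - 2` df.  The
#' default interval is a seeded percentile bootstrap; `ci_method =
#' "fisher"` instead uses the Fisher z transform with the Bonett-Wright
#' adjusted standard error `sqrt((1 + rho^2/2) / (n - 3))`.
#'
#' @inheritParams pearson_r
#' @param ci_method `"bootstrap"`, `"fisher"` or `"none"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return One-row tibble as in [pearson_r()].
#' @export
spearman_rho <- function(x, y, ci_method = c("bootstrap", "fisher", "none"),
                         n_boot = 2000, seed = 1, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  n <- check_series(x, y, 4)
  rho <- spearman_estimate(x, y)
  if (is.na(rho)) {
    warning("constant series: Spearman correlation undefined")
    return(cor_result("spearman", NA_real_, NA_real_, NA_real_, NA_real_, n,
                      ci_method))
  }
  ci <- switch(ci_method,
    bootstrap = bootstrap_ci(x, y, spearman_estimate, n_boot, seed, conf_level),
    fisher = fisher_ci(rho, sqrt((1 + rho^2 / 2) / (n - 3)), conf_level),
    none = c(NA_real_, NA_real_)
  )
  cor_result("spearman", rho, ci[1], ci[2], cor_p_from_t(rho, n), n, ci_method)
}

# Concordant/discordant pair counts via the cumulative contingency table;
# works on value levels rather than enumerating the O(n^2) pairs.
tau_b_counts <- function(x, y) {
  m <- table(factor(x), factor(y))
  m <- matrix(as.numeric(m), nrow = nrow(m))
  nr <- nrow(m)
  nc <- ncol(m)
  total <- sum(m)
  if (nr == 1L || nc == 1L) {
    return(list(C = 0, D = 0, t_row = rowSums(m), t_col = colSums(m),
                n = total))
  }
  cs <- apply(m, 2, cumsum)            # cs[i, j] = sum rows <= i of col j
  csum <- t(apply(cs, 1, cumsum))      # csum[i, j] = sum rows <= i, cols <= j
  rowcum <- cumsum(rowSums(m))
  colcum <- cumsum(colSums(m))
  br <- total - matrix(rowcum, nr, nc) -
    matrix(colcum, nr, nc, byrow = TRUE) + csum
  bl <- cbind(0, matrix(colcum[-nc], nr, nc - 1L, byrow = TRUE) -
                csum[, -nc, drop = FALSE])
  list(C = sum(m * br), D = sum(m * bl),
       t_row = rowSums(m), t_col = colSums(m), n = total)
}

#' Kendall tau-b rank correlation with tie correction
#'
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' with concordant/discordant counts computed from the cumulative
#' contingency table and the usual tie terms `n_1`, `n_2`.  The p-value
#' uses the normal approximation with the tie-corrected null variance of
#' `C - D`.  Intervals as in [spearman_rho()] (Fisher variant uses the
#' Fieller-Hartley-Pearson standard error `sqrt(0.437 / (n - 4))`).
#'
#' @inheritParams spearman_rho
#' @return One-row tibble as in [pearson_r()].  All-tied series yield `NA`
#'   with a warning.
#' @export
kendall_tau_b <- function(x, y, ci_method = c("bootstrap", "fisher", "none"),
                          n_boot = 2000, seed = 1, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  n <- check_series(x, y, 3)
  est <- function(x, y) {
    ct <- tau_b_counts(x, y)
    n0 <- ct$n * (ct$n - 1) / 2
    n1 <- sum(ct$t_row * (ct$t_row - 1) / 2)
    n2 <- sum(ct$t_col * (ct$t_col - 1) / 2)
    den <- sqrt((n0 - n1) * (n0 - n2))
    if (den == 0) NA_real_ else (ct$C - ct$D) / den
  }
  tau <- est(x, y)
  if (is.na(tau)) {
    warning("constant series: Kendall tau-b undefined")
    return(cor_result("kendall", NA_real_, NA_real_, NA_real_, NA_real_, n,
                      ci_method))
  }
  ct <- tau_b_counts(x, y)
  ti <- ct$t_row
  uj <- ct$t_col
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(ti * (ti - 1) * (2 * ti + 5))
  vu <- sum(uj * (uj - 1) * (2 * uj + 5))
  v1 <- sum(ti * (ti - 1)) * sum(uj * (uj - 1)) / (2 * n * (n - 1))
  v2 <- sum(ti * (ti - 1) * (ti - 2)) * sum(uj * (uj - 1) * (uj - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v <- (v0 - vt - vu) / 18 + v1 + v2
  p <- if (v <= 0) NA_real_ else 2 * stats::pnorm(-abs((ct$C - ct$D) / sqrt(v)))
  ci <- switch(ci_method,
    bootstrap = bootstrap_ci(x, y, est, n_boot, seed, conf_level),
    fisher = if (n > 4) fisher_ci(tau, sqrt(0.437 / (n - 4)), conf_level)
             else c(NA_real_, NA_real_),
    none = c(NA_real_, NA_real_)
  )
  cor_result("kendall", tau, ci[1], ci[2], p, n, ci_method)
}

# Exact two-sided signed-rank p-value by a generating-function DP over the
# doubled midranks (doubling makes tied midranks integral).  Counts, over
# all 2^n equiprobable sign assignments, the number of subsets of ranks
# whose sum is <= / >= the observed statistic.
signed_rank_exact_p <- function(ranks, v_obs) {
  d <- as.integer(round(2 * ranks))
  total_sum <- sum(d)
  f <- numeric(total_sum + 1L)
  f[1L] <- 1
  for (dk in d) {
    if (dk > 0) {
      f[(dk + 1L):(total_sum + 1L)] <- f[(dk + 1L):(total_sum + 1L)] +
        f[1L:(total_sum + 1L - dk)]
    }
  }
  v2 <- round(2 * v_obs)
  sums <- 0:total_sum
  n_total <- 2^length(d)
  p_le <- sum(f[sums <= v2]) / n_total
  p_ge <- sum(f[sums >= v2]) / n_total
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test on paired series
#'
#' Tests the paired differences `x - y`.  Zero differences are discarded
#' (the discard convention); ranks of the absolute differences use
#' midranks.  For 12 or fewer non-zero differences the p-value is exact
#' (full enumeration of the signed-rank null via a subset-sum recursion);
#' beyond that a normal approximation with tie correction and continuity
#' correction is used.  Because many automated metrics live on arbitrary
#' (even unbounded) scales, `rescale = TRUE` min-max rescales `y` to
#' `[0, 1]` before pairing.
#'
#' @inheritParams pearson_r
#' @param rescale Min-max rescale `y` before pairing (default `FALSE`
#'   here; the report generator [correlation_table()] rescales by
#'   default).
#' @param exact_limit Largest number of non-zero differences for which the
#'   exact p-value is computed.
#' @return One-row tibble: `statistic` (V, sum of positive-difference
#'   ranks), `p_value`, `n`, `n_effective`, `method`
#'   (`"exact"`/`"normal"`/`"degenerate"`), `rescaled`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, rescale = FALSE, exact_limit = 12) {
  n <- check_series(x, y, 1)
  if (rescale) {
    rng <- range(y)
    if (rng[1] == rng[2]) {
      warning("constant metric series; rescaling maps it to 0")
      y <- rep(0, n)
    } else {
      y <- (y - rng[1]) / (rng[2] - rng[1])
    }
  }
  d <- x - y
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, n = n,
                          n_effective = 0L, method = "degenerate",
                          rescaled = rescale, degenerate = TRUE))
  }
  if (n_eff < 5) {
    warning("fewer than 5 non-zero differences; p-value has little resolution")
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n_eff <= exact_limit) {
    p <- signed_rank_exact_p(r, v)
    method <- "exact"
  } else {
    mu <- n_eff * (n_eff + 1) / 4
    ties <- table(r)
    sigma2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(statistic = v, p_value = min(1, p), n = n,
                 n_effective = as.integer(n_eff), method = method,
                 rescaled = rescale, degenerate = FALSE)
}

#' Compare two dependent, overlapping correlations
#'
#' Tests whether `cor(human, a)` differs from `cor(human, b)` when both
#' share the human series, using Steiger's z for overlapping dependent
#' correlations (Williams-type pooled estimate) by default, or a seeded
#' percentile bootstrap of the correlation difference as a cross-check.
#'
#' @param human,a,b Three aligned numeric series.
#' @param method `"steiger"` or `"bootstrap"`.
#' @param cor_method Correlation to compare: `"pearson"` or `"spearman"`
#'   (ranks are taken before correlating).
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `z` (NA for bootstrap), `p_value`, `delta`
#'   (difference of correlations), `r_human_a`, `r_human_b`, `r_ab`, `n`,
#'   `method`.
#' @export
compare_dependent_correlations <- function(human, a, b,
                                           method = c("steiger", "bootstrap"),
                                           cor_method = c("pearson", "spearman"),
                                           n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  cor_method <- match.arg(cor_method)
  n <- check_series(human, a, 10)
  check_series(human, b, 10)
  prep <- if (cor_method == "spearman") function(v) rank(v) else identity
  cc <- function(u, v) pearson_estimate(prep(u), prep(v))
  r12 <- cc(human, a)
  r13 <- cc(human, b)
  r23 <- cc(a, b)
  if (anyNA(c(r12, r13, r23))) {
    warning("constant series: dependent-correlation comparison undefined")
    return(tibble::tibble(z = NA_real_, p_value = NA_real_, delta = NA_real_,
                          r_human_a = r12, r_human_b = r13, r_ab = r23,
                          n = n, method = method))
  }
  delta <- r12 - r13
  if (method == "steiger") {
    if (delta == 0) {
      z <- 0
      p <- 1
    } else {
      # clamp away exact +/-1 so the Fisher transform stays finite
      r12c <- clamp(r12, -1 + 1e-7, 1 - 1e-7)
      r13c <- clamp(r13, -1 + 1e-7, 1 - 1e-7)
      rbar <- (r12c + r13c) / 2
      psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
      s <- psi / (1 - rbar^2)^2
      z <- (atanh(r12c) - atanh(r13c)) * sqrt((n - 3) / (2 - 2 * s))
      p <- 2 * stats::pnorm(-abs(z))
    }
    return(tibble::tibble(z = z, p_value = p, delta = delta,
                          r_human_a = r12, r_human_b = r13, r_ab = r23,
                          n = n, method = "steiger"))
  }
  deltas <- with_seed(seed, {
    vapply(seq_len(n_boot), function(k) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- cc(human[idx], a[idx]) - cc(human[idx], b[idx])
      if (is.na(d)) 0 else d
    }, numeric(1))
  })
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)) + 1 / n_boot)
  tibble::tibble(z = NA_real_, p_value = p, delta = delta,
                 r_human_a = r12, r_human_b = r13, r_ab = r23,
                 n = n, method = "bootstrap")
}

#' Cohen's kappa for interrater agreement
#'
#' `kappa = (po - pe) / (1 - pe)` with optional linear or quadratic
#' disagreement weighting over the ordered category set.  The default
#' acceptance threshold of 0.70 reflects the adjudication bar commonly
#' required before annotation proceeds.
#'
#' @param rater_a,rater_b Equal-length label vectors from a shared
#'   category set.
#' @param weights `"none"`, `"linear"` or `"quadratic"`.
#' @param categories Optional ordered category levels (defaults to the
#'   sorted union of observed labels).
#' @param threshold Pass threshold for the agreement flag.
#' @return An `agreement_report` list: `kappa`, `po`, `pe`, `weights`,
#'   `threshold`, `pass`, `n`, `degenerate`, `table`.
#' @export
cohen_kappa <- function(rater_a, rater_b,
                        weights = c("none", "linear", "quadratic"),
                        categories = NULL, threshold = 0.70) {
  weights <- match.arg(weights)
  if (length(rater_a) != length(rater_b)) stop("raters must label the same units")
  n <- length(rater_a)
  if (n == 0) stop("no labels")
  categories <- categories %||% sort(unique(c(rater_a, rater_b)))
  fa <- factor(rater_a, levels = categories)
  fb <- factor(rater_b, levels = categories)
  if (anyNA(fa) || anyNA(fb)) stop("labels outside the category set")
  k <- length(categories)
  pobs <- table(fa, fb) / n
  idx <- seq_len(k)
  wmat <- switch(weights,
    none = diag(k),
    linear = 1 - abs(outer(idx, idx, "-")) / max(1, k - 1),
    quadratic = 1 - (outer(idx, idx, "-") / max(1, k - 1))^2
  )
  po <- sum(pobs * wmat)
  pe <- sum(outer(rowSums(pobs), colSums(pobs)) * wmat)
  degenerate <- FALSE
  if (1 - pe < .Machine$double.eps^0.5) {
    # both raters (near) constant on the same label: agreement is trivially
    # perfect but chance-corrected kappa is undefined
    kappa <- 1
    degenerate <- TRUE
    warning("expected agreement is 1; kappa reported as 1 with degenerate flag")
  } else {
    kappa <- (po - pe) / (1 - pe)
  }
  structure(
    list(kappa = kappa, po = po, pe = pe, weights = weights,
         threshold = threshold, pass = kappa >= threshold,
         n = n, degenerate = degenerate, table = pobs * n),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> kappa =", round(x$kappa, 4),
      "(", x$weights, "weights, n =", x$n, ")\n")
  cat("  po =", round(x$po, 4), "| pe =", round(x$pe, 4),
      "| threshold", x$threshold, "->", if (x$pass) "PASS" else "FAIL", "\n")
  if (x$degenerate) cat("  note: degenerate (expected agreement = 1)\n")
  invisible(x)
}
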
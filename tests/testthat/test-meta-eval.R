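test_that("pearson_r matches the direct formula and its trivial cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_r(x, 2 * x + 3)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)

  set.seed(41)
  x <- rnorm(10)
  y <- rnorm(10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$estimate, r_hand, tolerance = 1e-14)
  # cross-check estimate and p against the reference implementation
  ct <- cor.test(x, y)
  expect_equal(res$estimate, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(c(res$ci_lower, res$ci_upper), as.numeric(ct$conf.int),
               tolerance = 1e-10)

  expect_warning(res <- pearson_r(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$estimate))
})

test_that("spearman_rho is rank-based and handles ties like Pearson on midranks", {
  x <- c(1, 4, 2, 8, 5, 7)
  expect_equal(spearman_rho(x, exp(x), ci_method = "none")$estimate, 1)
  expect_equal(spearman_rho(x, -x^3, ci_method = "none")$estimate, -1)

  set.seed(42)
  for (k in 1:50) {
    x <- sample(1:5, 25, replace = TRUE)  # heavy ties
    y <- sample(1:5, 25, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    rho <- spearman_rho(x, y, ci_method = "none")$estimate
    expect_equal(rho, pearson_r(rank(x), rank(y))$estimate, tolerance = 1e-12)
    expect_equal(rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("kendall_tau_b matches brute-force pair counting and stats::cor", {
  expect_equal(kendall_tau_b(1:8, (1:8)^2, ci_method = "none")$estimate, 1)
  expect_equal(kendall_tau_b(1:8, -(1:8), ci_method = "none")$estimate, -1)

  set.seed(43)
  for (k in 1:40) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    tau <- kendall_tau_b(x, y, ci_method = "none")$estimate
    expect_equal(tau, oracle_tau_b(x, y), tolerance = 1e-12)
    expect_equal(tau, cor(x, y, method = "kendall"), tolerance = 1e-12)
  }

  expect_warning(res <- kendall_tau_b(rep(2, 6), 1:6, ci_method = "none"),
                 "constant")
  expect_true(is.na(res$estimate))
})

test_that("kendall p-value agrees with the reference normal approximation", {
  set.seed(44)
  x <- sample(1:5, 40, replace = TRUE)
  y <- sample(1:5, 40, replace = TRUE)
  ours <- kendall_tau_b(x, y, ci_method = "none")
  ref <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE,
                                   continuity = FALSE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("wilcoxon exact p equals sign enumeration and wilcox.test", {
  set.seed(45)
  for (k in 1:30) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, oracle_wilcoxon_exact_p(x - y),
                 tolerance = 1e-12)
    # without ties the reference exact distribution applies
    expect_equal(res$p_value, wilcox.test(x, y, paired = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # tied absolute differences still match the enumeration oracle
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 2, 3, 2, 7, 7, 4, 6.5)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               oracle_wilcoxon_exact_p(x - y), tolerance = 1e-12)
})

test_that("wilcoxon large-sample path matches the continuity-corrected normal test", {
  set.seed(46)
  x <- rnorm(60)
  y <- rnorm(60, 0.2)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$method, "normal")
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("wilcoxon degenerate and symmetry cases behave as documented", {
  x <- c(0.1, 0.5, 0.9, 0.3, 0.7)
  res <- wilcoxon_signed_rank(x, x)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)

  # antisymmetric differences put the statistic at the null centre
  d <- c(0.3, -0.3, 0.8, -0.8, 1.2, -1.2)
  res <- wilcoxon_signed_rank(d, rep(0, 6))
  expect_equal(res$statistic, 6 * 7 / 4)

  # min-max rescaling makes unbounded metrics comparable
  human <- c(0.2, 0.4, 0.6, 0.8, 0.5, 0.3)
  metric <- c(-500, -300, -100, -50, -200, -400)
  res <- wilcoxon_signed_rank(human, metric, rescale = TRUE)
  expect_true(res$rescaled)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("correlations are invariant under the transforms their theory promises", {
  set.seed(47)
  x <- rnorm(30)
  y <- rnorm(30)
  # Pearson: positive affine transforms
  expect_equal(pearson_r(x, y)$estimate,
               pearson_r(2 * x + 1, 0.5 * y - 3)$estimate, tolerance = 1e-12)
  # Spearman / Kendall: strictly monotone transforms
  expect_equal(spearman_rho(x, y, ci_method = "none")$estimate,
               spearman_rho(exp(x), y^3 + y, ci_method = "none")$estimate,
               tolerance = 1e-12)
  expect_equal(kendall_tau_b(x, y, ci_method = "none")$estimate,
               kendall_tau_b(exp(x), y^3 + y, ci_method = "none")$estimate,
               tolerance = 1e-12)
})

test_that("bootstrap intervals are seeded and cover the planted correlation", {
  set.seed(48)
  x <- rnorm(80)
  y <- 0.6 * x + rnorm(80, sd = 0.8)
  a <- spearman_rho(x, y, ci_method = "bootstrap", n_boot = 500, seed = 9)
  b <- spearman_rho(x, y, ci_method = "bootstrap", n_boot = 500, seed = 9)
  expect_identical(a, b)
  expect_true(a$ci_lower < a$estimate && a$estimate < a$ci_upper)
  f <- spearman_rho(x, y, ci_method = "fisher")
  expect_equal(f$ci_method, "fisher")
  expect_true(f$ci_lower < f$estimate && f$estimate < f$ci_upper)
})

test_that("dependent-correlation comparison behaves across its regimes", {
  set.seed(49)
  h <- rnorm(200)
  a <- 0.7 * h + rnorm(200, sd = 0.7)

  # identical metrics: no difference at all
  res <- compare_dependent_correlations(h, a, a)
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)

  # a permuted copy destroys the correlation: strongly significant
  b <- sample(a)
  res_perm <- compare_dependent_correlations(h, a, b)
  expect_lt(res_perm$p_value, 0.01)
  boot <- compare_dependent_correlations(h, a, b, method = "bootstrap",
                                         n_boot = 1000, seed = 5)
  expect_lt(boot$p_value, 0.02)

  # a sign-flipped copy is maximally different
  res_flip <- compare_dependent_correlations(h, a, -a)
  expect_gt(abs(res_flip$z), abs(res_perm$z))

  expect_warning(
    res <- compare_dependent_correlations(h, rep(1, 200), a),
    "constant"
  )
  expect_true(is.na(res$p_value))
})

test_that("spearman variant of the dependent comparison uses ranks", {
  set.seed(50)
  h <- rnorm(100)
  a <- 0.8 * h + rnorm(100, sd = 0.5)
  res <- compare_dependent_correlations(h, exp(a), a, cor_method = "spearman")
  # monotone transform leaves rank correlations equal
  expect_equal(res$z, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})
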
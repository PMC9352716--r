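test_that("pooled-SD effect size matches hand and published arithmetic", {
  # published summary-statistic rows recompute to the printed d
  expect_equal(cohens_d_pooled(81.49, 21.67, 21, 30.35, 19.25, 16), 2.47,
               tolerance = 0.005)
  expect_equal(cohens_d_pooled(0.71, 0.27, 21, 1.21, 0.55, 14), 1.24,
               tolerance = 0.005)
  expect_equal(cohens_d_pooled(5, 1, 10, 5, 2, 10), 0)
  # symmetric in group order, invariant under common affine rescale
  set.seed(8)
  for (i in 1:20) {
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    s1 <- runif(1, 0.1, 3); s2 <- runif(1, 0.1, 3)
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    d <- cohens_d_pooled(m1, s1, n1, m2, s2, n2)
    expect_equal(cohens_d_pooled(m2, s2, n2, m1, s1, n1), d)
    a <- runif(1, 0.2, 4); b <- runif(1, -10, 10)
    expect_equal(cohens_d_pooled(a * m1 + b, a * s1, n1, a * m2 + b, a * s2, n2), d)
  }
  expect_error(cohens_d_pooled(1, 0, 5, 2, 0, 5), "degenerate")
})

test_that("rank-sum statistic uses the Mann-Whitney convention", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$W, 0)
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2))$W, 4)  # n_x * n_y
  set.seed(17)
  for (i in 1:25) {
    x <- runif(sample(2:6, 1)); y <- runif(sample(2:6, 1))
    w <- wilcoxon_rank_sum(x, y)
    expect_gte(w$W, 0); expect_lte(w$W, length(x) * length(y))
    expect_equal(w$W + wilcoxon_rank_sum(y, x)$W, length(x) * length(y))
    o <- wilcox_enum_oracle(x, y)
    expect_equal(w$W, o$W)
    expect_equal(w$p_value, o$p_value, tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(c(1, 1), c(1, 1)), "identical")
})

test_that("the normality gate picks the t-test or the rank test appropriately", {
  x <- qnorm(ppoints(20), 10, 2)       # textbook-normal samples
  gc <- compare_groups(x, x + 1e-9, variable = "flat")
  expect_equal(gc$test_used, "students_t")
  expect_gt(gc$p_value, 0.99)
  # zero-inflated sample (like DNT route scores) forces the rank test
  set.seed(21)
  zi <- c(rep(0, 15), runif(5, 0, 2))
  nm <- rnorm(20, 1, 0.5)
  gz <- compare_groups(zi, nm)
  expect_equal(gz$test_used, "wilcoxon_rank_sum")
  # attached effect size equals the summary-statistic formula
  expect_equal(gz$cohens_d,
               cohens_d_pooled(mean(zi), sd(zi), 20, mean(nm), sd(nm), 20))
})

test_that("ANCOVA reports the marginal group F on (1, n-3) df", {
  set.seed(31)
  n <- 36
  grp <- factor(rep(c("control", "patient"), c(21, 15)))
  cov <- runif(n, 10, 60)
  y <- 2 + 0.8 * (grp == "patient") + rnorm(n, 0, 0.4)
  af <- ancova_adjusted(y, grp, cov)
  expect_equal(af$df_between, 1L)
  expect_equal(af$df_within, 33L)
  expect_lt(af$p_value, 0.01)
  # equivalent to the squared t of the group coefficient
  ref <- summary(lm(y ~ grp + cov))$coefficients
  expect_equal(af$F_statistic, ref[2, "t value"]^2)
  expect_equal(af$p_value, ref[2, "Pr(>|t|)"])
  # inverse transform: fits 1/y; zero outcomes are rejected
  afi <- ancova_adjusted(y, grp, cov, transform = "inverse")
  refi <- summary(lm(I(1 / y) ~ grp + cov))$coefficients
  expect_equal(afi$p_value, refi[2, "Pr(>|t|)"])
  expect_error(ancova_adjusted(c(0, y[-1]), grp, cov, transform = "inverse"),
               "inverse")
})

test_that("ANCOVA group test holds its nominal type-I error under permutation", {
  set.seed(32)
  n <- 36
  cov <- runif(n, 10, 60)
  y <- 1 + 0.02 * cov + rnorm(n, 0, 0.5)   # no true group effect
  rej <- 0L
  for (i in 1:2000) {
    grp <- factor(sample(rep(c("a", "b"), c(21, 15))))
    if (ancova_adjusted(y, grp, cov)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 2000, 0.03)
  expect_lt(rej / 2000, 0.07)
})

test_that("standardized regression returns beta, R2, f2 and a residual flag", {
  set.seed(41)
  x <- rnorm(500)
  y <- 0.5 * x + rnorm(500, 0, sqrt(1 - 0.25))
  rf <- linear_regression_standardized(x, y)
  expect_equal(rf$beta_standardized, 0.5, tolerance = 0.1)
  expect_equal(rf$f_squared, rf$r_squared / (1 - rf$r_squared))
  expect_true(rf$residuals_normal)
  # beta on standardized variables equals the Pearson correlation
  expect_equal(rf$beta_standardized, cor(x, y))
  expect_equal(rf$r_squared, cor(x, y)^2)
  expect_error(linear_regression_standardized(x, x), "perfect fit")
  expect_error(linear_regression_standardized(rep(1, 10), rnorm(10)),
               "zero variance")
})

test_that("f2 is strictly increasing in R2 and brackets the published pairings", {
  f2 <- function(r2) r2 / (1 - r2)
  r2s <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(f2(r2s)) > 0))
  expect_true(round(f2(0.29), 2) %in% c(0.41, 0.42))
  expect_equal(round(f2(0.27), 2), 0.37)
  expect_true(round(f2(0.26), 2) %in% c(0.35, 0.36))
  expect_true(round(f2(0.22), 2) %in% c(0.28, 0.29))
})

test_that("logistic risk prediction returns odds ratios and flags separation", {
  # constant predictor: no information, unit odds ratio
  l0 <- logistic_risk(rep(2, 10), rep(c("high", "low"), 5))
  expect_equal(l0$odds_ratio, 1)
  set.seed(51)
  x <- rnorm(300)
  lab <- ifelse(runif(300) < plogis(0.7 * x), "high", "low")
  lf <- logistic_risk(x, lab)
  expect_gt(lf$odds_ratio, 1)
  expect_equal(lf$n_high + lf$n_low, 300)
  # complete separation is an error, not a divergent estimate
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  labs <- rep(c("low", "high"), each = 20)
  expect_error(logistic_risk(xs, labs), "separation")
  expect_error(logistic_risk(1:4, rep("high", 4)), "both risk classes")
})
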
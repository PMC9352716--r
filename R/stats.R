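#' Pooled-SD Cohen's d from summary statistics
#'
#' Unsigned standardized mean difference with the pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`, computable directly
#' from printed group means/SDs/ns.
#'
#' @param mean1,sd1,n1 first group's mean, SD, and size (`n1 >= 2`).
#' @param mean2,sd2,n2 second group's summary statistics.
#' @return non-negative effect size.
#' @examples
#' cohens_d_pooled(81.49, 21.67, 21, 30.35, 19.25, 16)  # ~2.47
#' @export
cohens_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) stop_navdis("degenerate groups: both SDs are zero")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  abs(mean1 - mean2) / sp
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with the Mann-Whitney statistic of the first
#' sample: the sum of `x`'s pooled midranks minus `n_x (n_x + 1) / 2`, so
#' `W` lies in `[0, n_x n_y]`. The p-value is exact for small untied
#' samples and a tie-corrected normal approximation otherwise (delegated to
#' [stats::wilcox.test()]).
#'
#' @param x,y non-empty numeric samples.
#' @return list with `W` and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1L) {
    stop_navdis("all values identical across both samples")
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL, correct = TRUE))
  list(W = unname(wt$statistic), p_value = wt$p.value)
}

#' Normality-gated two-group comparison with effect size
#'
#' Runs a Shapiro-Wilk check on each group at `alpha_normality`; when both
#' groups look normal a pooled-variance Student's t-test is used, otherwise
#' the Wilcoxon rank-sum test. A pooled-SD Cohen's d from the sample moments
#' is always attached.
#'
#' @param x,y numeric samples (n >= 3 each, for the normality check).
#' @param alpha_normality significance level of the normality gate.
#' @param variable optional label carried into the result.
#' @return object of class `group_comparison`.
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05, variable = "") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 3, length(y) >= 3)
  normal <- function(v) {
    if (sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha_normality
  }
  both_normal <- normal(x) && normal(y)
  if (both_normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    test_used <- "students_t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wr <- wilcoxon_rank_sum(x, y)
    test_used <- "wilcoxon_rank_sum"; statistic <- wr$W; p <- wr$p_value
  }
  out <- list(variable = variable, test_used = test_used, statistic = statistic,
              p_value = p,
              cohens_d = cohens_d_pooled(mean(x), sd(x), length(x),
                                         mean(y), sd(y), length(y)),
              n1 = length(x), n2 = length(y),
              mean1 = mean(x), sd1 = sd(x), mean2 = mean(y), sd2 = sd(y))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  stat_lab <- if (x$test_used == "students_t") "t" else "W"
  cat(sprintf("%s: %s = %.3f, p = %.4g, d = %.2f (n = %d vs %d)\n",
              if (nzchar(x$variable)) x$variable else "comparison",
              stat_lab, x$statistic, x$p_value, x$cohens_d, x$n1, x$n2))
  invisible(x)
}

#' One-way ANCOVA with optional inverse transform
#'
#' Tests the group effect on an outcome while controlling for a continuous
#' covariate (here: map-view duration). Positively skewed outcomes can be
#' inverse-transformed (`y -> 1/y`) to license the parametric fit. The group
#' effect is the marginal F with `(1, n - 3)` degrees of freedom from the
#' least-squares fit `outcome ~ group + covariate`.
#'
#' @param outcome numeric outcome.
#' @param group two-level factor (or coercible).
#' @param covariate numeric covariate, same length.
#' @param transform `"none"` or `"inverse"`; the latter requires strictly
#'   positive outcomes.
#' @return object of class `ancova_fit` with `F_statistic`, `df_between`,
#'   `df_within`, `p_value`, `transform_applied`.
#' @export
ancova_adjusted <- function(outcome, group, covariate,
                            transform = c("none", "inverse")) {
  transform <- match.arg(transform)
  keep <- complete.cases(outcome, group, covariate)
  outcome <- outcome[keep]; covariate <- covariate[keep]
  group <- droplevels(as.factor(group[keep]))
  stopifnot(nlevels(group) == 2, length(outcome) >= 5)
  if (transform == "inverse") {
    if (any(outcome == 0)) stop_navdis("inverse transform undefined at outcome 0")
    outcome <- 1 / outcome
  }
  fit <- stats::lm(outcome ~ group + covariate)
  sm <- summary(fit)$coefficients
  tg <- sm[2, "t value"]
  n <- length(outcome)
  out <- list(F_statistic = tg^2, df_between = 1L, df_within = n - 3L,
              p_value = sm[2, "Pr(>|t|)"], transform_applied = transform,
              n = n)
  class(out) <- "ancova_fit"
  out
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("ANCOVA group effect: F(%d,%d) = %.3f, p = %.4g (transform: %s)\n",
              x$df_between, x$df_within, x$F_statistic, x$p_value,
              x$transform_applied))
  invisible(x)
}

#' Standardized simple linear regression with Cohen's f-squared
#'
#' Z-scores predictor and outcome, fits ordinary least squares, and reports
#' the standardized slope (beta), its two-sided p-value, R-squared,
#' `f^2 = R^2 / (1 - R^2)`, and a Shapiro-Wilk residual-normality flag.
#'
#' @param x predictor sample (non-zero variance, n >= 3).
#' @param y outcome sample.
#' @return object of class `regression_fit`.
#' @export
linear_regression_standardized <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  stopifnot(length(x) >= 3)
  if (sd(x) == 0) stop_navdis("zero variance in predictor")
  if (sd(y) == 0) stop_navdis("zero variance in outcome")
  if (stats::cor(x, y)^2 >= 1 - 1e-12) {
    stop_navdis("perfect fit: f^2 undefined at R^2 = 1")
  }
  zx <- as.numeric(scale(x)); zy <- as.numeric(scale(y))
  fit <- stats::lm(zy ~ zx)
  r2 <- summary(fit)$r.squared
  sm <- summary(fit)$coefficients
  out <- list(beta_standardized = unname(coef(fit)[2]),
              p_value = sm[2, "Pr(>|t|)"],
              r_squared = r2, f_squared = r2 / (1 - r2),
              residuals_normal = stats::shapiro.test(resid(fit))$p.value > 0.05,
              n = length(x))
  class(out) <- "regression_fit"
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("beta = %.3f, p = %.4g, R^2 = %.3f, f^2 = %.3f (residuals %s, n = %d)\n",
              x$beta_standardized, x$p_value, x$r_squared, x$f_squared,
              if (x$residuals_normal) "normal" else "non-normal", x$n))
  invisible(x)
}

#' Binomial logistic regression for risk-group prediction
#'
#' Fits label ~ predictor by maximum likelihood and reports the odds ratio
#' per unit of the predictor with its Wald p-value. Complete separation -
#' a real hazard at the small sample sizes this design invites - is raised
#' as an error rather than returned as a divergent estimate.
#'
#' @param x numeric predictor.
#' @param labels vector of `"high"` / `"low"` risk labels (or a factor whose
#'   second level is the event); both classes must be present, n >= 4.
#' @return object of class `logistic_fit` with `odds_ratio`, `p_value`,
#'   `n_high`, `n_low`.
#' @export
logistic_risk <- function(x, labels) {
  keep <- complete.cases(x, labels)
  x <- x[keep]; labels <- labels[keep]
  yb <- if (is.factor(labels)) labels == levels(labels)[2] else labels == "high"
  stopifnot(length(x) >= 4)
  if (length(unique(yb)) < 2) stop_navdis("both risk classes must be present")
  if (sd(x) == 0) {
    # a constant predictor carries no information: unit odds ratio
    out <- list(odds_ratio = 1, p_value = 1, n_high = sum(yb), n_low = sum(!yb))
    class(out) <- "logistic_fit"
    return(out)
  }
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(yb ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  slope <- unname(coef(fit)[2])
  if (warned_sep || abs(slope) > 20) {
    stop_navdis("complete (or quasi-complete) separation: odds ratio diverges")
  }
  sm <- summary(fit)$coefficients
  out <- list(odds_ratio = exp(slope), p_value = sm[2, "Pr(>|z|)"],
              n_high = sum(yb), n_low = sum(!yb))
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: OR = %.2f, p = %.4g (high n = %d, low n = %d)\n",
              x$odds_ratio, x$p_value, x$n_high, x$n_low))
  invisible(x)
}
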
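#' Moments of a truncated normal distribution
#'
#' Mean and standard deviation of a normal distribution with underlying
#' location `mu` and scale `sigma`, truncated to `[lower, upper]`.
#'
#' @param mu,sigma underlying (pre-truncation) normal parameters; `sigma > 0`.
#' @param lower,upper truncation bounds; may be infinite.
#' @return named numeric vector with elements `mean` and `sd`.
#' @export
tnorm_moments <- function(mu, sigma, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper)
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
    return(c(mean = NaN, sd = NaN))
  }
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  # difference of CDFs via whichever tail avoids 1 - 1 cancellation
  Z <- if (is.finite(a) && a > 0) {
    pnorm(a, lower.tail = FALSE) - pnorm(b, lower.tail = FALSE)
  } else {
    pnorm(b) - pnorm(a)
  }
  if (!is.finite(Z) || Z <= 0) return(c(mean = NaN, sd = NaN))
  da <- dnorm(a)
  db <- dnorm(b)
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (ada - bdb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Quantiles and random draws from a truncated normal
#'
#' Inverse-CDF implementation, stable even when the truncation interval lies
#' far in one tail of the underlying normal.
#'
#' @param p probabilities in `[0, 1]`.
#' @inheritParams tnorm_moments
#' @return numeric vector of quantiles.
#' @export
qtnorm <- function(p, mu, sigma, lower = -Inf, upper = Inf) {
  stopifnot(all(p >= 0 & p <= 1), sigma >= 0)
  if (sigma == 0) return(rep(min(max(mu, lower), upper), length(p)))
  pa <- pnorm(lower, mu, sigma)
  if (pa < 0.5) {
    pb <- pnorm(upper, mu, sigma)
    q <- qnorm(pa + p * (pb - pa), mu, sigma)
  } else {
    # interval in the upper tail: work with survival probabilities so the
    # CDF difference never cancels to 0 or rounds to 1
    sa <- pnorm(lower, mu, sigma, lower.tail = FALSE)
    sb <- pnorm(upper, mu, sigma, lower.tail = FALSE)
    q <- qnorm(sa - p * (sa - sb), mu, sigma, lower.tail = FALSE)
  }
  pmin(pmax(q, lower), upper)
}

#' @rdname qtnorm
#' @param n number of draws.
#' @export
rtnorm <- function(n, mu, sigma, lower = -Inf, upper = Inf) {
  qtnorm(runif(n), mu, sigma, lower, upper)
}

#' Find truncated-normal parameters that reproduce target moments
#'
#' Solves for underlying `(mu, sigma)` such that the *truncated* distribution
#' on `[lower, upper]` has exactly the target mean, and a standard deviation
#' as close to the target as the family allows. For strongly bounded targets
#' (e.g. a coefficient of variation above 1 next to a zero bound) the exact
#' target SD is not achievable by any truncated normal; the fit then keeps
#' the mean exact and reports the achieved SD.
#'
#' @param target_mean,target_sd desired moments of the truncated variable;
#'   `target_sd >= 0` and `lower < target_mean < upper`.
#' @inheritParams tnorm_moments
#' @return list with `mu`, `sigma`, `mean`, `sd` (achieved truncated
#'   moments) and `sd_matched` (TRUE when the achieved SD is within 1% of
#'   the target).
#' @export
fit_truncnorm <- function(target_mean, target_sd, lower = -Inf, upper = Inf) {
  stopifnot(lower < upper, target_sd >= 0)
  if (target_sd == 0) {
    return(list(mu = target_mean, sigma = 0, mean = target_mean, sd = 0,
                sd_matched = TRUE))
  }
  if (target_mean <= lower || target_mean >= upper) {
    stop_navdis("target mean %.4g outside truncation bounds [%g, %g]",
                target_mean, lower, upper)
  }
  # bounds at 8+ sd from the mean leave the normal effectively untruncated
  if (lower < target_mean - 8 * target_sd && upper > target_mean + 8 * target_sd) {
    return(list(mu = target_mean, sigma = target_sd, mean = target_mean,
                sd = target_sd, sd_matched = TRUE))
  }

  mu_for_mean <- function(sigma) {
    # truncated mean is strictly increasing in mu; 36 sd either side of the
    # target keeps every pnorm/dnorm ratio representable
    lo_mu <- target_mean - 36 * sigma
    hi_mu <- target_mean + 36 * sigma
    f <- function(m) tnorm_moments(m, sigma, lower, upper)[["mean"]] - target_mean
    flo <- f(lo_mu); fhi <- f(hi_mu)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    uniroot(f, c(lo_mu, hi_mu), tol = 1e-12)$root
  }
  sd_err <- function(log_sigma) {
    mu <- mu_for_mean(exp(log_sigma))
    if (!is.finite(mu)) return(1e10)
    (tnorm_moments(mu, exp(log_sigma), lower, upper)[["sd"]] - target_sd)^2
  }
  opt <- optimize(sd_err, c(log(target_sd / 5), log(target_sd * 25)),
                  tol = 1e-12)
  sigma <- exp(opt$minimum)
  mu <- mu_for_mean(sigma)
  if (!is.finite(mu)) {   # fall back to the untuned scale, mean still exact
    sigma <- target_sd
    mu <- mu_for_mean(sigma)
  }
  if (!is.finite(mu)) {
    stop_navdis("could not match truncated mean %.4g on [%g, %g]",
                target_mean, lower, upper)
  }
  mom <- tnorm_moments(mu, sigma, lower, upper)
  list(mu = mu, sigma = sigma, mean = mom[["mean"]], sd = mom[["sd"]],
       sd_matched = abs(mom[["sd"]] - target_sd) <= 0.01 * target_sd)
}
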
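#' Distribution of a ratio of shifted standard normals
#'
#' Distribution function and density of `W = (a + X)/(b + Y)` where `X` and
#' `Y` are independent standard normal variables. This is Marsaglia's general
#' ratio-of-normals law; every correlated, nonzero-mean normal ratio reduces
#' to it by a linear transformation. For `a = b = 0` it is the standard
#' Cauchy distribution; for large `b` it approaches a normal distribution.
#'
#' The CDF is computed by one-dimensional adaptive quadrature over the
#' denominator variable: the standard normal density of `y` is integrated
#' against `P(X <= t(b + y) - a)` on the region where `b + y > 0` and
#' against `P(X >= t(b + y) - a)` where `b + y < 0`. The integral is
#' truncated at ten standard deviations of `y` (normal mass beyond is below
#' 1e-23) and split at the sign change of the denominator and at the point
#' where the inner normal CDF transitions, so the absolute error is held
#' below 1e-8.
#'
#' @param q,x vector of quantiles.
#' @param a numerator shift: mean of the numerator normal.
#' @param b denominator shift: mean of the denominator normal.
#'
#' @return `pratio_normal()` returns `P(W <= q)`; `dratio_normal()` the
#'   density at `x`. Both are vectorised over their first argument.
#'
#' @examples
#' pratio_normal(0, a = 0, b = 0)   # standard Cauchy: 0.5
#' pratio_normal(1, a = 0, b = 0)   # 0.75
#' @export
pratio_normal <- function(q, a, b) {
  check_scalar_finite(a, "a")
  check_scalar_finite(b, "b")
  if (!is.numeric(q) || anyNA(q)) stop_invalid("`q` must be numeric, no NA.")
  vapply(q, ratio_normal_cdf_one, numeric(1), a = a, b = b)
}

ratio_normal_cdf_one <- function(t, a, b) {
  if (t == Inf) return(1)
  if (t == -Inf) return(0)
  lo <- b - 10
  hi <- b + 10
  # shift so the integration variable is the denominator v = b + y
  f_pos <- function(v) dnorm(v - b) * pnorm(t * v - a)
  f_neg <- function(v) dnorm(v - b) * pnorm(t * v - a, lower.tail = FALSE)
  brk <- c(lo, 0, if (t != 0) a / t, hi)
  brk <- sort(unique(pmin(pmax(brk, lo), hi)))
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    l <- brk[i]; u <- brk[i + 1L]
    if (u <= l) next
    f <- if ((l + u) / 2 > 0) f_pos else f_neg
    total <- total + integrate(f, l, u, rel.tol = 1e-11, abs.tol = 1e-11,
                               subdivisions = 500L)$value
  }
  min(max(total, 0), 1)
}

#' @rdname pratio_normal
#' @export
dratio_normal <- function(x, a, b) {
  check_scalar_finite(a, "a")
  check_scalar_finite(b, "b")
  if (!is.numeric(x) || anyNA(x)) stop_invalid("`x` must be numeric, no NA.")
  vapply(x, function(t) {
    if (!is.finite(t)) return(0)
    f <- function(v) dnorm(v - b) * abs(v) * dnorm(t * v - a)
    integrate(f, b - 10, b + 10, rel.tol = 1e-10, abs.tol = 1e-12,
              subdivisions = 500L)$value
  }, numeric(1))
}

check_cauchy_like_params <- function(b, r, delta0) {
  check_scalar_finite(b, "b")
  check_positive(r, "r")
  check_scalar_finite(delta0, "delta0")
  invisible(NULL)
}

# Null-boundary numerator shift: under delta = delta0, mu_NI = theta2 (1 -
# delta0), so a = -mu_NI / sigma_NI = -(1 - delta0) b / r.
null_boundary_a <- function(b, r, delta0) -(1 - delta0) * b / r

#' The Cauchy-like null distribution of the fraction-retention ratio test
#'
#' Distribution function, density, quantile function and random generation
#' for the law of `Z = r (a + X)/(b + Y) + 1` with `X`, `Y` independent
#' standard normals, evaluated at the null boundary of the fraction-retention
#' hypothesis: `a = -(1 - delta0) b / r`. Here `b` is the standardized
#' historical control effect (`theta2 / sigma_H`), `r = sigma_NI / sigma_H`
#' the ratio of the two difference-estimate standard deviations, and
#' `delta0` the retention fraction under test. This is the reference
#' distribution of the ratio test statistic `1 - (C.NI - T.NI)/(C.H - P.H)`.
#'
#' Quantiles are found by bracketing the target probability and root
#' refinement on the integrated CDF. The initial bracket
#' `1 +/- 50 r (1 + |a|)/(1 + |b|)` is expanded geometrically until it
#' straddles `p`, which is required because the distribution has Cauchy-type
#' tails whenever the denominator can cross zero.
#'
#' @param q,x vector of quantiles.
#' @param p vector of probabilities, strictly inside (0, 1).
#' @param n number of draws.
#' @param b standardized historical control effect.
#' @param r positive ratio `sigma_NI / sigma_H`.
#' @param delta0 retention fraction defining the null boundary.
#' @param seed optional integer seed for reproducible draws.
#'
#' @return `pcauchy_like()` the CDF, `dcauchy_like()` the density,
#'   `qcauchy_like()` quantiles accurate to 1e-8 in probability,
#'   `rcauchy_like()` a numeric vector of draws (infinite values from
#'   denominator zero-crossings are kept).
#'
#' @examples
#' pcauchy_like(1.0154, b = 3.1213, r = 1.1573, delta0 = 0.5)
#' qcauchy_like(0.975, b = 3, r = 1, delta0 = 0.5)
#' @export
pcauchy_like <- function(q, b, r, delta0) {
  check_cauchy_like_params(b, r, delta0)
  pratio_normal((q - 1) / r, a = null_boundary_a(b, r, delta0), b = b)
}

#' @rdname pcauchy_like
#' @export
dcauchy_like <- function(x, b, r, delta0) {
  check_cauchy_like_params(b, r, delta0)
  dratio_normal((x - 1) / r, a = null_boundary_a(b, r, delta0), b = b) / r
}

#' @rdname pcauchy_like
#' @export
qcauchy_like <- function(p, b, r, delta0) {
  check_cauchy_like_params(b, r, delta0)
  if (!is.numeric(p) || anyNA(p)) stop_domain("`p` must be numeric, no NA.")
  if (any(p <= 0 | p >= 1)) {
    stop_domain("`p` must lie strictly between 0 and 1.")
  }
  a <- null_boundary_a(b, r, delta0)
  vapply(p, cauchy_like_quantile_one, numeric(1), a = a, b = b, r = r)
}

cauchy_like_quantile_one <- function(p, a, b, r) {
  cdf <- function(z) ratio_normal_cdf_one((z - 1) / r, a, b)
  half <- 50 * r * (1 + abs(a)) / (1 + abs(b))
  lo <- 1 - half
  hi <- 1 + half
  while (cdf(lo) > p) {
    hi <- lo
    lo <- 1 - 2 * (1 - lo)
  }
  while (cdf(hi) < p) {
    lo <- hi
    hi <- 1 + 2 * (hi - 1)
  }
  uniroot(function(z) cdf(z) - p, lower = lo, upper = hi,
          tol = 1e-10, maxiter = 200L)$root
}

#' @rdname pcauchy_like
#' @export
rcauchy_like <- function(n, b, r, delta0, seed = NULL) {
  check_cauchy_like_params(b, r, delta0)
  n <- check_count(n, "n")
  a <- null_boundary_a(b, r, delta0)
  seed_stream(seed, 1L)
  x <- rnorm(n)
  y <- rnorm(n)
  # b + y = 0 is a probability-zero event; resulting infinities are kept
  r * (a + x) / (b + y) + 1
}
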
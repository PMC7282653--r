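#' Per-arm sufficient statistics
#'
#' `arm_stats()` bundles the sample mean, the `n - 1`-divisor sample
#' variance and the sample size of one arm; `summarize_arm()` computes them
#' from raw observations. These are the only data the generalized pivotal
#' quantities need.
#'
#' @param mean sample mean.
#' @param variance sample variance (divisor `n - 1`), non-negative.
#' @param n sample size, at least 2.
#' @param x numeric vector of at least two finite observations.
#'
#' @return an object of class `arm_stats`: a list with elements `mean`,
#'   `variance`, `n`.
#' @examples
#' summarize_arm(c(0, 2))
#' @export
arm_stats <- function(mean, variance, n) {
  check_scalar_finite(mean, "mean")
  check_scalar_finite(variance, "variance")
  if (variance < 0) stop_invalid("`variance` must be non-negative.")
  n <- check_count(n, "n", min = 2L)
  structure(list(mean = mean, variance = variance, n = n),
            class = "arm_stats")
}

#' @rdname arm_stats
#' @export
summarize_arm <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_data("Arm observations must be finite numeric values.")
  }
  if (length(x) < 2L) {
    stop_data("At least two observations per arm are required.")
  }
  arm_stats(mean = mean(x), variance = var(x), n = length(x))
}

#' @export
print.arm_stats <- function(x, ...) {
  cat(sprintf("arm_stats: mean %.6g, variance %.6g, n %d\n",
              x$mean, x$variance, x$n))
  invisible(x)
}

as_arm_stats <- function(x, name) {
  if (inherits(x, "arm_stats")) return(x)
  if (is.numeric(x)) return(summarize_arm(x))
  stop_invalid(sprintf(
    "`%s` must be a numeric vector of observations or an `arm_stats` object.",
    name))
}

# Core GPQ draws for one normal mean: R_mu = xbar - Z * sqrt((n-1) s^2 /
# (n U)) with Z ~ N(0,1), U ~ chi^2(n-1), on separately seeded substreams
# so that the two arms' streams are mutually independent.
gpq_mu_draws <- function(stats, M, seed, stream_z, stream_u) {
  seed_stream(seed, stream_z)
  z <- rnorm(M)
  seed_stream(seed, stream_u)
  u <- rchisq(M, df = stats$n - 1)
  stats$mean - z * sqrt((stats$n - 1) * stats$variance / (stats$n * u))
}

#' Generalized pivotal quantity draws for a normal mean
#'
#' Monte Carlo realizations of the generalized pivotal quantity (GPQ) for
#' the mean of a normal sample with unknown variance,
#' `R_mu = xbar - Z sqrt((n - 1) s^2 / (n U))`, where `Z` is standard
#' normal and `U` is chi-square with `n - 1` degrees of freedom,
#' independent of `Z`. The distribution of `R_mu` is free of the unknown
#' parameters and its observed value is the parameter itself, the two
#' defining properties of a GPQ.
#'
#' @param stats an [arm_stats()] object (or raw numeric vector).
#' @param M number of Monte Carlo draws.
#' @param seed optional integer seed; two independent substreams (for `Z`
#'   and `U`) are derived from it.
#' @return numeric vector of `M` draws.
#' @examples
#' sample_gpq_mu(arm_stats(0.24, 0.0144, 30), M = 5, seed = 1)
#' @export
sample_gpq_mu <- function(stats, M, seed = NULL) {
  stats <- as_arm_stats(stats, "stats")
  M <- check_count(M, "M")
  gpq_mu_draws(stats, M, seed, stream_z = 1L, stream_u = 2L)
}

#' GPQ draws for the ratio of two normal means
#'
#' Elementwise ratio of the mean-GPQs of the non-inferiority arm and the
#' historical arm, `R_ratio = R_muNI / R_muH`, built from four mutually
#' independent random streams (`Z_H`, `U_H`, `Z_NI`, `U_NI`). Draws where
#' the denominator GPQ crosses zero yield infinities and are retained: the
#' ratio GPQ genuinely has heavy tails when the historical effect is weak,
#' and trimming them would bias the generalized p-value.
#'
#' @param stats_h,stats_ni [arm_stats()] (or raw numeric vectors) for the
#'   historical control-vs-placebo arm and the NI treatment-vs-control arm.
#' @inheritParams sample_gpq_mu
#' @return an object of class `gpq_draws`: a numeric vector of `M` ratio
#'   draws with attributes `M` and `seed`.
#' @examples
#' sample_gpq_ratio(arm_stats(0.24, 1e-4, 30), arm_stats(0.12, 1e-4, 30),
#'                  M = 5, seed = 1)
#' @export
sample_gpq_ratio <- function(stats_h, stats_ni, M, seed = NULL) {
  stats_h <- as_arm_stats(stats_h, "stats_h")
  stats_ni <- as_arm_stats(stats_ni, "stats_ni")
  M <- check_count(M, "M")
  r_h <- gpq_mu_draws(stats_h, M, seed, stream_z = 1L, stream_u = 2L)
  r_ni <- gpq_mu_draws(stats_ni, M, seed, stream_z = 3L, stream_u = 4L)
  structure(r_ni / r_h, class = "gpq_draws", M = M,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Generalized p-value from ratio-GPQ draws
#'
#' The generalized p-value for `H0: mu_NI / mu_H >= 1 - delta0` (the
#' complement form of the retention hypothesis `delta <= delta0`) is the
#' fraction of ratio-GPQ draws at or above the null boundary `1 - delta0`.
#' A small value means the GPQ distribution sits almost entirely below the
#' boundary, i.e. the data support retention beyond `delta0`. Ties at the
#' boundary count toward the tail, and `+Inf` draws count while `-Inf`
#' draws do not, both conservative for rejection.
#'
#' @param draws a [sample_gpq_ratio()] result (any numeric vector works).
#' @param delta0 retention fraction under test.
#' @return the Monte Carlo generalized p-value in `[0, 1]`.
#' @export
gpv_pvalue <- function(draws, delta0) {
  check_scalar_finite(delta0, "delta0")
  if (!is.numeric(draws) || length(draws) == 0L || anyNA(draws)) {
    stop_invalid("`draws` must be a non-empty numeric vector without NA.")
  }
  mean(draws >= 1 - delta0)
}

#' The generalized p-value test of fraction retention
#'
#' Runs the GPV-based test of `H0: delta <= delta0` against
#' `H1: delta > delta0` from raw per-arm observations (or their
#' [arm_stats()]): historical control-vs-placebo effects and NI
#' treatment-vs-control effects, each modelled as a normal sample with its
#' own unknown variance. The test needs no large-sample approximation and
#' no assumption that the two variances are equal: nuisance parameters are
#' eliminated by the generalized-pivotal-quantity construction, and the
#' p-value is estimated by Monte Carlo over `M` GPQ draws
#' (see [sample_gpq_ratio()] and [gpv_pvalue()]).
#'
#' @param data either a data frame in long form with an `arm` column
#'   (values `"historical"` and `"ni"`) and a numeric `value` column, e.g.
#'   from [read_raw_samples()]; or `NULL` when `h` and `ni` are given
#'   directly.
#' @param h,ni alternative input: the two arms as numeric vectors or
#'   [arm_stats()] objects (ignored unless `data` is `NULL`).
#' @param delta0 retention fraction under test; default 0.5.
#' @param alpha one-sided significance level; default 0.025.
#' @param M number of Monte Carlo GPQ draws; default 10000.
#' @param seed optional integer seed; all four GPQ substreams are derived
#'   from it, so a fixed seed reproduces the result exactly.
#'
#' @return a one-row `ni_test_result` tibble with `method = "gpv"`,
#'   `statistic = NA` (the GPV test has no single test statistic),
#'   `p_value`, `reject`, `delta0`, `alpha`, `mc_draws` and `seed`.
#'
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   arm = rep(c("historical", "ni"), each = 30),
#'   value = c(rnorm(30, 0.24, 0.12), rnorm(30, 0.02, 0.12)))
#' gpv_test(d, delta0 = 0.5, seed = 7)
#' @export
gpv_test <- function(data = NULL, h = NULL, ni = NULL, delta0 = 0.5,
                     alpha = 0.025, M = 10000, seed = NULL) {
  check_scalar_finite(delta0, "delta0")
  check_prob_open(alpha, "alpha")
  M <- check_count(M, "M")
  if (!is.null(data)) {
    arms <- split_arm_data(data)
    h <- arms$historical
    ni <- arms$ni
  }
  if (is.null(h) || is.null(ni)) {
    stop_invalid("Supply either `data` or both `h` and `ni`.")
  }
  stats_h <- as_arm_stats(h, "h")
  stats_ni <- as_arm_stats(ni, "ni")
  draws <- sample_gpq_ratio(stats_h, stats_ni, M, seed = seed)
  p <- gpv_pvalue(draws, delta0)
  d <- tibble(study_id = "gpv", delta0 = delta0, alpha = alpha)
  assemble_result(d, method = "gpv", statistic = NA_real_, p_value = p,
                  mc_draws = M,
                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

split_arm_data <- function(data) {
  if (!is.data.frame(data) || !all(c("arm", "value") %in% names(data))) {
    stop_invalid("`data` must have columns `arm` and `value`.")
  }
  arms <- unique(data$arm)
  if (!setequal(arms, c("historical", "ni"))) {
    stop_data("`arm` must contain exactly the labels \"historical\" and \"ni\".")
  }
  list(historical = data$value[data$arm == "historical"],
       ni = data$value[data$arm == "ni"])
}

#' @export
print.gpq_draws <- function(x, ...) {
  cat(sprintf("gpq_draws: %d ratio-GPQ realizations (seed %s)\n",
              attr(x, "M"), format(attr(x, "seed"))))
  print(summary(unclass(x)))
  invisible(x)
}
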
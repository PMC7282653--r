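#' Summary-statistics tests of the fraction-retention hypothesis
#'
#' Apply Rothmann's test, Wang's test, or the ratio test to one or more
#' non-inferiority trial summaries. Each test addresses
#' `H0: delta <= delta0` versus `H1: delta > delta0`, where
#' `delta = theta1 / theta2` is the fraction of the historical control
#' effect (`theta2`, control vs placebo) retained by the new treatment
#' (`theta1`, treatment vs placebo), under the constancy assumption.
#'
#' The input carries, per trial, the estimated treatment-vs-control
#' difference in the NI trial (`mu_ni_hat`, e.g. a log hazard ratio) with
#' its standard deviation `sigma_ni`, and the historical control-vs-placebo
#' difference `mu_h_hat` with standard deviation `sigma_h`. Both standard
#' deviations are treated as known, matching the tests' normal-theory
#' derivations.
#'
#' The three statistics are, writing `m = mu_ni_hat`, `h = mu_h_hat`:
#' * Rothmann: `Z_R = (m - (1 - delta0) h) / sqrt(sigma_ni^2 +
#'   (1 - delta0)^2 sigma_h^2)`, with the p-value the lower standard-normal
#'   tail of `Z_R` (small `m` relative to `(1 - delta0) h` is evidence of
#'   retention).
#' * Wang: `W = ((1 - m/h) - delta0) / (sqrt(sigma_ni^2 +
#'   (1 - delta0)^2 sigma_h^2) / |h|)`, with an upper-tail p-value. For
#'   `h > 0` this is algebraically `-Z_R`, so the two p-values coincide.
#' * Ratio: `z = 1 - m/h`, the plug-in retention estimate, referred to the
#'   Cauchy-like null distribution [pcauchy_like()] with per-trial plug-in
#'   `b = h / sigma_h` and `r = sigma_ni / sigma_h`; p-value is the upper
#'   tail `1 - G(z)`.
#'
#' @param data a data frame with numeric columns `mu_ni_hat`, `sigma_ni`,
#'   `mu_h_hat`, `sigma_h` (one row per trial). Optional columns
#'   `study_id`, `delta0` and `alpha` are honoured; explicit arguments
#'   override the latter two.
#' @param delta0 retention fraction under test. Default 0.5 (the usual
#'   "retain at least half the control effect"); a `delta0` column in
#'   `data` is used when the argument is `NULL`.
#' @param alpha one-sided significance level; default 0.025, same column
#'   convention as `delta0`.
#' @param methods for [ni_test()], the subset of
#'   `c("rothmann", "wang", "ratio")` to run.
#'
#' @return A tibble of class `ni_test_result` with one row per trial (and
#'   per method for [ni_test()]): `study_id`, `method`, `statistic`,
#'   `p_value`, `reject`, `delta0`, `alpha`, plus `b_hat`, `r_hat`,
#'   `delta_hat` for the ratio test.
#'
#' @examples
#' xeloda_summary() |> ni_test(delta0 = 0.5)
#' @export
ni_test <- function(data, methods = c("rothmann", "wang", "ratio"),
                    delta0 = NULL, alpha = NULL) {
  methods <- match.arg(methods, c("rothmann", "wang", "ratio", "gpv"),
                       several.ok = TRUE)
  if ("gpv" %in% methods) {
    stop_data(paste(
      "The GPV test cannot be computed from summary statistics alone:",
      "it needs the per-arm observations (or their sample mean, variance",
      "and size). Use `gpv_test()` on raw arm data instead."))
  }
  force(data)
  fns <- list(rothmann = rothmann_test, wang = wang_test, ratio = ratio_test)
  out <- purrr::map(methods, function(m) {
    fns[[m]](data, delta0 = delta0, alpha = alpha)
  })
  new_ni_test_result(dplyr::bind_rows(out))
}

#' @rdname ni_test
#' @export
rothmann_test <- function(data, delta0 = NULL, alpha = NULL) {
  d <- prepare_summary(data, delta0, alpha)
  se <- sqrt(d$sigma_ni^2 + (1 - d$delta0)^2 * d$sigma_h^2)
  z <- (d$mu_ni_hat - (1 - d$delta0) * d$mu_h_hat) / se
  p <- pnorm(z)
  assemble_result(d, method = "rothmann", statistic = z, p_value = p)
}

#' @rdname ni_test
#' @export
wang_test <- function(data, delta0 = NULL, alpha = NULL) {
  d <- prepare_summary(data, delta0, alpha)
  check_nonzero_h(d)
  se <- sqrt(d$sigma_ni^2 + (1 - d$delta0)^2 * d$sigma_h^2) / abs(d$mu_h_hat)
  w <- ((1 - d$mu_ni_hat / d$mu_h_hat) - d$delta0) / se
  p <- pnorm(w, lower.tail = FALSE)
  assemble_result(d, method = "wang", statistic = w, p_value = p)
}

#' @rdname ni_test
#' @export
ratio_test <- function(data, delta0 = NULL, alpha = NULL) {
  d <- prepare_summary(data, delta0, alpha)
  check_nonzero_h(d)
  b_hat <- d$mu_h_hat / d$sigma_h
  r_hat <- d$sigma_ni / d$sigma_h
  z_hat <- 1 - d$mu_ni_hat / d$mu_h_hat
  p <- purrr::pmap_dbl(
    list(z_hat, b_hat, r_hat, d$delta0),
    function(z, b, r, d0) 1 - pcauchy_like(z, b = b, r = r, delta0 = d0))
  assemble_result(d, method = "ratio", statistic = z_hat, p_value = p,
                  extra = tibble(b_hat = b_hat, r_hat = r_hat,
                                 delta_hat = z_hat))
}

#' Plug-in standardized effects from trial summaries
#'
#' Augments a summary table with the plug-in estimates used by the ratio
#' test: `b_hat = mu_h_hat / sigma_h` (standardized historical control
#' effect), `r_hat = sigma_ni / sigma_h`, and the observed retention
#' `delta_hat = 1 - mu_ni_hat / mu_h_hat`.
#'
#' @inheritParams ni_test
#' @return the input as a tibble with columns `b_hat`, `r_hat`,
#'   `delta_hat` appended.
#' @examples
#' estimate_b_r(xeloda_summary())
#' @export
estimate_b_r <- function(data) {
  d <- prepare_summary(data, delta0 = NULL, alpha = NULL)
  as_tibble(data) |>
    dplyr::mutate(
      b_hat = d$mu_h_hat / d$sigma_h,
      r_hat = d$sigma_ni / d$sigma_h,
      delta_hat = 1 - d$mu_ni_hat / d$mu_h_hat)
}

summary_columns <- c("mu_ni_hat", "sigma_ni", "mu_h_hat", "sigma_h")

prepare_summary <- function(data, delta0, alpha) {
  if (!is.data.frame(data)) {
    stop_invalid("`data` must be a data frame of trial summaries.")
  }
  if (nrow(data) == 0L) stop_data("`data` has no rows.")
  missing_cols <- setdiff(summary_columns, names(data))
  if (length(missing_cols) > 0L) {
    stop_data(sprintf("`data` is missing required column(s): %s.",
                      paste(missing_cols, collapse = ", ")))
  }
  d <- as_tibble(data)
  for (col in summary_columns) {
    x <- d[[col]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      bad <- if (is.numeric(x)) which(!is.finite(x))[1] else 1L
      stop_data(sprintf("Column `%s` must be finite numeric (see row %d).",
                        col, bad))
    }
  }
  if (any(d$sigma_ni <= 0) || any(d$sigma_h <= 0)) {
    bad <- which(d$sigma_ni <= 0 | d$sigma_h <= 0)[1]
    stop_data(sprintf("Standard deviations must be positive (see row %d).",
                      bad))
  }
  d$delta0 <- resolve_param(delta0, d, "delta0", 0.5)
  d$alpha <- resolve_param(alpha, d, "alpha", 0.025)
  if (any(d$alpha <= 0 | d$alpha >= 1)) {
    stop_domain("`alpha` must lie strictly between 0 and 1.")
  }
  if (!"study_id" %in% names(d)) {
    d$study_id <- paste0("trial_", seq_len(nrow(d)))
  }
  d
}

resolve_param <- function(arg, d, name, default) {
  if (!is.null(arg)) {
    check_scalar_finite(arg, name)
    return(rep(arg, nrow(d)))
  }
  if (name %in% names(d)) {
    x <- d[[name]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      stop_data(sprintf("Column `%s` must be finite numeric.", name))
    }
    return(x)
  }
  rep(default, nrow(d))
}

check_nonzero_h <- function(d) {
  if (any(d$mu_h_hat == 0)) {
    bad <- which(d$mu_h_hat == 0)[1]
    stop_data(sprintf(
      "`mu_h_hat` is zero in row %d: the retention ratio is undefined.",
      bad))
  }
  invisible(NULL)
}

assemble_result <- function(d, method, statistic, p_value, extra = NULL,
                            mc_draws = NA_integer_, seed = NA_integer_) {
  out <- tibble(
    study_id = d$study_id,
    method = method,
    statistic = statistic,
    p_value = p_value,
    reject = p_value < d$alpha,
    delta0 = d$delta0,
    alpha = d$alpha,
    mc_draws = mc_draws,
    seed = seed)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  new_ni_test_result(out)
}

new_ni_test_result <- function(x) {
  class(x) <- c("ni_test_result", class(x))
  x
}
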
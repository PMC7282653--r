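#' Monte Carlo operating characteristics of the summary-statistics tests
#'
#' Estimates the rejection rate (type-I error when `delta_true = delta0`,
#' power otherwise) of Rothmann's, Wang's and/or the ratio test by drawing
#' estimator-level summaries: per replicate one
#' `mu_ni_hat ~ N(mu_ni, sigma_ni^2)` and one
#' `mu_h_hat ~ N(mu_h, sigma_h^2)`, where `sigma_h = mu_h / b`,
#' `sigma_ni = mu_h / b_over_r` and `mu_ni = mu_h (1 - delta_true)`.
#' The standard deviations are treated as known, as the tests assume; the
#' ratio test plugs in the per-replicate `b_hat = mu_h_hat / sigma_h` with
#' `r = sigma_ni / sigma_h` known.
#'
#' @param delta0 retention fraction under test.
#' @param delta_true true retention fraction generating the data; equal to
#'   `delta0` for type-I error, larger for power.
#' @param mu_h true historical control effect; default 0.24, a typical
#'   log-hazard-ratio-scale effect.
#' @param b standardized historical control effect `mu_h / sigma_h`.
#' @param b_over_r `mu_h / sigma_ni`, the historical effect scaled by the
#'   NI-trial difference SD.
#' @param n_reps number of simulation replicates; default 10000.
#' @param alpha one-sided level; default 0.025.
#' @param seed optional integer master seed.
#' @param methods subset of `c("rothmann", "wang", "ratio")`.
#'
#' @return a tibble of class `fracret_sim`, one row per method, with the
#'   cell parameters, `rejection_rate`, the binomial Monte Carlo standard
#'   error `mc_se = sqrt(rate (1 - rate) / n_reps)`, `n_reps` and `seed`.
#'
#' @examples
#' simulate_summary_tests(delta0 = 0.5, b = 2, b_over_r = 2,
#'                        n_reps = 200, seed = 1, methods = "rothmann")
#' @export
simulate_summary_tests <- function(delta0 = 0.5, delta_true = delta0,
                                   mu_h = 0.24, b, b_over_r,
                                   n_reps = 10000, alpha = 0.025,
                                   seed = NULL,
                                   methods = c("rothmann", "wang", "ratio")) {
  methods <- match.arg(methods, c("rothmann", "wang", "ratio", "gpv"),
                       several.ok = TRUE)
  if ("gpv" %in% methods) {
    stop_invalid(paste(
      "The GPV test operates on per-arm samples, not estimator-level",
      "summaries; use `simulate_gpv()` for its operating characteristics."))
  }
  check_scalar_finite(delta0, "delta0")
  check_scalar_finite(delta_true, "delta_true")
  check_positive(mu_h, "mu_h")
  check_positive(b, "b")
  check_positive(b_over_r, "b_over_r")
  n_reps <- check_count(n_reps, "n_reps")
  check_prob_open(alpha, "alpha")

  sigma_h <- mu_h / b
  sigma_ni <- mu_h / b_over_r
  mu_ni <- mu_h * (1 - delta_true)
  r <- sigma_ni / sigma_h

  seed_stream(seed, 1L)
  m_hat <- rnorm(n_reps, mu_ni, sigma_ni)
  h_hat <- rnorm(n_reps, mu_h, sigma_h)

  se <- sqrt(sigma_ni^2 + (1 - delta0)^2 * sigma_h^2)
  rates <- vapply(methods, function(method) {
    rej <- switch(method,
      rothmann = pnorm((m_hat - (1 - delta0) * h_hat) / se) < alpha,
      wang = {
        w <- ((1 - m_hat / h_hat) - delta0) / (se / abs(h_hat))
        pnorm(w, lower.tail = FALSE) < alpha
      },
      ratio = {
        z_hat <- 1 - m_hat / h_hat
        b_hat <- h_hat / sigma_h
        vapply(seq_len(n_reps), function(i) {
          p <- 1 - pcauchy_like(z_hat[i], b = b_hat[i], r = r,
                                delta0 = delta0)
          p < alpha
        }, logical(1))
      })
    mean(rej)
  }, numeric(1))
  rates <- unname(rates)

  new_sim_result(tibble(
    method = methods,
    delta0 = delta0, delta_true = delta_true, mu_h = mu_h,
    b = b, b_over_r = b_over_r,
    n_h = NA_integer_, n_ni = NA_integer_,
    alpha = alpha, n_reps = n_reps, gpq_draws = NA_integer_,
    rejection_rate = rates,
    mc_se = sqrt(rates * (1 - rates) / n_reps),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Monte Carlo operating characteristics of the GPV test
#'
#' Estimates the rejection rate of the generalized-p-value test. Per
#' replicate, `n_h` observations are drawn from
#' `N(mu_h, sigma_h^2)` and `n_ni` from `N(mu_ni, sigma_ni^2)` with
#' per-observation standard deviations `sigma_h = mu_h / b` and
#' `sigma_ni = mu_h / b_over_r` and `mu_ni = mu_h (1 - delta_true)`; the
#' GPV test is then run on the replicate's sample statistics with
#' `gpq_draws` Monte Carlo GPQ realizations.
#'
#' @inheritParams simulate_summary_tests
#' @param n_h,n_ni per-arm sample sizes; default 30.
#' @param gpq_draws GPQ draws `M` per replicate; default 10000.
#'
#' @return a one-row `fracret_sim` tibble (`method = "gpv"`) with
#'   `rejection_rate`, `mc_se`, the cell parameters and `seed`.
#'
#' @examples
#' simulate_gpv(delta0 = 0.5, b = 2, b_over_r = 2, n_reps = 50,
#'              gpq_draws = 200, seed = 1)
#' @export
simulate_gpv <- function(delta0 = 0.5, delta_true = delta0, mu_h = 0.24,
                         b, b_over_r, n_h = 30, n_ni = 30,
                         n_reps = 10000, gpq_draws = 10000,
                         alpha = 0.025, seed = NULL) {
  check_scalar_finite(delta0, "delta0")
  check_scalar_finite(delta_true, "delta_true")
  check_positive(mu_h, "mu_h")
  check_positive(b, "b")
  check_positive(b_over_r, "b_over_r")
  n_h <- check_count(n_h, "n_h", min = 2L)
  n_ni <- check_count(n_ni, "n_ni", min = 2L)
  n_reps <- check_count(n_reps, "n_reps")
  gpq_draws <- check_count(gpq_draws, "gpq_draws")
  check_prob_open(alpha, "alpha")

  sigma_h <- mu_h / b
  sigma_ni <- mu_h / b_over_r
  mu_ni <- mu_h * (1 - delta_true)
  boundary <- 1 - delta0

  rej <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    seed_stream(rep_seed, 5L)
    x_h <- rnorm(n_h, mu_h, sigma_h)
    y_ni <- rnorm(n_ni, mu_ni, sigma_ni)
    draws <- sample_gpq_ratio(summarize_arm(x_h), summarize_arm(y_ni),
                              M = gpq_draws, seed = rep_seed)
    rej[i] <- gpv_pvalue(draws, delta0) < alpha
  }
  rate <- mean(rej)

  new_sim_result(tibble(
    method = "gpv",
    delta0 = delta0, delta_true = delta_true, mu_h = mu_h,
    b = b, b_over_r = b_over_r,
    n_h = n_h, n_ni = n_ni,
    alpha = alpha, n_reps = n_reps, gpq_draws = gpq_draws,
    rejection_rate = rate,
    mc_se = sqrt(rate * (1 - rate) / n_reps),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Run a grid of simulation cells
#'
#' Maps [simulate_summary_tests()] / [simulate_gpv()] over the rows of a
#' specification table, deriving one reproducible seed per cell from a
#' single master seed, and returns one tidy table keyed by
#' `(delta0, delta_true, b, b_over_r, n, method)`.
#'
#' @param grid a data frame with one simulation cell per row. Required
#'   columns: `method` (one of rothmann, wang, ratio, gpv), `delta0`, `b`,
#'   `b_over_r`. Optional: `delta_true` (defaults to `delta0`), `mu_h`
#'   (0.24), `n_h`/`n_ni` (30, GPV only), `n_reps` (10000), `gpq_draws`
#'   (10000, GPV only), `alpha` (0.025).
#' @param master_seed integer; cell seeds are derived from it by position,
#'   so cells are reproducible independently of each other.
#'
#' @return a `fracret_sim` tibble with one row per cell.
#'
#' @examples
#' grid <- tidyr::crossing(method = c("rothmann", "gpv"),
#'                         delta0 = 0.5, b = 2, b_over_r = c(2, 4))
#' run_grid(dplyr::mutate(grid, n_reps = 50, gpq_draws = 100),
#'          master_seed = 1)
#' @export
run_grid <- function(grid, master_seed = 1L) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop_domain("`grid` must be a data frame with at least one row.")
  }
  required <- c("method", "delta0", "b", "b_over_r")
  missing_cols <- setdiff(required, names(grid))
  if (length(missing_cols) > 0L) {
    stop_data(sprintf("`grid` is missing column(s): %s.",
                      paste(missing_cols, collapse = ", ")))
  }
  g <- as_tibble(grid)
  col_or <- function(name, default) {
    if (name %in% names(g)) g[[name]] else rep(default, nrow(g))
  }
  delta_true <- col_or("delta_true", NA_real_)
  mu_h <- col_or("mu_h", 0.24)
  n_h <- col_or("n_h", 30)
  n_ni <- col_or("n_ni", 30)
  n_reps <- col_or("n_reps", 10000)
  gpq_draws <- col_or("gpq_draws", 10000)
  alpha <- col_or("alpha", 0.025)

  rows <- purrr::map(seq_len(nrow(g)), function(i) {
    cell_seed <- derive_seed(master_seed, i)
    dt <- if (is.na(delta_true[i])) g$delta0[i] else delta_true[i]
    if (g$method[i] == "gpv") {
      simulate_gpv(delta0 = g$delta0[i], delta_true = dt, mu_h = mu_h[i],
                   b = g$b[i], b_over_r = g$b_over_r[i],
                   n_h = n_h[i], n_ni = n_ni[i], n_reps = n_reps[i],
                   gpq_draws = gpq_draws[i], alpha = alpha[i],
                   seed = cell_seed)
    } else {
      simulate_summary_tests(delta0 = g$delta0[i], delta_true = dt,
                             mu_h = mu_h[i], b = g$b[i],
                             b_over_r = g$b_over_r[i], n_reps = n_reps[i],
                             alpha = alpha[i], seed = cell_seed,
                             methods = g$method[i])
    }
  })
  new_sim_result(dplyr::bind_rows(rows))
}

#' Standard simulation grids
#'
#' `type1_error_grid()` builds the null-boundary grid used to check size:
#' retention levels `delta0` crossed with standardized control effects `b`
#' and `b_over_r`, every cell at `delta_true = delta0`.
#' `power_grid()` builds the equal-sample-size grid used to study the GPV
#' test's size and power together: per-arm sizes `n` crossed with
#' `b_over_r` at fixed `b`, each cell once at the null
#' (`delta_true = delta0`) and once at the alternative
#' (`delta_true = delta1`).
#'
#' @param delta0 retention levels.
#' @param b,b_over_r standardized-effect grids.
#' @param methods which tests to include (one row per method per cell).
#' @param n per-arm sample sizes (GPV grid).
#' @param delta1 alternative retention fraction; default 0.625.
#' @param n_reps,gpq_draws Monte Carlo sizes applied to every cell.
#' @param alpha one-sided level.
#' @return a tibble ready for [run_grid()].
#' @examples
#' nrow(type1_error_grid(methods = "gpv"))  # 45 cells
#' @export
type1_error_grid <- function(delta0 = c(0.5, 0.7, 0.9, 1.1, 1.2),
                             b = c(2, 3, 4), b_over_r = c(2, 4, 8),
                             methods = c("rothmann", "wang", "ratio", "gpv"),
                             n_reps = 10000, gpq_draws = 10000,
                             alpha = 0.025) {
  tidyr::crossing(method = methods, delta0 = delta0, b = b,
                  b_over_r = b_over_r) |>
    dplyr::mutate(delta_true = .data$delta0, n_reps = n_reps,
                  gpq_draws = gpq_draws, alpha = alpha)
}

#' @rdname type1_error_grid
#' @export
power_grid <- function(n = c(30, 40, 50), b = 2, b_over_r = c(2, 4, 8),
                       delta0 = 0.5, delta1 = 0.625, methods = "gpv",
                       n_reps = 10000, gpq_draws = 10000, alpha = 0.025) {
  tidyr::crossing(method = methods, n = n, b = b, b_over_r = b_over_r,
                  delta_true = c(delta0, delta1)) |>
    dplyr::mutate(delta0 = delta0, n_h = .data$n, n_ni = .data$n,
                  n_reps = n_reps, gpq_draws = gpq_draws, alpha = alpha) |>
    dplyr::select(-"n")
}

new_sim_result <- function(x) {
  class(x) <- unique(c("fracret_sim", class(x)))
  x
}
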
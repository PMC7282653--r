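#' Tidiers for test and simulation results
#'
#' `tidy()` returns the result as a plain tibble, one row per test or
#' simulation cell. `glance()` condenses a result set to a single row.
#'
#' @param x an `ni_test_result` or `fracret_sim` object.
#' @param ... unused, for generic consistency.
#'
#' @return a tibble.
#' @name fracret-tidiers
NULL

#' @rdname fracret-tidiers
#' @export
tidy.ni_test_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ni_test_result")
  out
}

#' @rdname fracret-tidiers
#' @export
glance.ni_test_result <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_reject = sum(x$reject),
    n_methods = length(unique(x$method)),
    min_p_value = min(x$p_value),
    alpha = if (length(unique(x$alpha)) == 1L) x$alpha[1] else NA_real_)
}

#' @rdname fracret-tidiers
#' @export
tidy.fracret_sim <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "fracret_sim")
  out
}

#' @rdname fracret-tidiers
#' @export
glance.fracret_sim <- function(x, ...) {
  null_cells <- x$delta_true == x$delta0
  tibble(
    n_cells = nrow(x),
    n_methods = length(unique(x$method)),
    max_type1_error = if (any(null_cells)) {
      max(x$rejection_rate[null_cells])
    } else NA_real_,
    max_power = if (any(!null_cells)) {
      max(x$rejection_rate[!null_cells])
    } else NA_real_,
    total_reps = sum(x$n_reps))
}

#' @rdname fracret-tidiers
#' @export
tidy.gpq_draws <- function(x, ...) {
  tibble(draw = seq_along(x), ratio = as.numeric(x))
}

#' @rdname fracret-tidiers
#' @export
glance.gpq_draws <- function(x, ...) {
  v <- as.numeric(x)
  tibble(
    M = attr(x, "M"),
    seed = attr(x, "seed"),
    median = stats::median(v),
    q2.5 = stats::quantile(v, 0.025, names = FALSE),
    q97.5 = stats::quantile(v, 0.975, names = FALSE),
    prop_infinite = mean(is.infinite(v)))
}
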
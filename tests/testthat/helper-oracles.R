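# Independent brute-force oracles and shared fixtures.

# Monte Carlo estimate of P((a + X)/(b + Y) <= t): the sampling oracle for
# the integrated ratio-of-normals CDF.
mc_ratio_cdf <- function(t, a, b, n = 1e5, seed = 1) {
  set.seed(seed)
  w <- (a + rnorm(n)) / (b + rnorm(n))
  p <- mean(w <= t)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# The six Xeloda summary rows with the p-values printed for them, used to
# check the closed-form and integrated tests against published results.
xeloda_printed <- function() {
  dplyr::mutate(
    xeloda_summary(),
    p_rothmann = c(0.1010, 0.0165, 0.0129, 0.0891, 0.0129, 0.0083),
    p_wang = c(0.1009, 0.0164, 0.0128, 0.0890, 0.0128, 0.0083),
    p_ratio = c(0.0830, 0.0140, 0.0062, 0.0774, 0.0110, 0.0044),
    b_hat_4dp = rep(c(3.1213, 4.0438), each = 3),
    r_hat_4dp = c(1.1573, 1.1560, 0.8173, 1.4637, 1.4621, 1.0337))
}

# Random valid summary tables for property-style checks.
random_summary <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    study_id = paste0("s", seq_len(n)),
    mu_ni_hat = rnorm(n, 0, 0.2),
    sigma_ni = runif(n, 0.02, 0.3),
    mu_h_hat = runif(n, 0.05, 0.5),
    sigma_h = runif(n, 0.02, 0.3))
}

# Absolute-tolerance comparison (testthat tolerances are relative, which is
# far too strict for p-values printed to 4 decimal places).
expect_within <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)), tol)
}
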
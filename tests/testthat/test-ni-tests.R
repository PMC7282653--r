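# Summary-statistics tests: published Xeloda values, algebraic identities,
# monotonicity, and input validation.

test_that("Rothmann and Wang p-values reproduce the published Xeloda rows", {
  px <- xeloda_printed()
  r <- rothmann_test(px)
  w <- wang_test(px)
  expect_within(r$p_value, px$p_rothmann, 2e-4)
  expect_within(w$p_value, px$p_wang, 2e-4)
  expect_equal(r$reject, px$p_rothmann < 0.025)
})

test_that("ratio test reproduces the published Xeloda rows", {
  px <- xeloda_printed()
  res <- ratio_test(px)
  expect_within(res$p_value, px$p_ratio, 2e-4)
  expect_equal(res$statistic, 1 - px$mu_ni_hat / px$mu_h_hat)
})

test_that("plug-in standardized effects match the published values to 4 dp", {
  est <- estimate_b_r(xeloda_summary())
  px <- xeloda_printed()
  expect_equal(round(est$b_hat, 4), px$b_hat_4dp)
  expect_equal(round(est$r_hat, 4), px$r_hat_4dp)
  # retention estimates delta_hat = 1 - mu_ni_hat/mu_h_hat, printed for the
  # 10-trial meta-analysis rows
  expect_equal(round(est$delta_hat[1:3], 4), c(1.0154, 1.3605, 1.1845))
})

test_that("Wang and Rothmann p-values coincide whenever mu_h_hat > 0", {
  d <- random_summary(50, seed = 5)
  pr <- rothmann_test(d, delta0 = 0.5)$p_value
  pw <- wang_test(d, delta0 = 0.5)$p_value
  expect_equal(pw, pr, tolerance = 1e-12)
  # also across delta0 values
  for (d0 in c(0.3, 0.7, 0.9)) {
    expect_equal(wang_test(d, delta0 = d0)$p_value,
                 rothmann_test(d, delta0 = d0)$p_value, tolerance = 1e-12)
  }
})

test_that("boundary summaries give a null p-value of one half", {
  d <- tibble::tibble(mu_ni_hat = 0.5 * 0.3, sigma_ni = 0.1,
                      mu_h_hat = 0.3, sigma_h = 0.1)
  r <- rothmann_test(d, delta0 = 0.5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5)
})

test_that("Rothmann p is monotone in the summary estimates", {
  base <- list(sigma_ni = 0.08, sigma_h = 0.07)
  h_grid <- seq(0.1, 0.5, by = 0.05)
  p_h <- vapply(h_grid, function(h) {
    rothmann_test(tibble::tibble(mu_ni_hat = -0.05, sigma_ni = base$sigma_ni,
                                 mu_h_hat = h, sigma_h = base$sigma_h),
                  delta0 = 0.5)$p_value
  }, numeric(1))
  expect_true(all(diff(p_h) < 0))
  m_grid <- seq(-0.2, 0.2, by = 0.05)
  p_m <- vapply(m_grid, function(m) {
    rothmann_test(tibble::tibble(mu_ni_hat = m, sigma_ni = base$sigma_ni,
                                 mu_h_hat = 0.3, sigma_h = base$sigma_h),
                  delta0 = 0.5)$p_value
  }, numeric(1))
  expect_true(all(diff(p_m) > 0))
})

test_that("ratio test inverts its own critical value", {
  d0 <- 0.5; alpha <- 0.025
  b_hat <- 0.2341 / 0.0750; r_hat <- 0.0868 / 0.0750
  z_star <- qcauchy_like(1 - alpha, b = b_hat, r = r_hat, delta0 = d0)
  # build a summary whose statistic lands exactly on the critical value
  mu_h <- 0.2341
  d <- tibble::tibble(mu_ni_hat = (1 - z_star) * mu_h, sigma_ni = 0.0868,
                      mu_h_hat = mu_h, sigma_h = 0.0750)
  expect_equal(ratio_test(d, delta0 = d0, alpha = alpha)$p_value, alpha,
               tolerance = 1e-6)
})

test_that("ratio test p agrees with a pure Monte Carlo tail estimate", {
  d <- tibble::tibble(mu_ni_hat = -0.0432, sigma_ni = 0.0613,
                      mu_h_hat = 0.2398, sigma_h = 0.0593)
  res <- ratio_test(d, delta0 = 0.5)
  draws <- rcauchy_like(1e6, b = 0.2398 / 0.0593, r = 0.0613 / 0.0593,
                        delta0 = 0.5, seed = 31)
  p_mc <- mean(draws > res$statistic)
  expect_lt(abs(res$p_value - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / 1e6))
})

test_that("decisions are consistent with p < alpha and inputs validated", {
  d <- random_summary(20, seed = 9)
  res <- ni_test(d, delta0 = 0.4, alpha = 0.1)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_identical(res$reject, res$p_value < res$alpha)
  # per-row delta0/alpha columns are honoured when arguments are omitted
  d2 <- dplyr::mutate(d, delta0 = 0.3, alpha = 0.2)
  res2 <- rothmann_test(d2)
  expect_identical(unique(res2$delta0), 0.3)
  expect_identical(res2$reject, res2$p_value < 0.2)

  zero_h <- tibble::tibble(mu_ni_hat = 0.1, sigma_ni = 0.1,
                           mu_h_hat = 0, sigma_h = 0.1)
  expect_error(wang_test(zero_h), class = "fracret_data_error")
  expect_error(ratio_test(zero_h), class = "fracret_data_error")
  expect_error(rothmann_test(dplyr::select(d, -"sigma_h")),
               class = "fracret_data_error")
  expect_error(rothmann_test(dplyr::mutate(d, sigma_ni = -1)),
               class = "fracret_data_error")
  expect_error(ni_test(d, methods = "gpv"), class = "fracret_data_error")
})
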
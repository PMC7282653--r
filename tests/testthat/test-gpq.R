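# Generalized pivotal quantities and the GPV test.

test_that("arm summaries are computed with the n-1 divisor", {
  s <- summarize_arm(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$variance, 0)
  expect_equal(s$n, 3L)
  s2 <- summarize_arm(c(0, 2))
  expect_equal(s2$mean, 1)
  expect_equal(s2$variance, 2)
  x <- rnorm(20)
  expect_equal(summarize_arm(x), summarize_arm(rev(sample(x))))
  expect_error(summarize_arm(1), class = "fracret_data_error")
  expect_error(summarize_arm(c(1, NA)), class = "fracret_data_error")
  expect_error(arm_stats(0, -1, 5), class = "fracret_invalid_parameter")
})

test_that("mean GPQ draws center on the observed mean", {
  # E[R_mu] = xbar because Z has mean 0 independently of the scale factor
  st <- arm_stats(mean = 0.24, variance = 0.0144, n = 30)
  dr <- sample_gpq_mu(st, M = 1e6, seed = 3)
  expect_lt(abs(mean(dr) - 0.24), 3 * sd(dr) / sqrt(1e6))
  # zero variance degenerates to the mean exactly
  dr0 <- sample_gpq_mu(arm_stats(0.5, 0, 10), M = 100, seed = 1)
  expect_identical(dr0, rep(0.5, 100))
  # determinism
  expect_identical(sample_gpq_mu(st, 1000, seed = 9),
                   sample_gpq_mu(st, 1000, seed = 9))
})

test_that("ratio GPQ streams are mutually independent and seeded", {
  st_h <- arm_stats(0.24, 0.0144, 30)
  # with a degenerate NI arm of mean 1 the ratio draws are exactly 1/R_muH,
  # which must coincide with the separately seeded mean-GPQ stream
  r <- sample_gpq_ratio(st_h, arm_stats(1, 0, 5), M = 500, seed = 11)
  expect_equal(1 / as.numeric(r), sample_gpq_mu(st_h, 500, seed = 11))
  # changing the NI arm leaves the historical stream untouched
  r2 <- sample_gpq_ratio(st_h, arm_stats(2, 0, 7), M = 500, seed = 11)
  expect_equal(2 / as.numeric(r2), 1 / as.numeric(r))
  # both arms degenerate: all draws equal the mean ratio
  rd <- sample_gpq_ratio(arm_stats(0.24, 0, 4), arm_stats(0.12, 0, 4),
                         M = 50, seed = 2)
  expect_identical(as.numeric(rd), rep(0.5, 50))
  expect_identical(attr(rd, "M"), 50L)
})

test_that("GPV p-value tail conventions hold", {
  expect_equal(gpv_pvalue(c(0.1, 0.2, 0.3), delta0 = 0.5), 0)
  expect_equal(gpv_pvalue(rep(0.5, 10), delta0 = 0.5), 1)   # ties in tail
  expect_equal(gpv_pvalue(c(0.2, 0.8, Inf, -Inf), delta0 = 0.5), 0.5)
  expect_error(gpv_pvalue(numeric(0), 0.5),
               class = "fracret_invalid_parameter")
})

test_that("GPV test is reproducible and rejects clear retention", {
  set.seed(4)
  h <- rnorm(30, 0.24, 0.02)
  ni <- rnorm(30, -0.004, 0.02)
  r1 <- gpv_test(h = h, ni = ni, delta0 = 0.5, M = 4000, seed = 21)
  r2 <- gpv_test(h = h, ni = ni, delta0 = 0.5, M = 4000, seed = 21)
  expect_identical(r1, r2)
  expect_lt(r1$p_value, 0.01)
  expect_true(r1$reject)
  expect_identical(r1$mc_draws, 4000L)
  expect_identical(r1$seed, 21L)
  # degenerate arms sitting exactly on the boundary never reject
  r0 <- gpv_test(h = arm_stats(0.24, 0, 5), ni = arm_stats(0.12, 0, 5),
                 delta0 = 0.5, M = 100, seed = 1)
  expect_equal(r0$p_value, 1)
  expect_false(r0$reject)
})

test_that("GPV p-value is invariant to joint rescaling of both arms", {
  set.seed(6)
  h <- rnorm(25, 0.3, 0.1)
  ni <- rnorm(20, 0.1, 0.15)
  p1 <- gpv_test(h = h, ni = ni, M = 2000, seed = 17)$p_value
  for (c0 in c(0.2, 3, 117)) {
    p2 <- gpv_test(h = c0 * h, ni = c0 * ni, M = 2000, seed = 17)$p_value
    # exact up to floating-point rounding of draws sitting on the boundary
    expect_lt(abs(p2 - p1), 2 / 2000)
  }
})

test_that("GPV p-value is nondecreasing in the NI-arm mean", {
  set.seed(8)
  h <- rnorm(30, 0.24, 0.12)
  ni0 <- rnorm(30, 0, 0.12)
  ni0 <- ni0 - mean(ni0)  # exactly centred so shifts set the mean directly
  shifts <- seq(-0.1, 0.25, by = 0.05)
  p <- vapply(shifts, function(s) {
    gpv_test(h = h, ni = ni0 + s, M = 3000, seed = 33)$p_value
  }, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("95% GPQ intervals for the ratio cover the true value", {
  set.seed(99)
  hits <- 0L
  n_rep <- 2000L
  for (i in seq_len(n_rep)) {
    xh <- rnorm(30, 0.24, 0.12)
    yn <- rnorm(30, 0.12, 0.12)
    dr <- sample_gpq_ratio(summarize_arm(xh), summarize_arm(yn),
                           M = 1000, seed = 7000 + i)
    q <- quantile(dr, c(0.025, 0.975), names = FALSE)
    hits <- hits + (q[1] <= 0.5 && 0.5 <= q[2])
  }
  # binomial 3-SE band around nominal 95% plus slack for the GPQ's own
  # finite-sample approximation
  expect_lt(abs(hits / n_rep - 0.95), 0.02)
})

test_that("long-format input and malformed arms are handled", {
  set.seed(10)
  d <- tibble::tibble(arm = rep(c("historical", "ni"), each = 10),
                      value = c(rnorm(10, 0.3, 0.1), rnorm(10, 0.1, 0.1)))
  res <- gpv_test(d, M = 500, seed = 2)
  direct <- gpv_test(h = d$value[1:10], ni = d$value[11:20], M = 500,
                     seed = 2)
  expect_equal(res$p_value, direct$p_value)
  expect_error(gpv_test(dplyr::mutate(d, arm = "x")),
               class = "fracret_data_error")
  expect_error(gpv_test(), class = "fracret_invalid_parameter")
  expect_error(gpv_test(h = 1:5, ni = 1:5, M = 0),
               class = "fracret_domain_error")
})
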
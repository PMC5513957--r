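test_that("parameter validation rejects degenerate settings", {
  expect_error(sim_params(slope = -5, n = 1, k = 10, sdR = 75), "n")
  expect_error(sim_params(slope = -5, n = 10, k = 0, sdR = 75), "k")
  expect_error(sim_params(slope = -5, n = 10, k = 10, sdR = -1), "sdR")
  expect_error(sim_params(slope = -5, n = 10, k = 10, sdR = 75,
                          sigma_log = 0), "sigma_log")
  expect_error(sim_params(slope = -5, n = 10, k = 10, sdR = 75,
                          magnitudes = c(1, 2)), "magnitudes")
  expect_error(sim_params(slope_a = -2, n = 10, k = 10, sdR = 75), "slope_b")
  expect_error(sample_error(0, 75), "count")
  expect_error(sample_error(10, 0), "sdR")
  expect_error(sample_error(10, 75, sigma_log = -1), "sigma_log")
})

test_that("error draws have mean 0, SD sdR, positive skew, finite lower bound", {
  set.seed(101)
  e <- sample_error(5e5, sdR = 75, sigma_log = 0.5)
  expect_lt(abs(mean(e)), 4 * 75 / sqrt(5e5))
  expect_lt(abs(sd(e) - 75), 1)
  skew <- mean((e - mean(e))^3) / sd(e)^3
  expect_gt(skew, 0.5)
  bound <- error_lower_bound(75, 0.5)
  expect_lt(bound, 0)
  expect_gt(min(e), bound)
})

test_that("lognormal rescaling matches the closed-form moment formula", {
  # Var(L) = exp(2 mu + sigma^2)(exp(sigma^2) - 1) with mu = 0 gives
  # s = sdR / sqrt(exp(2 sigma^2) - exp(sigma^2))
  s_expected <- 75 / sqrt(exp(2 * 0.25) - exp(0.25))
  expect_equal(snarcpower:::lognorm_scale(75, 0.5), s_expected)
  expect_equal(error_lower_bound(75, 0.5), -s_expected * exp(0.25 / 2))
  # and the construction's SD is exact for other shapes too
  for (sig in c(0.25, 0.5, 1)) {
    s <- snarcpower:::lognorm_scale(30, sig)
    var_l <- exp(2 * sig^2) - exp(sig^2)
    expect_equal(s^2 * var_l, 30^2)
  }
})

test_that("subject trials follow the slope model exactly when noise is off", {
  p <- sim_params(slope = -4, n = 10, k = 2, sdR = 75)
  tr <- simulate_subject(p, errors = 0)
  expect_equal(dim(tr), c(2L, 10L, 2L))
  expect_equal(unname(tr[1, "9", "right"]), 482)
  expect_equal(unname(tr[1, "9", "left"]), 518)
  expect_equal(unname(tr[2, "9", "right"] - tr[2, "9", "left"]), -36)
  p0 <- sim_params(slope = 0, n = 10, k = 3, sdR = 75)
  tr0 <- simulate_subject(p0, errors = 0)
  expect_true(all(tr0 == 500))
})

test_that("a simulated sample is complete and seed-reproducible", {
  p <- sim_params(slope = -5, n = 10, k = 7, sdR = 150, magnitudes = 1:9)
  set.seed(5)
  s1 <- simulate_sample(p)
  expect_length(s1, 10)
  expect_true(all(vapply(s1, length, integer(1)) == 2 * 9 * 7))
  set.seed(5)
  s2 <- simulate_sample(p)
  expect_identical(s1, s2)
  set.seed(6)
  s3 <- simulate_sample(p)
  expect_false(identical(s1[[1]], s3[[1]]))
})

test_that("expected dRT equals slope times magnitude; cell-mean variance is sdR^2/k", {
  p <- sim_params(slope = -4, n = 10, k = 5, sdR = 75)
  set.seed(202)
  drts <- vapply(seq_len(1500), function(i) drt_profile(simulate_subject(p)),
                 numeric(10))
  avg <- rowMeans(drts)
  se <- sqrt(2 * 75^2 / 5 / 1500)   # Var(dRT(m)) = 2 sdR^2 / k
  expect_true(all(abs(avg - (0:9) * -4) < 4 * se))
  v <- apply(drts, 1, var)
  expect_true(all(abs(v / (2 * 75^2 / 5) - 1) < 0.25))
})

test_that("slope estimates are unbiased for the generative slope", {
  p <- sim_params(slope = -5, n = 10, k = 20, sdR = 75)
  set.seed(303)
  est <- snarcpower:::simulate_slope_estimates(-5, 2000, 20, 75, 0.5, 0:9)
  se <- theory_slope_sd(75, 20) / sqrt(2000)
  expect_lt(abs(mean(est) - (-5)), 3 * se)
})
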
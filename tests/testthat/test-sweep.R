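test_that("grid enumeration is the full Cartesian product in fixed order", {
  spec <- sim1_grid_spec(10, seed = 1)
  cells <- enumerate_grid(spec)
  expect_equal(nrow(cells), 256)
  expect_equal(cells$cell, 1:256)
  # slope varies fastest
  expect_equal(cells$slope_or_sld[1:4], c(-7, -5, -3, -1))
  expect_equal(anyDuplicated(cells[-1]), 0)

  one <- power_grid_spec("one_group", slopes = -3, n = 20, k = 20, sdR = 150,
                         replications = 5, seed = 1)
  expect_equal(nrow(enumerate_grid(one)), 1)

  # extended plot grid: 12 k-levels x 9 n-levels x 4 slopes x 4 sdR
  plot_spec <- power_grid_spec(
    "one_group", slopes = c(-7, -5, -3, -1),
    n = c(10, 12, 14, 16, 18, 20, 30, 40, 50), k = seq(10, 120, by = 10),
    sdR = c(75, 150, 225, 300), replications = 10, seed = 1)
  expect_equal(nrow(enumerate_grid(plot_spec)), 12 * 9 * 4 * 4)

  expect_error(power_grid_spec("one_group", slopes = numeric(0), n = 10,
                               k = 10, sdR = 75), "non-empty")
  expect_error(power_grid_spec("two_group", slopes = c(-3), n = 10,
                               k = 10, sdR = 75), "slope_diffs")
})

test_that("power estimates follow the binomial formulas", {
  p <- sim_params(slope = -7, n = 10, k = 10, sdR = 75)
  out <- run_cell_one_group(p, replications = 20, seed = 9)
  pe <- power_estimate(out, 0.05)
  expect_equal(unname(pe["power"]), mean(out$sig[, "0.05"]))
  expect_equal(unname(pe["mc_se"]),
               sqrt(pe[["power"]] * (1 - pe[["power"]]) / 20))
  expect_error(power_estimate(out, 0.2), "not coded")
  # hand cases through the same formulas
  expect_equal(unname(sqrt(0.5 * 0.5 / 1000)), 0.0158, tolerance = 1e-3)
})

test_that("vectorized cell runners reproduce the subject-level pipeline", {
  p <- sim_params(slope = -3, n = 8, k = 5, sdR = 150)
  out <- run_cell_one_group(p, replications = 15, seed = 42)
  set.seed(42)
  p_naive <- replicate(15, {
    one_sample_snarc_test(sample_slopes(simulate_sample(p)))$p_value
  })
  expect_equal(out$p_values, p_naive, tolerance = 1e-10)

  p2 <- sim_params(slope_a = -2, slope_b = 2, n = 6, k = 4, sdR = 75)
  out2 <- run_cell_two_group(p2, replications = 15, seed = 42)
  set.seed(42)
  p_naive2 <- replicate(15, {
    pa <- sim_params(slope = p2$slope_a, n = 6, k = 4, sdR = 75)
    pb <- sim_params(slope = p2$slope_b, n = 6, k = 4, sdR = 75)
    two_sample_slope_test(sample_slopes(simulate_sample(pa)),
                          sample_slopes(simulate_sample(pb)))$p_value
  })
  expect_equal(out2$p_values, p_naive2, tolerance = 1e-10)
})

test_that("runs are seed-reproducible and cells re-run identically in isolation", {
  spec <- power_grid_spec("one_group", slopes = c(-5, -3), n = c(10, 20),
                          k = 10, sdR = 150, replications = 30, seed = 123)
  r1 <- run_grid(spec)
  r2 <- run_grid(spec)
  expect_identical(r1$power, r2$power)
  expect_identical(r1$outcomes, r2$outcomes)

  # cell 3 of the grid, re-run on its own derived substream
  cells <- enumerate_grid(spec)
  row <- cells[3, ]
  p <- sim_params(slope = row$slope_or_sld, n = row$n, k = row$k,
                  sdR = row$sdR)
  iso <- run_cell_one_group(p, 30, spec$alphas,
                            derive_cell_seed(spec$seed, 3))
  in_grid <- r1$outcomes[r1$outcomes$slope_or_sld == row$slope_or_sld &
                           r1$outcomes$n == row$n, ]
  expect_equal(unname(iso$sig[, "0.05"]), in_grid$sig_05)

  # a different master seed changes the raw outcomes
  spec_b <- power_grid_spec("one_group", slopes = c(-5, -3), n = c(10, 20),
                            k = 10, sdR = 150, replications = 30, seed = 124)
  r3 <- run_grid(spec_b)
  expect_false(identical(r1$outcomes, r3$outcomes))
})

test_that("two-group power is invariant to a common slope shift", {
  a <- sim_params(slope_a = -2, slope_b = 2, n = 10, k = 10, sdR = 150)
  b <- sim_params(slope_a = -6, slope_b = -2, n = 10, k = 10, sdR = 150)
  oa <- run_cell_two_group(a, 200, seed = 31)
  ob <- run_cell_two_group(b, 200, seed = 31)
  expect_equal(oa$p_values, ob$p_values, tolerance = 1e-9)
})

test_that("long outcome table has one row per cell and replication", {
  spec <- power_grid_spec("two_group", slope_diffs = c(2, 8), n = 10, k = 10,
                          sdR = c(75, 300), replications = 25, seed = 5)
  res <- run_grid(spec)
  expect_equal(nrow(res$outcomes), 4 * 25)
  expect_named(res$outcomes, c("mode", "slope_or_sld", "n", "k", "sdR",
                               "replication", "sig_05", "sig_01", "sig_001"))
  expect_true(all(res$outcomes$sig_05 %in% 0:1))
  # significance monotone across alphas in every replication
  expect_true(all(res$outcomes$sig_01 <= res$outcomes$sig_05))
  expect_true(all(res$outcomes$sig_001 <= res$outcomes$sig_01))
  expect_equal(nrow(res$power), 4 * 3)
  expect_true(all(res$power$power >= 0 & res$power$power <= 1))
})

test_that("null cells reject at close to the nominal rate", {
  p0 <- sim_params(slope = 0, n = 10, k = 10, sdR = 150)
  out <- run_cell_one_group(p0, replications = 2000, seed = 88)
  rate <- mean(out$sig[, "0.05"])
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})
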
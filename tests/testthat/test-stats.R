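test_that("Fisher z closed forms and round trip", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-15)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z_inverse(fisher_z(r)), r, tolerance = 1e-15)
  expect_error(fisher_z(1), "< 1")
  expect_true(all(diff(fisher_z(r)) > 0))   # strict monotonicity
})

test_that("parcel-signal correlation handles identity, nulls and alignment", {
  set.seed(41)
  sig <- rnorm(900)
  x <- rbind(sig, rnorm(900))
  r <- parcel_signal_correlation(x, sig)
  expect_equal(unname(r[1]), 1, tolerance = 1e-12)
  expect_lt(abs(r[2]), 0.1)   # null r ~ N(0, 1/sqrt(T))

  expect_error(parcel_signal_correlation(x, sig[1:100]), "mismatch")

  # time-varying input is trimmed to window centres
  ts <- quick_ts(8, 100, seed = 42)
  tvc <- time_varying_centrality(ts, window_spec(50, 1), density = 0.2)
  full_sig <- rnorm(100)
  r2 <- parcel_signal_correlation(tvc, full_sig)
  win <- enumerate_windows(100, window_spec(50, 1))
  r2_manual <- cor(tvc$values[1, ], full_sig[win$center])
  expect_equal(unname(r2[1]), r2_manual, tolerance = 1e-12)
  expect_error(parcel_signal_correlation(tvc, rnorm(10)), "too short")
})

test_that("integer-TR lag shifts the signal before correlating", {
  set.seed(43)
  sig <- rnorm(200)
  lagged <- rbind(c(rep(0, 3), sig[1:197]))  # parcel follows signal by 3 TR
  r0 <- parcel_signal_correlation(lagged, sig, lag_s = 0)
  r3 <- parcel_signal_correlation(lagged, sig, lag_s = 3)
  expect_gt(r3, 0.99)
  expect_lt(abs(r0), 0.3)
})

test_that("group test: symmetric values, Bonferroni arithmetic, Z mapping", {
  vals <- matrix(rep(c(0.3, -0.3), 5), ncol = 1)
  gt <- group_test(vals, n_tests = 1)
  expect_equal(gt$table$t, 0, tolerance = 1e-12)
  expect_equal(gt$table$p, 1, tolerance = 1e-12)
  expect_equal(gt$table$Z, 0, tolerance = 1e-12)

  # p = 0.001 with 360 tests -> corrected 0.36
  expect_equal(min(1, 0.001 * 360), 0.36)
  set.seed(44)
  vals2 <- matrix(rnorm(20 * 5), 20, 5)
  gt2 <- group_test(vals2, n_tests = 360)
  expect_equal(gt2$table$p_corrected, pmin(1, gt2$table$p * 360))
  expect_true(all(gt2$table$p_corrected >= gt2$table$p))

  # two-tailed p of 0.05 maps to Z ~ 1.96
  expect_equal(qnorm(1 - 0.05 / 2), 1.96, tolerance = 1e-2)
  # configured cutoff for FWE 0.01 over 360 parcels
  gt3 <- group_test(vals2, n_tests = 360, fwe_level = 0.01)
  expect_equal(gt3$z_threshold, qnorm(1 - 0.01 / 360 / 2), tolerance = 1e-12)
})

test_that("group test detects a strong one-sample effect", {
  set.seed(45)
  vals <- matrix(rnorm(20 * 3, mean = 0.5, sd = 0.1), 20, 3)
  gt <- group_test(vals, n_tests = 60)
  expect_true(all(gt$table$significant))
  expect_true(all(gt$table$p_corrected < 0.01))
  expect_lt(abs(mean(vals[, 1]) - 0.5), 0.1)
})

test_that("paired mode tests the difference and needs matching dims", {
  set.seed(46)
  a <- matrix(rnorm(12 * 4), 12, 4)
  b <- a + 0.8
  gt <- group_test(a, b, mode = "paired", n_tests = 4)
  expect_true(all(gt$table$t < 0))
  expect_true(all(gt$table$significant))
  gt2 <- group_test(a, a + matrix(rnorm(48, sd = 1e-2), 12, 4),
                    mode = "paired", n_tests = 4)
  expect_equal(gt2$mode, "paired")
  expect_error(group_test(a, b[1:6, ], mode = "paired"), "identical")
  expect_error(group_test(a[1:2, , drop = FALSE]), "3 participants")
})

test_that("group-average r map is the Fisher-z mean back-transformed", {
  expect_equal(group_average_r_map(matrix(0, 3, 2)), c(0, 0))
  expect_equal(group_average_r_map(matrix(0.42, 5, 1)), 0.42,
               tolerance = 1e-12)
  two <- matrix(c(0.2, 0.6), 2, 1)
  expect_equal(group_average_r_map(two),
               tanh((atanh(0.2) + atanh(0.6)) / 2), tolerance = 1e-12)
  expect_equal(round(group_average_r_map(two), 3), 0.420)
  # invariant to participant ordering
  set.seed(47)
  m <- matrix(runif(10 * 4, -0.8, 0.8), 10, 4)
  expect_equal(group_average_r_map(m), group_average_r_map(m[10:1, ]))
  expect_error(group_average_r_map(matrix(c(1, 0), 2, 1)), "< 1")
})

test_that("spatial map correlation and its comparison behave as closed forms", {
  set.seed(48)
  a <- rnorm(50)
  expect_equal(spatial_map_correlation(a, a), 1)
  expect_equal(spatial_map_correlation(a, -a + 2), -1)
  b <- rnorm(50)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(spatial_map_correlation(a, b), num / den, tolerance = 1e-12)
  names(a) <- paste0("P", 1:50)
  b2 <- b; names(b2) <- paste0("Q", 1:50)
  expect_error(spatial_map_correlation(a, b2), "mismatched")

  expect_equal(compare_map_correlations(0.4, 0.4, 100)$Z, 0)
  expect_equal(compare_map_correlations(0.4, 0.4, 100)$p, 1)
  z <- compare_map_correlations(0.78, 0.60, 360)
  expect_equal(z$Z, (atanh(0.78) - atanh(0.60)) / sqrt(2 / 357),
               tolerance = 1e-12)
  expect_equal(z$Z, 4.70, tolerance = 0.01)
  zr <- compare_map_correlations(0.60, 0.78, 360)
  expect_equal(zr$Z, -z$Z)
  expect_error(compare_map_correlations(0.5, 0.2, 3), "n > 3")
})

test_that("covariate correlation matches the direct formula and null band", {
  # 5-participant toy table against the formula
  vals <- matrix(c(1, 2, 3, 4, 5,
                   2, 1, 4, 3, 5,
                   5, 4, 3, 2, 1), 5, 3)
  cov <- c(1.2, 2.1, 2.9, 4.2, 4.8)
  r <- covariate_correlation(vals, cov)
  for (j in 1:3) expect_equal(unname(r[j]), cor(vals[, j], cov),
                              tolerance = 1e-12)
  # covariate equal to a parcel's values -> r = 1
  expect_equal(unname(covariate_correlation(vals, vals[, 1])[1]), 1,
               tolerance = 1e-12)
  # independent covariate at n = 50: most |r| below the 95% null band
  set.seed(49)
  vals2 <- matrix(rnorm(50 * 200), 50, 200)
  r2 <- covariate_correlation(vals2, rnorm(50))
  expect_gt(mean(abs(r2) < 0.28), 0.90)
  expect_error(covariate_correlation(vals2, rep(1, 50)), "constant")
  expect_error(covariate_correlation(vals[1:3, ], cov[1:3]), "4 participants")
})

test_that("one-sample FWE on null correlations stays near the nominal level", {
  # 60 parcels x 20 participants x 60 repetitions of true-null r values
  set.seed(50)
  n_rep <- 60
  fw <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    rmat <- matrix(NA_real_, 20, 60)
    for (p in 1:20) {
      noise <- matrix(rnorm(61 * 80), 61, 80)
      rmat[p, ] <- as.numeric(cor(t(noise))[1, -1])
    }
    gt <- group_test(atanh(rmat), n_tests = 60, fwe_level = 0.01)
    fw[k] <- any(gt$table$significant)
  }
  # binomial 95% upper band for 60 draws at p = 0.01
  expect_lte(sum(fw), qbinom(0.975, n_rep, 0.01))
})
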
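test_that("binary pattern construction, BSR and interval round trip agree", {
  # no suppression
  p0 <- make_binary_pattern(NULL, duration = 10, sample_rate = 10)
  expect_equal(compute_bsr(p0), 0)
  expect_equal(nrow(p0$intervals), 0)

  # fully suppressed
  p1 <- make_binary_pattern(matrix(c(0, 10), 1), 10, 10)
  expect_equal(compute_bsr(p1), 100)

  # 50 of 200 s suppressed at 10 Hz -> 500 of 2000 samples
  p2 <- make_binary_pattern(matrix(c(20, 50, 100, 120), 2, byrow = TRUE),
                            200, 10)
  expect_equal(compute_bsr(p2), 25)
  expect_equal(sum(p2$values == 0), 500)

  # round trip intervals -> pattern -> intervals is the identity
  iv <- matrix(c(1.5, 3.0, 7.2, 9.9, 12.0, 12.5), 3, 2, byrow = TRUE)
  p3 <- make_binary_pattern(iv, 20, 10)
  expect_equal(unname(p3$intervals), iv)

  # BSR equals the interval-length fraction exactly for grid-aligned input
  expect_equal(compute_bsr(p3), 100 * sum(iv[, 2] - iv[, 1]) / 20)
  # suppression and burst fractions are complementary
  expect_equal(compute_bsr(p3) + 100 * mean(p3$values == 1), 100)

  expect_error(make_binary_pattern(matrix(c(1, 5, 4, 8), 2, byrow = TRUE),
                                   10, 10), "overlap")
})

test_that("simulated alternation honours the renewal expectation", {
  # suppression disabled
  off <- simulate_bs_pattern(bs_sim_params(mean_suppression_duration = 0,
                                           total_duration = 100,
                                           sample_rate = 50), seed = 1)
  expect_equal(compute_bsr(off$pattern), 0)

  # expected BSR = mean_supp / (mean_burst + mean_supp); mean over 100 seeds
  prm <- bs_sim_params(mean_burst_duration = 15, mean_suppression_duration = 5,
                       total_duration = 4000, sample_rate = 20)
  bsrs <- vapply(1:100, function(s) {
    sim <- simulate_bs_pattern(prm, seed = s)
    expect_true(all(diff(sim$intervals[, 1]) > 0))
    expect_true(all(sim$intervals[, 2] > sim$intervals[, 1]))
    compute_bsr(sim$pattern)
  }, numeric(1))
  expect_true(all(bsrs >= 0 & bsrs <= 100))
  expect_lt(abs(mean(bsrs) - 25), 2)

  # long-run convergence within one point
  long <- simulate_bs_pattern(bs_sim_params(mean_burst_duration = 15,
                                            mean_suppression_duration = 5,
                                            total_duration = 1e5,
                                            sample_rate = 5), seed = 7)
  expect_lt(abs(compute_bsr(long$pattern) - 25), 1)

  expect_error(bs_sim_params(mean_burst_duration = -1), "positive")
})

test_that("canonical HRF has the expected double-gamma shape", {
  h <- canonical_hrf(dt = 0.01)
  expect_equal(h[1], 0, tolerance = 1e-10)
  expect_equal(max(h), 1)
  argmax <- (which.max(h) - 1) * 0.01
  expect_gte(argmax, 4.5)
  expect_lte(argmax, 5.5)
  # exactly one sign change: positive lobe then undershoot
  s <- sign(h[abs(h) > 1e-12])
  expect_equal(sum(diff(s) != 0), 1)
  # oracle: dense evaluation of the closed form at the mode of the first lobe
  p <- hrf_params()
  tdense <- seq(0, 32, by = 1e-3)
  dense <- dgamma(tdense, p$peak_delay, scale = 1) -
    dgamma(tdense, p$undershoot_delay, scale = 1) / 6
  expect_equal(argmax, tdense[which.max(dense)], tolerance = 0.02)
})

test_that("BS regressor equals brute-force causal convolution", {
  iv <- matrix(c(4, 7, 15, 16.5, 24, 30), 3, 2, byrow = TRUE)
  pat <- make_binary_pattern(iv, 40, 10)
  reg <- build_bs_regressor(pat, tr = 2, n_volumes = 20, n_drop = 2)
  expect_length(reg$values, 18)
  expect_equal(mean(reg$values), 0, tolerance = 1e-12)

  # independent O(N*K) convolution oracle
  kern <- canonical_hrf(dt = 0.1)
  x <- pat$values
  naive <- vapply(seq_along(x), function(n) {
    ks <- seq_len(min(n, length(kern)))
    sum(kern[ks] * x[n - ks + 1]) * 0.1
  }, numeric(1))
  sampled <- naive[round((0:19) * 2 * 10) + 1][-(1:2)]
  expect_equal(reg$values, sampled - mean(sampled), tolerance = 1e-10)
})

test_that("BS regressor is linear in the pattern and flat for steady input", {
  all1 <- make_binary_pattern(NULL, 200, 10)
  # drop enough volumes that only the post-transient steady state remains
  r1s <- build_bs_regressor(all1, tr = 2, n_volumes = 100, n_drop = 20)
  expect_lt(max(abs(r1s$values)), 1e-10)

  # impulse pattern reproduces the sampled HRF (flipped: 0 = suppression)
  imp <- bs_pattern(c(rep(1, 1), rep(1, 799)), 10)
  imp$values[5] <- 0L
  # linearity: regressor(1 - e_i) = regressor(1) - regressor(e_i kernel)
  ri <- build_bs_regressor(bs_pattern(imp$values, 10), 2, 40, 0)
  kern <- canonical_hrf(dt = 0.1)
  base <- build_bs_regressor(all1, 2, 40, 0)
  diffv <- base$values - ri$values
  # the difference of the two centered regressors is the centered sampled HRF
  samp <- rep(0, 800)
  idx <- 5 + seq_along(kern) - 1
  samp[idx[idx <= 800]] <- kern[idx <= 800] * 0.1
  svol <- samp[round((0:39) * 2 * 10) + 1]
  expect_equal(diffv, svol - mean(svol), tolerance = 1e-10)

  expect_error(build_bs_regressor(make_binary_pattern(NULL, 10, 10),
                                  2, 40, 0), "cover")
})

test_that("temporal Jaccard behaves at the boundaries", {
  a <- matrix(c(0, 1, 2, 3), 2, byrow = TRUE)
  expect_equal(interval_jaccard(a, a), 1)
  expect_equal(interval_jaccard(a, NULL), 0)
  expect_equal(interval_jaccard(NULL, NULL), 1)
  b <- matrix(c(0.5, 1.5), 1)
  expect_equal(interval_jaccard(matrix(c(0, 1), 1), b), 0.5 / 1.5)
})
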
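test_that("linear detrending removes exactly the fitted line", {
  nv <- 100
  ramp <- outer(c(1, -2, 0.5), seq_len(nv)) + 3
  run <- manual_run(ramp)
  out <- detrend_linear(run)
  expect_lt(max(abs(out$data)), 1e-10)

  # ramp + sinusoid: the sinusoid survives (closed-form projection oracle)
  t <- seq_len(nv)
  sine <- sin(2 * pi * 7 * t / nv)
  # make the sinusoid exactly orthogonal to [1, t] to avoid leakage
  X <- cbind(1, t)
  sine_o <- sine - X %*% qr.coef(qr(X), sine)
  y <- matrix(5 + 0.3 * t + sine_o, 1)
  out2 <- detrend_linear(manual_run(y))
  expect_equal(as.numeric(out2$data), as.numeric(sine_o), tolerance = 1e-8)
})

test_that("nuisance regression produces orthogonal residuals and is idempotent", {
  prm <- null_bold_params(8, 120)
  run <- null_run(prm, seed = 31)
  # plant one parcel equal to a nuisance column
  run$data[1, ] <- run$nuisance[, "wm"]
  out <- regress_nuisance(run)
  expect_lt(max(abs(out$data[1, ])), 1e-8)
  # residuals orthogonal to every regressor (scaled by the input magnitudes)
  ip <- abs(crossprod(t(out$data), cbind(1, run$nuisance)))
  norms <- outer(sqrt(rowSums(run$data^2)),
                 sqrt(colSums(cbind(1, run$nuisance)^2)))
  expect_lt(max(ip / norms), 1e-8)
  # idempotence
  out2 <- regress_nuisance(out)
  expect_equal(out$data, out2$data, tolerance = 1e-10)

  # collinear design is refused with the offending column named
  bad <- run
  bad$nuisance[, "csf"] <- bad$nuisance[, "wm"]
  expect_error(regress_nuisance(bad), "collinear")
})

test_that("band-pass filter passes the band and kills drift and DC", {
  nv <- 200
  t <- (0:(nv - 1)) * 2
  mk <- function(f) manual_run(matrix(sin(2 * pi * f * t), 1))
  gain <- function(f) {
    y <- bandpass(mk(f))$data[1, ]
    mid <- 40:(nv - 40)
    sd(y[mid]) / sd(sin(2 * pi * f * t)[mid])
  }
  expect_gt(gain(0.05), 0.9)   # passband
  expect_lt(gain(0.005), 0.1)  # slow drift
  expect_lt(gain(0.2), 0.1)    # high frequency
  const <- bandpass(manual_run(matrix(3, 1, nv)))
  expect_lt(max(abs(const$data)), 1e-10)
  expect_error(bandpass(manual_run(matrix(rnorm(nv), 1)), band = c(0.01, 0.3)),
               "Nyquist")
})

test_that("stage order commutes on data orthogonal to the nuisance space", {
  set.seed(77)
  nv <- 150
  nuis <- matrix(rnorm(nv * 8), nv, 8,
                 dimnames = list(NULL, bsfc:::nuisance_names()))
  bf <- signal::butter(4, c(0.01, 0.1) / 0.25, type = "pass")
  # explicit filter operator, so the orthogonality closure can include its
  # adjoint (filtfilt with edge initialization is not exactly symmetric)
  S <- apply(diag(nv), 2, function(e) signal::filtfilt(bf, e))
  t <- seq_len(nv)
  # the filtered constant is ~0 (DC gain), so only the nuisance columns are
  # pushed through the operator and its adjoint
  span <- cbind(1, t, nuis, S %*% nuis, t(S) %*% cbind(1, t, nuis))
  # project through an orthonormal basis: the span is numerically
  # rank-deficient because filtfilt is close to self-adjoint
  qs <- qr(span)
  Q <- qr.Q(qs)[, seq_len(qs$rank), drop = FALSE]
  Y <- matrix(rnorm(3 * nv), 3, nv)
  Y <- Y - t(Q %*% crossprod(Q, t(Y)))
  run <- manual_run(Y, nuisance = nuis)
  a <- preprocess(run, preproc_config(order = "regress_then_filter"))
  b <- preprocess(run, preproc_config(order = "filter_then_regress"))
  expect_equal(a$data, b$data, tolerance = 1e-6)
})

test_that("regression before filtering leaves less residual nuisance", {
  # paired comparison over 20 seeded runs with strong nuisance contamination
  prm <- bold_sim_params(n_parcels = 10, n_volumes = 150,
                         coupling_betas = rep(0, 10), latent_blocks = list(),
                         nuisance_gain = rep(1.5, 8), noise_sd = 1,
                         regions = tiny_regions(10))
  bf <- signal::butter(4, c(0.01, 0.1) / 0.25, type = "pass")
  worse <- 0
  for (sd in 1:20) {
    run <- null_run(prm, seed = 100 + sd)
    # the run's true (filtered) nuisance component, from generator ground
    # truth: what an ideal pipeline would remove completely
    ctrue <- t(apply(run$ground_truth$nuisance_contribution, 1,
                     function(x) signal::filtfilt(bf, x - mean(x))))
    resid_cor <- function(out) {
      mean(abs(vapply(seq_len(nrow(ctrue)), function(p) {
        cor(out$data[p, ], ctrue[p, ])
      }, numeric(1))))
    }
    a <- resid_cor(preprocess(run, preproc_config("regress_then_filter")))
    b <- resid_cor(preprocess(run, preproc_config("filter_then_regress")))
    worse <- worse + (a < b)
  }
  expect_equal(worse, 20)
})

test_that("preprocessing is linear and records its stages", {
  prm <- null_bold_params(5, 80)
  run <- null_run(prm, seed = 41)
  cfg <- preproc_config()
  a <- preprocess(run, cfg)
  run3 <- run; run3$data <- run$data * 3
  b <- preprocess(run3, cfg)
  expect_equal(b$data, 3 * a$data, tolerance = 1e-8)
  expect_equal(a$stages, c("detrend", "regress", "bandpass[0.01-0.1]"))
})

test_that("including the BS regressor removes the coupling component", {
  sim <- simulate_bs_pattern(bs_sim_params(total_duration = 300,
                                           sample_rate = 50), seed = 51)
  prm <- bold_sim_params(n_parcels = 12, n_volumes = 150,
                         coupling_betas = rep(1.5, 12),
                         latent_blocks = list(), nuisance_gain = rep(0.3, 8),
                         noise_sd = 1, regions = tiny_regions(12))
  run <- simulate_bold_run(sim$pattern, prm, "O", "BS", seed = 52)
  reg <- build_bs_regressor(sim$pattern, 2, 150, n_drop = 0)
  run$bs_regressor <- reg
  plain <- preprocess(run, preproc_config())
  corrected <- preprocess(run, preproc_config(include_bs_regressor = TRUE))
  # the corrected parcel-mean no longer tracks the regressor
  expect_lt(abs(cor(colMeans(corrected$data), reg$values)),
            abs(cor(colMeans(plain$data), reg$values)))
  expect_lt(mean_offdiag(fc_matrix(corrected)),
            mean_offdiag(fc_matrix(plain)))
  # immediately after regression (before filtering) residuals are orthogonal
  reg_only <- regress_nuisance(detrend_linear(run), include_bs = TRUE)
  expect_lt(max(abs(reg_only$data %*% reg$values)) /
              (max(abs(reg_only$data)) * sqrt(sum(reg$values^2))), 1e-8)
})
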
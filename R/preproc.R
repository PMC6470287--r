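#' Preprocessing configuration
#'
#' @param order `"regress_then_filter"` (nuisance regression before temporal
#'   filtering — the more effective ordering, applied throughout the main
#'   pipeline) or `"filter_then_regress"` (the conventional alternative, kept
#'   for the strategy comparison).
#' @param band band-pass edges in Hz (default 0.01–0.1).
#' @param include_bs_regressor add the HRF-convolved BS pattern to the
#'   nuisance design, removing the burst-suppression coupling component.
#' @param filter_order Butterworth order (applied forward-backward).
#' @export
preproc_config <- function(order = c("regress_then_filter",
                                     "filter_then_regress"),
                           band = c(0.01, 0.1),
                           include_bs_regressor = FALSE, filter_order = 4) {
  order <- match.arg(order)
  if (band[1] <= 0 || band[2] <= band[1]) stop("invalid band")
  list(order = order, band = band,
       include_bs_regressor = include_bs_regressor,
       filter_order = filter_order)
}

#' Remove per-parcel linear drift
#'
#' Least-squares line (intercept + slope) removed from every parcel series;
#' the output has zero mean per parcel.
#'
#' @param run a [bold_run].
#' @return The detrended run.
#' @export
detrend_linear <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  nv <- ncol(run$data)
  if (nv < 3) stop("need at least 3 volumes")
  X <- cbind(1, seq_len(nv) - (nv + 1) / 2)
  run$data <- run$data - t(X %*% qr.coef(qr(X), t(run$data)))
  run$stages <- c(run$stages, "detrend")
  run
}

# OLS residuals of each row of Y (parcels x volumes) on design X (volumes x p)
ols_residuals <- function(Y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y - t(X %*% qr.coef(qrX, t(Y)))
}

#' Regress nuisance covariates out of a run
#'
#' Per-parcel OLS on intercept + linear drift + the run's nuisance table
#' (six motion parameters, white matter, CSF), optionally augmented with the
#' run's attached BS regressor. The drift column keeps the design consistent
#' with the detrending stage: without it, detrending the data but not the
#' regressors re-introduces the regressors' own trend components into the
#' residuals. Residuals are exactly orthogonal to every regressor.
#'
#' @param run a [bold_run].
#' @param include_bs also regress the HRF-convolved BS pattern
#'   (`run$bs_regressor` must be present).
#' @return The run with residual data.
#' @export
regress_nuisance <- function(run, include_bs = FALSE) {
  stopifnot(inherits(run, "bold_run"))
  nv <- ncol(run$data)
  X <- cbind(intercept = 1, trend = seq_len(nv) - (nv + 1) / 2,
             run$nuisance)
  if (include_bs) {
    if (is.null(run$bs_regressor)) {
      stop("include_bs = TRUE but the run has no attached bs_regressor")
    }
    if (length(run$bs_regressor$values) != ncol(run$data)) {
      stop("BS regressor length does not match retained volumes")
    }
    X <- cbind(X, bs = run$bs_regressor$values)
  }
  run$data <- ols_residuals(run$data, X)
  run$stages <- c(run$stages,
                  if (include_bs) "regress+bs" else "regress")
  run
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward-backward (zero phase, no lag that
#' would distort connectivity). Each parcel is demeaned before filtering, so
#' a constant series maps to exactly zero.
#'
#' @param run a [bold_run].
#' @param band pass-band edges in Hz.
#' @param filter_order Butterworth order.
#' @return The filtered run.
#' @export
bandpass <- function(run, band = c(0.01, 0.1), filter_order = 4) {
  stopifnot(inherits(run, "bold_run"))
  nyq <- 1 / (2 * run$tr)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq) {
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  bf <- signal::butter(filter_order, band / nyq, type = "pass")
  run$data <- t(apply(run$data, 1, function(x) {
    signal::filtfilt(bf, x - mean(x))
  }))
  rownames(run$data) <- run$regions
  run$stages <- c(run$stages, sprintf("bandpass[%g-%g]", band[1], band[2]))
  run
}

#' Full parcel-level preprocessing
#'
#' Linear detrend, then nuisance regression and temporal filtering in the
#' configured order. With `order = "regress_then_filter"` and
#' `include_bs_regressor = TRUE` this is the corrected pipeline that removes
#' both conventional nuisance and the burst-suppression coupling component
#' before connectivity analysis. Applied stages are recorded on the run.
#'
#' @param run a [bold_run].
#' @param config a [preproc_config()].
#' @return The preprocessed run.
#' @export
preprocess <- function(run, config = preproc_config()) {
  run <- detrend_linear(run)
  if (config$order == "regress_then_filter") {
    run <- regress_nuisance(run, include_bs = config$include_bs_regressor)
    run <- bandpass(run, config$band, config$filter_order)
  } else {
    run <- bandpass(run, config$band, config$filter_order)
    run <- regress_nuisance(run, include_bs = config$include_bs_regressor)
  }
  run
}

#' Discard leading volumes of a run
#'
#' Trims the data and the nuisance table together; used to drop pre-steady-
#' state volumes (conventionally the first 10) before preprocessing so that
#' the run aligns with a regressor built with the same `n_drop`.
#'
#' @param run a [bold_run].
#' @param n number of leading volumes to drop.
#' @export
drop_leading_volumes <- function(run, n = 10) {
  stopifnot(inherits(run, "bold_run"))
  if (n <= 0) return(run)
  if (n >= ncol(run$data)) stop("cannot drop all volumes")
  run$data <- run$data[, -seq_len(n), drop = FALSE]
  run$nuisance <- run$nuisance[-seq_len(n), , drop = FALSE]
  run
}
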
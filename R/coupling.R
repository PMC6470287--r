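#' Per-run burst-suppression coupling GLM
#'
#' For each parcel, ordinary least squares of the (preprocessed) series on
#' intercept + the HRF-convolved BS regressor; the slope quantifies how
#' strongly that parcel's BOLD fluctuations track the burst-suppression
#' alternation.
#'
#' @param run a preprocessed [bold_run].
#' @param regressor a `volume_regressor` from [build_bs_regressor()]; length
#'   must match the run's retained volumes.
#' @return List of class `coupling_result` with per-parcel `betas`, `tstats`,
#'   `regions`, and `run_id`.
#' @export
fit_coupling_glm <- function(run, regressor) {
  stopifnot(inherits(run, "bold_run"))
  x <- regressor$values
  if (length(x) != ncol(run$data)) {
    stop("regressor length (", length(x), ") != retained volumes (",
         ncol(run$data), ")")
  }
  if (stats::var(x) == 0) {
    stop("degenerate design: BS regressor has zero variance ",
         "(no suppression epochs in this run?)")
  }
  X <- cbind(1, x)
  qrX <- qr(X)
  B <- qr.coef(qrX, t(run$data))          # 2 x parcels
  R <- t(run$data) - X %*% B
  df <- length(x) - 2L
  s2 <- colSums(R^2) / df
  xtxinv <- solve(crossprod(X))[2, 2]
  se <- sqrt(xtxinv * s2)
  tstat <- ifelse(se > 0, B[2, ] / se, 0)
  structure(list(betas = unname(B[2, ]), tstats = unname(tstat),
                 regions = run$regions,
                 run_id = paste(run$subject, run$group, sep = "/")),
            class = "coupling_result")
}

#' Group-level coupling test
#'
#' One-sample test of the per-parcel coupling betas across runs, adjusted
#' for subject: each parcel's betas are modelled as
#' `beta ~ intercept + subject indicators` (dummy coding, first subject as
#' reference) and the intercept's t statistic is reported, with two-tailed p
#' and Bonferroni correction across parcels.
#'
#' @param results list of `coupling_result` objects over runs.
#' @param subjects character vector, one subject ID per run.
#' @param alpha family-wise significance level (default 0.05).
#' @return List of class `group_coupling_result`: `regions`, `mean_beta`,
#'   `tstat`, `p`, `significant` (Bonferroni mask), `n_runs`.
#' @export
group_coupling_test <- function(results, subjects, alpha = 0.05) {
  n <- length(results)
  if (n < 3) stop("need at least 3 runs")
  if (length(subjects) != n) stop("one subject ID per run required")
  B <- do.call(rbind, lapply(results, `[[`, "betas"))  # runs x parcels
  subjects <- factor(subjects)
  X <- matrix(1, n, 1)
  if (nlevels(subjects) > 1) {
    X <- cbind(X, stats::model.matrix(~subjects)[, -1, drop = FALSE])
  }
  if (n < ncol(X) + 2) stop("insufficient runs for the covariate design")
  qrX <- qr(X)
  Coef <- qr.coef(qrX, B)
  R <- B - X %*% Coef
  df <- n - ncol(X)
  s2 <- colSums(R^2) / df
  se <- sqrt(solve(crossprod(X))[1, 1] * s2)
  tstat <- ifelse(se > 0, Coef[1, ] / se, ifelse(Coef[1, ] == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(regions = results[[1]]$regions,
                 mean_beta = unname(colMeans(B)),
                 tstat = unname(tstat), p = unname(p),
                 significant = unname(p < alpha / ncol(B)),
                 n_runs = n, df = df),
            class = "group_coupling_result")
}
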
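#' Seed-based connectivity map for one run
#'
#' The seed regressor is the mean preprocessed time course over the seed
#' regions; every other parcel is regressed on `[intercept, seed]` and the
#' slope (connectivity strength) and its t statistic are reported. By the
#' OLS identity the slope equals `cov(target, seed) / var(seed)`.
#'
#' @param run a preprocessed [bold_run].
#' @param seed a [seed_spec()].
#' @return data.frame of class `seed_map` with columns `region`, `beta`,
#'   `t`; seed regions are excluded from the targets. Attributes `seed_name`
#'   and `run_id` identify the map.
#' @export
seed_connectivity <- function(run, seed) {
  stopifnot(inherits(run, "bold_run"))
  missing <- setdiff(seed$seed_regions, run$regions)
  if (length(missing)) {
    stop("seed region(s) not in the parcellation: ",
         paste(missing, collapse = ", "))
  }
  s <- colMeans(run$data[seed$seed_regions, , drop = FALSE])
  if (stats::var(s) == 0) stop("degenerate seed: constant mean time course")
  targets <- setdiff(run$regions, seed$seed_regions)
  X <- cbind(1, s)
  qrX <- qr(X)
  Y <- t(run$data[targets, , drop = FALSE])
  B <- qr.coef(qrX, Y)
  R <- Y - X %*% B
  df <- length(s) - 2L
  s2 <- colSums(R^2) / df
  se <- sqrt(solve(crossprod(X))[2, 2] * s2)
  out <- data.frame(region = targets, beta = unname(B[2, ]),
                    t = unname(ifelse(se > 0, B[2, ] / se, 0)))
  attr(out, "seed_name") <- seed$name
  attr(out, "run_id") <- paste(run$subject, run$group, sep = "/")
  class(out) <- c("seed_map", "data.frame")
  out
}

#' Group analysis of seed-connectivity maps
#'
#' Per group, a covariate-adjusted one-sample test of the per-target betas
#' (intercept t of `beta ~ 1 + subject`), Bonferroni-corrected across
#' targets. Between groups, a linear model of beta on
#' `[intercept, group (BS = 1), subject]` per target, again with Bonferroni
#' correction. With two groups the repeated-measures comparison reduces to
#' exactly this covariate-adjusted model.
#'
#' @param maps list of `seed_map` data.frames over runs (same targets).
#' @param groups,subjects run labels.
#' @param alpha family-wise level (default 0.05).
#' @return List of class `seed_group_result`: `within` (per group: region,
#'   mean beta, t, p, significant) and `between` (region, t, p, significant).
#' @export
seed_group_compare <- function(maps, groups, subjects, alpha = 0.05) {
  if (length(maps) < 4) stop("insufficient runs for a group comparison")
  if (length(unique(groups)) < 2) stop("both groups must be present")
  targets <- maps[[1]]$region
  B <- do.call(rbind, lapply(maps, `[[`, "beta"))  # runs x targets
  ntest <- length(targets)

  within <- lapply(split(seq_along(groups), groups), function(idx) {
    if (length(idx) < 3) stop("insufficient runs in one group")
    sub <- factor(subjects[idx])
    X <- matrix(1, length(idx), 1)
    if (nlevels(sub) > 1) {
      X <- cbind(X, stats::model.matrix(~sub)[, -1, drop = FALSE])
    }
    qrX <- qr(X)
    Bi <- B[idx, , drop = FALSE]
    Coef <- qr.coef(qrX, Bi)
    R <- Bi - X %*% Coef
    df <- length(idx) - ncol(X)
    if (df < 1) stop("insufficient runs for the covariate design")
    se <- sqrt(solve(crossprod(X))[1, 1] * colSums(R^2) / df)
    tt <- ifelse(se > 0, Coef[1, ] / se, 0)
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(region = targets, mean_beta = unname(colMeans(Bi)),
               t = unname(tt), p = unname(p),
               significant = unname(p < alpha / ntest))
  })

  X <- group_design(groups, subjects)
  et <- edge_group_t(B, X)
  p <- 2 * stats::pt(-abs(et$t), et$df)
  between <- data.frame(region = targets, t = unname(et$t), p = unname(p),
                        significant = unname(p < alpha / ntest))
  structure(list(within = within, between = between, alpha = alpha),
            class = "seed_group_result")
}
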
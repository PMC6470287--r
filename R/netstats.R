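#' Whole-brain functional connectivity matrix
#'
#' Pearson correlations between the preprocessed time courses of every pair
#' of parcels.
#'
#' @param run a preprocessed [bold_run].
#' @return Symmetric region-by-region correlation matrix of class
#'   `fc_matrix` with attribute `scale = "r"` and unit diagonal.
#' @export
fc_matrix <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  if (ncol(run$data) < 3) stop("need at least 3 volumes")
  v <- apply(run$data, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance parcel(s): ",
         paste(run$regions[v == 0], collapse = ", "))
  }
  m <- stats::cor(t(run$data))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(run$regions, run$regions)
  structure(m, class = c("fc_matrix", "matrix"), scale = "r")
}

#' Fisher z-transform of a correlation matrix
#'
#' `atanh` applied off-diagonal (variance stabilization before edgewise
#' linear models); the diagonal is set to 0.
#'
#' @param m an `fc_matrix` on the r scale.
#' @return `fc_matrix` with attribute `scale = "z"`.
#' @export
fisher_z <- function(m) {
  if (!identical(attr(m, "scale"), "r")) stop("input must be on the r scale")
  off <- m; diag(off) <- 0
  if (any(abs(off) >= 1)) {
    bad <- which(abs(off) >= 1, arr.ind = TRUE)[1, ]
    stop("|r| = 1 off-diagonal at edge ", rownames(m)[bad[1]], " - ",
         colnames(m)[bad[2]], ": Fisher z is infinite")
  }
  z <- atanh(off)
  structure(z, class = c("fc_matrix", "matrix"), scale = "z",
            dimnames = dimnames(m))
}

#' Hedges' g effect size
#'
#' Bias-corrected standardized mean difference:
#' `g = J * (mean(x) - mean(y)) / s_pooled`, with small-sample correction
#' `J = 1 - 3 / (4 (n_x + n_y) - 9)` and `s_pooled` the pooled standard
#' deviation.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @export
hedges_g <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need at least 2 observations per group")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) stop("undefined effect size: zero pooled variance")
  J <- 1 - 3 / (4 * (nx + ny) - 9)
  J * (mean(x) - mean(y)) / sqrt(sp2)
}

upper_tri_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# stack the upper triangles of a list of matrices into a runs x edges matrix
stack_edges <- function(mats) {
  ut <- upper.tri(mats[[1]])
  t(vapply(mats, function(m) m[ut], numeric(sum(ut))))
}

# group-difference design: intercept, group indicator (BS = 1), subject dummies
group_design <- function(groups, subjects) {
  groups <- factor(groups, levels = c("SW", "BS"))
  if (any(is.na(groups))) stop("groups must be 'BS' or 'SW'")
  if (nlevels(droplevels(groups)) < 2) {
    stop("both groups must be present in the design")
  }
  subjects <- factor(subjects)
  X <- cbind(intercept = 1, group = as.numeric(groups == "BS"))
  if (nlevels(subjects) > 1) {
    S <- stats::model.matrix(~subjects)[, -1, drop = FALSE]
    X <- cbind(X, S)
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient group/subject design")
  X
}

# t statistics of the group coefficient for every column of Y (runs x edges)
edge_group_t <- function(Y, X) {
  qrX <- qr(X)
  B <- qr.coef(qrX, Y)
  R <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  s2 <- colSums(R^2) / df
  c22 <- chol2inv(chol(crossprod(X)))[2, 2]
  se <- sqrt(c22 * s2)
  tt <- B[2, ] / se
  tt[se == 0] <- 0
  list(t = tt, df = df)
}

#' Edgewise group comparison of connectivity
#'
#' For every edge, a linear model of Fisher-z connectivity on
#' `[intercept, group (BS = 1), subject indicators]`; reports the group
#' coefficient's t and two-tailed p, plus Hedges' g computed on the raw
#' per-group correlation samples.
#'
#' @param fc_list list of `fc_matrix` objects on the r scale, one per run.
#' @param groups character vector of run groups (`"BS"`/`"SW"`).
#' @param subjects character vector of run subjects.
#' @return data.frame with columns `region_i`, `region_j`, `t`, `p`, `g`.
#' @export
edgewise_group_stats <- function(fc_list, groups, subjects) {
  Z <- stack_edges(lapply(fc_list, fisher_z))
  Rr <- stack_edges(fc_list)
  X <- group_design(groups, subjects)
  et <- edge_group_t(Z, X)
  p <- 2 * stats::pt(-abs(et$t), et$df)
  bs <- groups == "BS"
  nx <- sum(bs); ny <- sum(!bs)
  J <- 1 - 3 / (4 * (nx + ny) - 9)
  mx <- colMeans(Rr[bs, , drop = FALSE])
  my <- colMeans(Rr[!bs, , drop = FALSE])
  vx <- apply(Rr[bs, , drop = FALSE], 2, stats::var)
  vy <- apply(Rr[!bs, , drop = FALSE], 2, stats::var)
  sp <- sqrt(((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2))
  g <- ifelse(sp > 0, J * (mx - my) / sp, NA_real_)
  labels <- rownames(fc_list[[1]])
  pr <- upper_tri_pairs(length(labels))
  data.frame(region_i = labels[pr[, 1]], region_j = labels[pr[, 2]],
             t = unname(et$t), p = unname(p), g = unname(g))
}

# permute group labels within subject strata; subjects with a single group
# keep their labels fixed automatically (any permutation maps them to
# themselves in label space)
permute_groups_within_subject <- function(groups, subjects) {
  g <- groups
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    g[idx] <- groups[idx[sample.int(length(idx))]]
  }
  g
}

#' Network-based statistic (component-extent) correction
#'
#' Family-wise-error control over connected components of suprathreshold
#' edges. Edges with `|t|` above the two-sided `edge_alpha` critical value
#' (from the edgewise group model) form a graph; the null distribution of
#' the maximal component extent (edge count) is built by permuting group
#' labels within subject strata, preserving subject effects under the null.
#' A component's p-value is `(1 + #[perm max >= observed]) / (1 + n_perm)`;
#' edges in components with `p < cluster_alpha` are flagged and signed by the
#' group coefficient.
#'
#' @param fc_list list of r-scale `fc_matrix` objects, one per run.
#' @param groups,subjects run labels.
#' @param edge_alpha edgewise threshold (default 0.001).
#' @param cluster_alpha component-level threshold (default 0.05).
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed for the permutations.
#' @return List of class `edge_group_stats`: `edges` (data.frame with `t`,
#'   `p`, `g`, `component`, `significant`, `direction`), `components`
#'   (extent and p per observed component), `n_increased`, `n_decreased`,
#'   `max_null_quantile`, and the inputs' group sizes.
#' @export
nbs_correction <- function(fc_list, groups, subjects, edge_alpha = 0.001,
                           cluster_alpha = 0.05, n_perm = 5000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  Z <- stack_edges(lapply(fc_list, fisher_z))
  X <- group_design(groups, subjects)
  et <- edge_group_t(Z, X)
  tcrit <- stats::qt(1 - edge_alpha / 2, et$df)
  labels <- rownames(fc_list[[1]])
  n <- length(labels)
  pr <- upper_tri_pairs(n)

  comp_of <- rep(NA_integer_, nrow(pr))
  comp_sizes <- integer(0)
  supra <- abs(et$t) > tcrit
  if (any(supra)) {
    gr <- igraph::graph_from_edgelist(cbind(pr[supra, 1], pr[supra, 2]),
                                      directed = FALSE)
    memb <- igraph::components(gr)$membership
    raw <- memb[pr[supra, 1]]
    used <- sort(unique(raw))            # drop isolated-vertex components
    comp_of[supra] <- match(raw, used)
    comp_sizes <- tabulate(match(raw, used), length(used))
  }

  set.seed(seed)
  null_max <- numeric(n_perm)
  Xp <- X
  strata <- split(seq_along(subjects), subjects)
  gnum <- as.numeric(groups == "BS")
  for (b in seq_len(n_perm)) {
    for (idx in strata) Xp[idx, 2] <- gnum[idx[sample.int(length(idx))]]
    tp <- edge_group_t(Z, Xp)$t
    sp <- abs(tp) > tcrit
    null_max[b] <- if (any(sp)) {
      grp <- igraph::graph_from_edgelist(cbind(pr[sp, 1], pr[sp, 2]),
                                         directed = FALSE)
      max(table(igraph::components(grp)$membership[pr[sp, 1]]))
    } else 0
  }
  comp_p <- vapply(comp_sizes, function(sz) {
    (1 + sum(null_max >= sz)) / (1 + n_perm)
  }, numeric(1))

  sig_comp <- which(comp_p < cluster_alpha)
  significant <- !is.na(comp_of) & comp_of %in% sig_comp
  direction <- ifelse(significant, ifelse(et$t > 0, "increased", "decreased"),
                      NA_character_)
  edges <- data.frame(region_i = labels[pr[, 1]], region_j = labels[pr[, 2]],
                      t = unname(et$t), g = NA_real_,
                      component = comp_of, significant = significant,
                      direction = direction)
  # carry Hedges' g from the uncorrected edgewise table
  edges$g <- edgewise_group_stats(fc_list, groups, subjects)$g
  structure(list(edges = edges,
                 components = data.frame(component = seq_along(comp_sizes),
                                         extent = comp_sizes, p = comp_p),
                 n_increased = sum(direction == "increased", na.rm = TRUE),
                 n_decreased = sum(direction == "decreased", na.rm = TRUE),
                 n_BS = sum(groups == "BS"), n_SW = sum(groups == "SW"),
                 edge_alpha = edge_alpha, cluster_alpha = cluster_alpha,
                 n_perm = n_perm, null_max = null_max),
            class = "edge_group_stats")
}

#' @export
print.edge_group_stats <- function(x, ...) {
  cat(sprintf(
    "<edge_group_stats> %d BS vs %d SW runs: %d significant edge(s) (%d increased, %d decreased) across %d component(s)\n",
    x$n_BS, x$n_SW, sum(x$edges$significant), x$n_increased, x$n_decreased,
    sum(x$components$p < x$cluster_alpha)))
  invisible(x)
}

block_geometry <- function(partition, regions) {
  lobe <- partition$lobe[match(regions, partition$region)]
  if (any(is.na(lobe))) {
    stop("partition does not cover region(s): ",
         paste(regions[is.na(lobe)], collapse = ", "))
  }
  lobes <- unique(lobe)
  pr <- upper_tri_pairs(length(regions))
  li <- match(lobe[pr[, 1]], lobes)
  lj <- match(lobe[pr[, 2]], lobes)
  block_i <- pmin(li, lj); block_j <- pmax(li, lj)
  edge_block <- (block_i - 1) * length(lobes) + block_j  # unordered pair key
  keys <- sort(unique(edge_block))
  list(lobes = lobes, edge_block = match(edge_block, keys),
       keys = keys, n_blocks = length(keys),
       block_labels = cbind(lobes[(keys - 1) %/% length(lobes) + 1],
                            lobes[(keys - 1) %% length(lobes) + 1]),
       m_b = tabulate(match(edge_block, keys), length(keys)),
       M = nrow(pr))
}

#' Lobe-block standardized residuals of disrupted edges
#'
#' Summarizes where significant ("disrupted") edges concentrate across lobe
#' pairs, correcting for unequal lobe sizes. For each unordered lobe pair
#' (including within-lobe blocks), the observed count `O` is compared with
#' the count expected if the `D` disrupted edges were spread uniformly over
#' all `M` possible edges, `E = D * m_b / M` with `m_b` the number of
#' possible edges in the block; the standardized residual is
#' `Z = (O - E) / sqrt(E)`.
#'
#' @param sig_mask logical upper-triangle edge mask (either a symmetric
#'   logical matrix or a vector in upper-triangle order) marking disrupted
#'   edges.
#' @param partition data.frame with columns `region`, `lobe`.
#' @param regions region labels in matrix order; defaults to
#'   `partition$region`.
#' @return data.frame of class `block_residuals` with columns `lobe_i`,
#'   `lobe_j`, `m_b`, `O`, `E`, `Z`.
#' @export
lobe_block_residuals <- function(sig_mask, partition, regions = NULL) {
  if (is.null(regions)) regions <- partition$region
  geo <- block_geometry(partition, regions)
  mask <- as_edge_mask(sig_mask, length(regions))
  D <- sum(mask)
  if (D == 0) stop("no disrupted edges")
  O <- tabulate(geo$edge_block[mask], geo$n_blocks)
  E <- D * geo$m_b / geo$M
  out <- data.frame(lobe_i = geo$block_labels[, 1],
                    lobe_j = geo$block_labels[, 2],
                    m_b = geo$m_b, O = O, E = E,
                    Z = ifelse(E > 0, (O - E) / sqrt(E), NA_real_))
  class(out) <- c("block_residuals", "data.frame")
  out
}

as_edge_mask <- function(sig_mask, n) {
  if (is.matrix(sig_mask)) sig_mask <- sig_mask[upper.tri(sig_mask)]
  sig_mask <- as.logical(sig_mask)
  if (length(sig_mask) != n * (n - 1) / 2) {
    stop("mask length does not match the upper triangle")
  }
  sig_mask
}

#' Permutation test of the lobe-block standardized residuals
#'
#' Builds the null by randomly reassigning the `D` disrupted edges uniformly
#' (without replacement) across all `M` possible whole-brain edges,
#' recomputing each block's `Z`. The p-value is the fraction of assignments
#' with a `Z` greater than or equal to the observed one (upper tail —
#' concentration above chance), Bonferroni-corrected over the number of
#' evaluated blocks.
#'
#' @inheritParams lobe_block_residuals
#' @param n_perm number of random reassignments (default 5000).
#' @param seed RNG seed.
#' @param alpha family-wise level for the Bonferroni flag.
#' @return The [lobe_block_residuals()] table plus columns `p` and
#'   `significant`.
#' @export
lobe_block_permutation <- function(sig_mask, partition, regions = NULL,
                                   n_perm = 5000, seed = 1, alpha = 0.05) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (is.null(regions)) regions <- partition$region
  geo <- block_geometry(partition, regions)
  mask <- as_edge_mask(sig_mask, length(regions))
  D <- sum(mask)
  if (D > geo$M) stop("more disrupted edges than possible edges")
  obs <- lobe_block_residuals(mask, partition, regions)
  E <- obs$E
  set.seed(seed)
  exceed <- integer(nrow(obs))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(geo$M, D)
    Op <- tabulate(geo$edge_block[idx], geo$n_blocks)
    Zp <- ifelse(E > 0, (Op - E) / sqrt(E), NA_real_)
    exceed <- exceed + as.integer(!is.na(Zp) & !is.na(obs$Z) & Zp >= obs$Z)
  }
  obs$p <- ifelse(is.na(obs$Z), NA_real_, exceed / n_perm)
  tested <- sum(!is.na(obs$Z))
  obs$significant <- !is.na(obs$p) & obs$p < alpha / tested
  obs
}
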
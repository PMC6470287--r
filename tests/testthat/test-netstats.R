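test_that("FC matrix and Fisher z behave like the textbook definitions", {
  set.seed(71)
  nv <- 120
  base <- rnorm(nv)
  Y <- rbind(base, base, rnorm(nv), sin(2 * pi * (1:nv) / 24),
             cos(2 * pi * (1:nv) / 24))
  run <- manual_run(Y)
  fc <- fc_matrix(run)
  expect_true(isSymmetric(unclass(fc)))
  expect_equal(unname(diag(fc)), rep(1, 5))
  expect_equal(fc[1, 2], 1)                        # duplicated series
  expect_lt(abs(fc[4, 5]), 1e-10)                  # sin/cos over whole periods

  run$data[3, ] <- 2
  expect_error(fc_matrix(run), "P003")

  # fisher z: closed form, diagonal convention, inverse pair
  m <- structure(diag(2), class = c("fc_matrix", "matrix"), scale = "r",
                 dimnames = list(c("a", "b"), c("a", "b")))
  m[1, 2] <- m[2, 1] <- 0.5
  z <- fisher_z(m)
  expect_equal(z[1, 2], atanh(0.5))
  expect_equal(round(z[1, 2], 4), 0.5493)
  expect_equal(unname(diag(z)), c(0, 0))
  expect_equal(tanh(z[1, 2]), 0.5, tolerance = 1e-12)
  m[1, 2] <- m[2, 1] <- 1
  expect_error(fisher_z(m), "infinite")
})

test_that("Hedges' g matches hand evaluation and is antisymmetric", {
  # hand oracle: J = 1 - 3/(4*4 - 9) = 4/7; d = -1/sqrt(2)
  expect_equal(hedges_g(c(0, 2), c(1, 3)), (4 / 7) * (-1 / sqrt(2)))
  expect_equal(round(hedges_g(c(0, 2), c(1, 3)), 3), -0.404)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- rnorm(8); y <- rnorm(5)
  expect_equal(hedges_g(x, y), -hedges_g(y, x))
  expect_error(hedges_g(c(1, 1), c(1, 1)), "pooled variance")
})

sim_fc_list <- function(n_runs, n_regions, nv = 60, seed = 1, shift = NULL,
                        groups = NULL) {
  set.seed(seed)
  lapply(seq_len(n_runs), function(i) {
    Y <- matrix(rnorm(n_regions * nv), n_regions, nv)
    if (!is.null(shift) && groups[i] == "BS") {
      f <- rnorm(nv)
      Y[shift, ] <- Y[shift, ] + 1.2 * rep(f, each = length(shift))
    }
    fc_matrix(manual_run(Y))
  })
}

test_that("edgewise group model is calibrated and detects planted blocks", {
  groups <- rep(c("BS", "SW"), each = 6)
  subjects <- rep(c("O", "T"), 6)

  # identical groups -> all t exactly 0
  fcs <- sim_fc_list(6, 8, seed = 72)
  st <- edgewise_group_stats(c(fcs, fcs), groups, subjects)
  expect_lt(max(abs(st$t)), 1e-8)

  # type-I calibration: fresh null cohorts, pooled fraction of p < 0.05
  set.seed(74)
  frac <- mean(replicate(100, {
    fcs <- lapply(1:12, function(i) {
      fc_matrix(manual_run(matrix(rnorm(8 * 60), 8, 60)))
    })
    st <- edgewise_group_stats(fcs, groups, subjects)
    mean(st$p < 0.05)
  }))
  expect_lt(abs(frac - 0.05), 0.02)

  # planted 4-region block separates affected from unaffected edges
  fcs <- sim_fc_list(12, 10, seed = 75, shift = 1:4, groups = groups)
  st <- edgewise_group_stats(fcs, groups, subjects)
  affected <- st$region_i %in% tiny_regions(4)[1:4] &
    st$region_j %in% tiny_regions(4)[1:4]
  expect_gt(median(abs(st$t[affected])), median(abs(st$t[!affected])))
  expect_true(all(st$g[affected] > 0))

  expect_error(edgewise_group_stats(fcs, rep("BS", 12), subjects),
               "both groups")
})

test_that("NBS flags planted components and respects trivial limits", {
  groups <- rep(c("BS", "SW"), each = 6)
  subjects <- rep(c("O", "T"), 6)
  fcs <- sim_fc_list(12, 10, seed = 76, shift = 1:4, groups = groups)

  res <- nbs_correction(fcs, groups, subjects, edge_alpha = 0.001,
                        n_perm = 200, seed = 1)
  planted <- res$edges$region_i %in% tiny_regions(4) &
    res$edges$region_j %in% tiny_regions(4)
  expect_gt(sum(res$edges$significant & planted), 0)
  expect_equal(sum(res$edges$significant & !planted), 0)
  expect_equal(unique(res$edges$direction[res$edges$significant]),
               "increased")

  # edge threshold alpha = 1 puts every edge in one component
  res_all <- nbs_correction(fcs, groups, subjects, edge_alpha = 0.999999,
                            n_perm = 100, seed = 2)
  expect_equal(sort(unique(res_all$edges$component)), 1)
  expect_equal(res_all$components$extent, nrow(res_all$edges))

  # observed max component is invariant under region relabelling
  perm <- c(4, 2, 9, 1, 7, 10, 3, 6, 5, 8)
  fcs_perm <- lapply(fcs, function(m) {
    structure(unclass(m)[perm, perm], class = class(m), scale = "r")
  })
  res_perm <- nbs_correction(fcs_perm, groups, subjects, edge_alpha = 0.001,
                             n_perm = 100, seed = 1)
  expect_equal(sort(res_perm$components$extent),
               sort(res$components$extent))
})

test_that("lobe-block residuals match the closed form and conserve counts", {
  part <- two_lobe_partition()
  # D = 3, all within lobe A: m_A = 3, M = 15, E_A = 0.6
  mask <- matrix(FALSE, 6, 6)
  mask[1, 2] <- mask[1, 3] <- mask[2, 3] <- TRUE
  res <- lobe_block_residuals(mask | t(mask), part)
  rowA <- res[res$lobe_i == "A" & res$lobe_j == "A", ]
  expect_equal(rowA$O, 3)
  expect_equal(rowA$E, 0.6)
  expect_equal(round(rowA$Z, 3), 3.098)
  expect_equal(sum(res$O), 3)
  expect_equal(sum(res$E), 3)
  expect_lt(abs(sum(res$O - res$E)), 1e-10)

  # saturation: all edges disrupted -> every Z = 0
  res_all <- lobe_block_residuals(rep(TRUE, 15), part)
  expect_true(all(abs(res_all$Z) < 1e-12))

  expect_error(lobe_block_residuals(rep(FALSE, 15), part), "no disrupted")
})

test_that("lobe-block permutation p matches exhaustive enumeration", {
  part <- two_lobe_partition()
  # D = 2 disrupted edges, both inside lobe A
  mask <- rep(FALSE, 15)
  geo <- bsfc:::block_geometry(part, part$region)
  withinA <- which(geo$edge_block == geo$edge_block[1])[1:2]
  mask[withinA] <- TRUE

  res <- lobe_block_permutation(mask, part, n_perm = 4000, seed = 3)
  rowA <- which(res$lobe_i == "A" & res$lobe_j == "A")

  # oracle: enumerate all C(15, 2) = 105 placements
  obsZ <- res$Z[rowA]
  EA <- res$E[rowA]
  combos <- combn(15, 2)
  exact <- mean(apply(combos, 2, function(cc) {
    O <- sum(geo$edge_block[cc] == geo$edge_block[withinA[1]])
    (O - EA) / sqrt(EA) >= obsZ
  }))
  expect_lt(abs(res$p[rowA] - exact), 0.02)

  # extremity: a fully concentrated block has the smallest p
  expect_equal(which.min(res$p), rowA)

  # calibration: masks drawn from the null give ~uniform p for a fixed block
  # (larger network so the block statistic is fine-grained enough for a KS
  # comparison against the continuous uniform)
  part60 <- data.frame(region = tiny_regions(60),
                       lobe = rep(c("A", "B"), each = 30))
  M60 <- choose(60, 2)
  set.seed(4)
  ps <- replicate(200, {
    m <- rep(FALSE, M60); m[sample.int(M60, 400)] <- TRUE
    r <- lobe_block_permutation(m, part60, n_perm = 1000,
                                seed = sample.int(1e6, 1))
    r$p[r$lobe_i == "A" & r$lobe_j == "B"]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
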
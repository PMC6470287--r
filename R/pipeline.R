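#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' study defaults: suppression detection, canonical HRF, 10 dropped leading
#' volumes, nuisance regression before 0.01-0.1 Hz filtering, edgewise
#' threshold 0.001 with component-level 0.05 over 5000 permutations, and
#' Bonferroni-corrected parcel/target tests at 0.05. All randomness flows
#' from `seed`.
#'
#' @param detection [detection_params()].
#' @param hrf [hrf_params()].
#' @param n_drop leading volumes discarded (default 10).
#' @param preproc [preproc_config()] used for the corrected pipeline; the
#'   BS regressor is always included for BS runs at the preprocessing stage.
#' @param edge_alpha,cluster_alpha,n_perm network-based-statistic settings.
#' @param alpha Bonferroni family-wise level for parcel/target tests.
#' @param seed master seed for permutation procedures.
#' @param partition lobe partition (data.frame `region`, `lobe`).
#' @export
pipeline_config <- function(detection = detection_params(),
                            hrf = hrf_params(), n_drop = 10,
                            preproc = preproc_config(),
                            edge_alpha = 0.001, cluster_alpha = 0.05,
                            n_perm = 5000, alpha = 0.05, seed = 1,
                            partition = default_parcellation()) {
  list(detection = detection, hrf = hrf, n_drop = n_drop, preproc = preproc,
       edge_alpha = edge_alpha, cluster_alpha = cluster_alpha,
       n_perm = n_perm, alpha = alpha, seed = seed, partition = partition)
}

#' Mean off-diagonal functional connectivity
#'
#' Summary statistic of global connectivity level — the quantity inflated by
#' uncorrected burst-suppression coupling.
#'
#' @param m an `fc_matrix`.
#' @export
mean_offdiag <- function(m) {
  mean(m[upper.tri(m)])
}

# derive a run's binary pattern: detect from EEG when available, otherwise
# fall back to the simulated pattern or stored intervals
run_pattern <- function(record, config) {
  duration <- ncol(record$bold$data) * record$bold$tr
  if (!is.null(record$eeg)) {
    ivals <- detect_suppressions(record$eeg, config$detection)
    make_binary_pattern(ivals, duration, record$eeg$sample_rate)
  } else if (!is.null(record$pattern)) {
    record$pattern
  } else if (!is.null(record$true_intervals)) {
    make_binary_pattern(record$true_intervals, duration, 100)
  } else {
    stop("BS run without EEG, pattern or intervals: ", record$subject,
         "/", record$run)
  }
}

#' Run the full burst-suppression connectivity analysis on a cohort
#'
#' Executes the end-to-end pipeline on in-memory cohort records (from
#' [simulate_cohort()] or [read_cohort()]):
#' suppression detection and BS-regressor construction for BS runs; dropping
#' of leading volumes; preprocessing in two variants — standard (nuisance
#' only) and corrected (nuisance + BS regressor for BS runs); per-run and
#' group-level coupling statistics on the standard-preprocessed BS runs;
#' whole-brain FC, edgewise group comparison and network-based-statistic
#' correction on the corrected runs; lobe-block residual permutation on the
#' significant edges; and seed-based group comparison for the default seeds.
#'
#' @param records cohort record list.
#' @param config a [pipeline_config()].
#' @param physio optional physiology table for the group report.
#' @return List of class `bsfc_results` with elements `coupling`
#'   (`group_coupling_result`), `coupling_runs`, `bsr` (per-run detected
#'   BSR), `edge_stats` (`edge_group_stats`), `lobe_blocks`, `seed_results`,
#'   `fc_mean` (per-run mean off-diagonal FC for both preprocessing
#'   variants), `physio` and `parameters`.
#' @export
analyze_cohort <- function(records, config = pipeline_config(),
                           physio = NULL) {
  groups <- vapply(records, `[[`, "", "group")
  subjects <- vapply(records, `[[`, "", "subject")
  is_bs <- groups == "BS"
  if (!any(is_bs) || all(is_bs)) stop("cohort needs both BS and SW runs")

  n_volumes <- ncol(records[[1]]$bold$data)
  regressors <- vector("list", length(records))
  detected_bsr <- rep(0, length(records))
  for (i in which(is_bs)) {
    pat <- run_pattern(records[[i]], config)
    detected_bsr[i] <- compute_bsr(pat)
    regressors[[i]] <- build_bs_regressor(pat, records[[i]]$bold$tr,
                                          n_volumes, config$n_drop,
                                          config$hrf)
  }

  standard <- vector("list", length(records))
  corrected <- vector("list", length(records))
  for (i in seq_along(records)) {
    run <- drop_leading_volumes(records[[i]]$bold, config$n_drop)
    run$bs_regressor <- regressors[[i]]
    cfg_std <- config$preproc; cfg_std$include_bs_regressor <- FALSE
    standard[[i]] <- preprocess(run, cfg_std)
    cfg_cor <- config$preproc
    cfg_cor$include_bs_regressor <- is_bs[i]
    corrected[[i]] <- preprocess(run, cfg_cor)
  }

  coupling_runs <- lapply(which(is_bs), function(i) {
    fit_coupling_glm(standard[[i]], regressors[[i]])
  })
  coupling <- group_coupling_test(coupling_runs, subjects[is_bs],
                                  alpha = config$alpha)

  fc_std <- lapply(standard, fc_matrix)
  fc_cor <- lapply(corrected, fc_matrix)
  edge_stats <- nbs_correction(fc_cor, groups, subjects,
                               edge_alpha = config$edge_alpha,
                               cluster_alpha = config$cluster_alpha,
                               n_perm = config$n_perm, seed = config$seed)

  lobe_blocks <- NULL
  if (any(edge_stats$edges$significant)) {
    lobe_blocks <- lobe_block_permutation(
      edge_stats$edges$significant,
      config$partition, regions = records[[1]]$bold$regions,
      n_perm = config$n_perm, seed = config$seed + 1, alpha = config$alpha)
  }

  seeds <- default_seeds()
  seeds <- Filter(function(s) all(s$seed_regions %in%
                                    records[[1]]$bold$regions), seeds)
  seed_results <- lapply(seeds, function(sd) {
    maps <- lapply(corrected, seed_connectivity, seed = sd)
    seed_group_compare(maps, groups, subjects, alpha = config$alpha)
  })

  structure(list(
    coupling = coupling, coupling_runs = coupling_runs,
    bsr = data.frame(subject = subjects, group = groups,
                     detected_bsr = detected_bsr),
    edge_stats = edge_stats, lobe_blocks = lobe_blocks,
    seed_results = seed_results,
    fc_mean = data.frame(
      subject = subjects, group = groups,
      standard = vapply(fc_std, mean_offdiag, numeric(1)),
      corrected = vapply(fc_cor, mean_offdiag, numeric(1))),
    physio = if (!is.null(physio)) physio_report(physio),
    parameters = config[c("edge_alpha", "cluster_alpha", "n_perm",
                          "n_drop", "alpha", "seed")]
  ), class = "bsfc_results")
}

#' @rdname analyze_cohort
#' @param manifest_path path to a cohort manifest on disk; inputs are
#'   validated (all referenced files must exist) before any computation.
#' @export
run_full_analysis <- function(manifest_path, config = pipeline_config(),
                              physio = NULL) {
  records <- read_cohort(manifest_path)
  analyze_cohort(records, config, physio)
}
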
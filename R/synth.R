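#' Burst-suppression alternation parameters
#'
#' The alternation is modelled as an alternating renewal process: burst and
#' suppression durations drawn independently from exponential (default,
#' memoryless) or gamma distributions. The long-run expected BSR is
#' `mean_suppression / (mean_burst + mean_suppression) * 100`. Default
#' durations (15 s bursts, 5 s suppressions, a 20 s cycle) describe a stable,
#' slowly alternating burst-suppression regime whose alternation frequency
#' (~0.05 Hz) lies inside the conventional 0.01-0.1 Hz BOLD band; published
#' recordings do not constrain the duration law further.
#'
#' @param mean_burst_duration,mean_suppression_duration mean state durations (s).
#' @param duration_distribution `"exponential"` or `"gamma"`.
#' @param gamma_shape shape parameter when `duration_distribution = "gamma"`
#'   (larger = more regular cycling).
#' @param total_duration simulated recording length (s).
#' @param sample_rate pattern/EEG sampling rate (Hz).
#' @export
bs_sim_params <- function(mean_burst_duration = 15, mean_suppression_duration = 5,
                          duration_distribution = c("exponential", "gamma"),
                          gamma_shape = 3, total_duration = 400,
                          sample_rate = 500) {
  duration_distribution <- match.arg(duration_distribution)
  if (mean_burst_duration <= 0 || total_duration <= 0 || sample_rate <= 0 ||
      mean_suppression_duration < 0 || gamma_shape <= 0) {
    stop("durations, gamma_shape and sample_rate must be positive")
  }
  list(mean_burst_duration = mean_burst_duration,
       mean_suppression_duration = mean_suppression_duration,
       duration_distribution = duration_distribution,
       gamma_shape = gamma_shape,
       total_duration = total_duration,
       sample_rate = sample_rate)
}

draw_duration <- function(n, mean, params) {
  if (params$duration_distribution == "exponential") {
    stats::rexp(n, rate = 1 / mean)
  } else {
    stats::rgamma(n, shape = params$gamma_shape,
                  scale = mean / params$gamma_shape)
  }
}

#' Simulate a burst-suppression pattern
#'
#' Draws alternating burst/suppression intervals (starting in burst) until
#' `total_duration` is covered and samples the binary series on the uniform
#' grid. With `mean_suppression_duration = 0` suppression is disabled and the
#' pattern is all ones (a slow-wave run).
#'
#' @param params a [bs_sim_params()] list.
#' @param seed integer RNG seed.
#' @return List with `pattern` (a [bs_pattern]) and `intervals` (the
#'   continuous-time ground-truth suppression intervals, clipped to
#'   `[0, total_duration)`).
#' @export
simulate_bs_pattern <- function(params, seed) {
  set.seed(seed)
  total <- params$total_duration
  ivals <- matrix(numeric(0), ncol = 2)
  if (params$mean_suppression_duration > 0) {
    t <- 0
    repeat {
      t <- t + draw_duration(1, params$mean_burst_duration, params)
      if (t >= total) break
      supp <- draw_duration(1, params$mean_suppression_duration, params)
      ivals <- rbind(ivals, c(t, min(t + supp, total)))
      t <- t + supp
      if (t >= total) break
    }
  }
  pattern <- make_binary_pattern(ivals, total, params$sample_rate)
  list(pattern = pattern, intervals = as_intervals(ivals))
}

#' EEG simulation parameters
#'
#' Two-regime amplitude model: a band-limited oscillation whose RMS is
#' `burst_amplitude` during non-suppression and `suppression_amplitude`
#' during suppression, plus white channel noise. All channels share the same
#' underlying pattern, as burst suppression is globally synchronized.
#'
#' @param n_channels number of EEG channels (default 21, the usable channels
#'   of a 28-electrode macaque cap).
#' @param burst_amplitude,suppression_amplitude regime RMS amplitudes (uV).
#' @param burst_band oscillation band (Hz), must lie inside (0, Nyquist).
#' @param channel_noise_sd additive white noise SD (uV).
#' @export
eeg_sim_params <- function(n_channels = 21, burst_amplitude = 50,
                           suppression_amplitude = 2.5,
                           burst_band = c(1, 30), channel_noise_sd = 1) {
  if (n_channels < 1) stop("need at least one channel")
  if (burst_amplitude <= suppression_amplitude || suppression_amplitude < 0) {
    stop("burst_amplitude must exceed suppression_amplitude >= 0")
  }
  if (burst_band[1] <= 0 || burst_band[2] <= burst_band[1]) {
    stop("invalid burst_band")
  }
  list(n_channels = n_channels, burst_amplitude = burst_amplitude,
       suppression_amplitude = suppression_amplitude,
       burst_band = burst_band, channel_noise_sd = channel_noise_sd)
}

#' Simulate multichannel EEG from a burst-suppression pattern
#'
#' @param pattern a [bs_pattern] at the EEG sampling rate.
#' @param params an [eeg_sim_params()] list.
#' @param seed integer RNG seed.
#' @return An [eeg_recording] with `n_channels` rows.
#' @export
simulate_eeg <- function(pattern, params, seed) {
  stopifnot(inherits(pattern, "bs_pattern"))
  fs <- pattern$sample_rate
  if (params$burst_band[2] >= fs / 2) {
    stop("burst_band must lie below the Nyquist frequency ", fs / 2, " Hz")
  }
  set.seed(seed)
  n <- length(pattern$values)
  env <- ifelse(pattern$values == 1L, params$burst_amplitude,
                params$suppression_amplitude)
  bf <- signal::butter(4, params$burst_band / (fs / 2), type = "pass")
  data <- matrix(0, params$n_channels, n)
  for (i in seq_len(params$n_channels)) {
    carrier <- signal::filtfilt(bf, stats::rnorm(n))
    carrier <- carrier / stats::sd(carrier)
    data[i, ] <- carrier * env + stats::rnorm(n, sd = params$channel_noise_sd)
  }
  eeg_recording(data, fs)
}

nuisance_names <- function() {
  c("mot1", "mot2", "mot3", "mot4", "mot5", "mot6", "wm", "csf")
}

# AR(1) series with unit marginal variance
ar1_series <- function(n, phi = 0.9) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov_sd <- sqrt(1 - phi^2)
  for (t in 2:n) x[t] <- phi * x[t - 1] + stats::rnorm(1, sd = innov_sd)
  x
}

#' Latent connectivity blocks of the default generator
#'
#' Each block is a latent factor loaded by a named region set; two parcels
#' loading `l_i`, `l_j` on the same factor acquire covariance `l_i * l_j`.
#' In BS-group runs the loading is `loading + delta`, so `delta != 0` injects
#' a known group difference in edge covariance. Defaults emulate the
#' networks of interest: a DMN-like block that persists in both states and
#' strengthens slightly under burst suppression, a thalamocortical block that
#' recovers under burst suppression, and an orbitofrontal block carrying the
#' largest group effect.
#'
#' @return List of blocks, each `list(name, regions, loading, delta)`.
#' @export
default_latent_blocks <- function() {
  bi <- function(x) c(paste0("L_", x), paste0("R_", x))
  list(
    list(name = "DMN", regions = bi(c("PCC", "RSC", "IPL", "PFCdm", "PFCdl")),
         loading = 0.8, delta = 0.2),
    list(name = "thalamocortical",
         regions = bi(c("Thal", "Put", "S1", "S2", "A1", "V1")),
         loading = 0.3, delta = 0.4),
    list(name = "OFC", regions = bi(c("OFCm", "OFCl", "OFCp")),
         loading = 0.4, delta = 0.5)
  )
}

#' BOLD simulation parameters
#'
#' The generative model for a parcel-by-volume run:
#' `Y[p, ] = beta[p] * s + sum_b L[p, b] * f_b + (W G N')[p, ] + e[p, ]`
#' where `s` is the HRF-convolved binary BS pattern sampled at volume onsets
#' (BS-group runs only), `f_b` are standard-normal latent block factors with
#' loadings `L` from `latent_blocks` (+`delta` in BS runs), `N` is the
#' simulated nuisance table (six AR(1) motion series plus WM and CSF, lag-1
#' coefficient 0.9), `G = diag(nuisance_gain)`, `W` a parcels-by-regressor
#' weight matrix drawn once per run from N(1, 0.3), and `e` white noise.
#'
#' @param n_parcels,n_volumes,tr acquisition geometry (defaults 94 regions,
#'   200 volumes, TR 2 s).
#' @param coupling_betas per-parcel BS coupling coefficients for BS runs, or
#'   `NULL` to draw them from N(`coupling_mean`, `coupling_sd`) per run.
#' @param coupling_mean,coupling_sd distribution of drawn coupling betas;
#'   positive mean mirrors the predominantly positive coupling seen in vivo.
#' @param latent_blocks see [default_latent_blocks()].
#' @param nuisance_gain length-8 gains of the nuisance contributions.
#' @param noise_sd white-noise SD (signal units).
#' @param regions parcel labels; defaults to [default_parcellation()].
#' @export
bold_sim_params <- function(n_parcels = 94, n_volumes = 200, tr = 2,
                            coupling_betas = NULL, coupling_mean = 1,
                            coupling_sd = 0.25,
                            latent_blocks = default_latent_blocks(),
                            nuisance_gain = rep(0.5, 8), noise_sd = 1,
                            regions = NULL) {
  if (n_parcels < 2 || tr <= 0 || n_volumes < 3) stop("invalid geometry")
  if (is.null(regions)) {
    pc <- default_parcellation()
    regions <- if (n_parcels == nrow(pc)) pc$region else
      sprintf("P%03d", seq_len(n_parcels))
  }
  if (length(regions) != n_parcels) stop("one label per parcel required")
  for (b in latent_blocks) {
    if (!all(b$regions %in% regions)) {
      # blocks referencing absent regions are dropped silently only if the
      # caller shrank the parcellation; treat as an error otherwise
      stop("latent block '", b$name, "' references unknown regions")
    }
  }
  list(n_parcels = n_parcels, n_volumes = n_volumes, tr = tr,
       coupling_betas = coupling_betas, coupling_mean = coupling_mean,
       coupling_sd = coupling_sd, latent_blocks = latent_blocks,
       nuisance_gain = nuisance_gain, noise_sd = noise_sd, regions = regions)
}

#' Parcel-level BOLD run container
#'
#' @param data parcels x volumes matrix.
#' @param regions parcel labels.
#' @param tr repetition time (s).
#' @param subject,group run identity; `group` is `"BS"` or `"SW"`.
#' @param nuisance volumes x 8 nuisance table (six motion parameters, white
#'   matter, CSF).
#' @param bs_regressor optional `volume_regressor` attached for preprocessing.
#' @param ground_truth optional generator ground truth.
#' @export
bold_run <- function(data, regions, tr, subject, group, nuisance,
                     bs_regressor = NULL, ground_truth = NULL) {
  data <- as.matrix(data)
  if (!group %in% c("BS", "SW")) stop("group must be 'BS' or 'SW'")
  if (length(regions) != nrow(data)) stop("one label per parcel required")
  if (anyDuplicated(regions)) stop("region labels must be unique")
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != ncol(data)) {
    stop("nuisance rows must match retained volumes")
  }
  rownames(data) <- regions
  structure(list(data = data, regions = regions, tr = tr, subject = subject,
                 group = group, nuisance = nuisance,
                 bs_regressor = bs_regressor, ground_truth = ground_truth,
                 stages = character(0)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s/%s: %d parcels x %d volumes, TR %g s [%s]\n",
              x$subject, x$group, nrow(x$data), ncol(x$data), x$tr,
              if (length(x$stages)) paste(x$stages, collapse = " -> ")
              else "raw"))
  invisible(x)
}

#' Simulate one parcel-level BOLD run
#'
#' See [bold_sim_params()] for the generative model. BS-group runs require a
#' pattern covering `n_volumes * tr` seconds; SW-group runs take
#' `pattern = NULL` (no coupling term).
#'
#' @param pattern a [bs_pattern] or `NULL`.
#' @param params a [bold_sim_params()] list.
#' @param subject subject ID.
#' @param group `"BS"` or `"SW"`.
#' @param seed integer RNG seed.
#' @return A [bold_run] with `ground_truth` recording the drawn coupling
#'   betas, applied block loadings, the injected volume-grid coupling time
#'   course, and the pattern's suppression intervals and BSR.
#' @export
simulate_bold_run <- function(pattern, params, subject, group, seed) {
  if (group == "BS" && is.null(pattern)) stop("BS runs require a pattern")
  nv <- params$n_volumes; np <- params$n_parcels
  if (!is.null(pattern) &&
      pattern$duration < (nv - 1) * params$tr) {
    stop("pattern does not cover the acquisition")
  }
  set.seed(seed)
  Y <- matrix(0, np, nv)
  truth <- list(betas = rep(0, np), intervals = NULL, achieved_bsr = 0,
                coupling_series = rep(0, nv), blocks = list())
  if (group == "BS") {
    s <- convolved_pattern_at_volumes(pattern, params$tr, nv)
    betas <- params$coupling_betas
    if (is.null(betas)) {
      betas <- stats::rnorm(np, params$coupling_mean, params$coupling_sd)
    }
    Y <- Y + outer(betas, s - mean(s))
    truth$betas <- betas
    truth$coupling_series <- s
    truth$intervals <- pattern$intervals
    truth$achieved_bsr <- compute_bsr(pattern)
  }
  for (b in params$latent_blocks) {
    l <- b$loading + if (group == "BS") b$delta else 0
    f <- stats::rnorm(nv)
    idx <- match(b$regions, params$regions)
    Y[idx, ] <- Y[idx, ] + l * rep(f, each = length(idx))
    truth$blocks[[b$name]] <- list(regions = b$regions, loading = l,
                                   delta = b$delta)
  }
  N <- vapply(seq_len(8), function(i) ar1_series(nv), numeric(nv))
  colnames(N) <- nuisance_names()
  W <- matrix(stats::rnorm(np * 8, 1, 0.3), np, 8)
  nuis_contrib <- W %*% (diag(params$nuisance_gain) %*% t(N))
  Y <- Y + nuis_contrib
  truth$nuisance_weights <- W
  truth$nuisance_contribution <- nuis_contrib
  if (params$noise_sd > 0) {
    Y <- Y + matrix(stats::rnorm(np * nv, sd = params$noise_sd), np, nv)
  }
  bold_run(Y, params$regions, params$tr, subject, group, nuisance = N,
           ground_truth = truth)
}

#' Cohort specification
#'
#' @param runs data.frame with columns `subject`, `session`, `run`, `group`
#'   (`"BS"`/`"SW"`) and `target_bsr` (percent; must be > 0 for BS rows and
#'   0 for SW rows).
#' @export
cohort_spec <- function(runs) {
  runs <- as.data.frame(runs)
  need <- c("subject", "session", "run", "group", "target_bsr")
  if (!all(need %in% names(runs))) {
    stop("cohort spec needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(runs[c("subject", "session", "run")])) {
    stop("duplicate (subject, session, run) keys in cohort spec")
  }
  if (!all(runs$group %in% c("BS", "SW"))) stop("group must be BS or SW")
  if (any(runs$group == "BS" & runs$target_bsr <= 0)) {
    stop("BS runs need target_bsr > 0")
  }
  if (any(runs$group == "SW" & runs$target_bsr != 0)) {
    stop("SW runs must have target_bsr = 0")
  }
  if (length(unique(runs$group)) < 2) stop("need at least one run per group")
  runs
}

#' Cohort specification mirroring the packaged physiology table
#'
#' Builds a [cohort_spec()] from the shipped per-run physiology fixture
#' (27 BS runs and 11 SW runs from two monkeys), using each run's recorded
#' BSR as its simulation target.
#'
#' @return data.frame usable with [simulate_cohort()].
#' @export
table1_cohort_spec <- function() {
  tb <- load_physio_table()
  cohort_spec(data.frame(subject = tb$subject, session = tb$session,
                         run = tb$run, group = tb$group,
                         target_bsr = tb$bsr_pct))
}

# split a target BSR into mean burst/suppression durations on a fixed cycle,
# flooring either state at 0.8 s to keep durations physiological; the 20 s
# default cycle keeps the alternation inside the 0.01-0.1 Hz BOLD passband
bsr_to_durations <- function(target_bsr, cycle = 20, floor_s = 0.8) {
  supp <- cycle * target_bsr / 100
  burst <- cycle - supp
  if (supp < floor_s) {
    supp <- floor_s
    burst <- floor_s * (100 - target_bsr) / target_bsr
  } else if (burst < floor_s) {
    burst <- floor_s
    supp <- floor_s * target_bsr / (100 - target_bsr)
  }
  c(burst = burst, suppression = supp)
}

#' Simulate a full EEG/BOLD cohort
#'
#' One record per spec row. Per-run seeds are derived deterministically from
#' the master seed, so an identical master seed reproduces the cohort
#' exactly. BS-run patterns target the spec's per-run BSR by splitting the
#' alternation cycle proportionally (see the vignette); SW runs have all-ones
#' patterns (BSR exactly 0).
#'
#' @param spec a [cohort_spec()] data.frame.
#' @param bs_params [bs_sim_params()]; per-run mean durations are overridden
#'   from `target_bsr`.
#' @param eeg_params [eeg_sim_params()], or `NULL` to skip EEG synthesis.
#' @param bold_params [bold_sim_params()].
#' @param seed master integer seed.
#' @return List of records `list(subject, session, run, group, target_bsr,
#'   achieved_bsr, pattern, true_intervals, eeg, bold)`.
#' @export
simulate_cohort <- function(spec, bs_params = bs_sim_params(),
                            eeg_params = eeg_sim_params(),
                            bold_params = bold_sim_params(), seed = 1) {
  spec <- cohort_spec(spec)
  records <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    run_seed <- (seed * 1009 + i * 101) %% .Machine$integer.max
    row <- spec[i, ]
    if (row$group == "BS") {
      dur <- bsr_to_durations(row$target_bsr)
      bp <- bs_params
      bp$mean_burst_duration <- dur[["burst"]]
      bp$mean_suppression_duration <- dur[["suppression"]]
      # a finite run realizes the renewal BSR only up to sampling noise;
      # re-draw (deterministically) until the run-level BSR is on target
      sim <- best <- simulate_bs_pattern(bp, run_seed)
      best_err <- abs(compute_bsr(best$pattern) - row$target_bsr)
      attempt <- 0
      while (best_err > 2 && attempt < 50) {
        attempt <- attempt + 1
        sim <- simulate_bs_pattern(bp, run_seed + 7919 * attempt)
        err <- abs(compute_bsr(sim$pattern) - row$target_bsr)
        if (err < best_err) { best <- sim; best_err <- err }
      }
      sim <- best
    } else {
      bp <- bs_params
      bp$mean_suppression_duration <- 0
      sim <- simulate_bs_pattern(bp, run_seed)
    }
    eeg <- if (!is.null(eeg_params)) {
      simulate_eeg(sim$pattern, eeg_params, run_seed + 1)
    }
    bold <- simulate_bold_run(if (row$group == "BS") sim$pattern else NULL,
                              bold_params, row$subject, row$group,
                              run_seed + 2)
    records[[i]] <- list(subject = row$subject, session = row$session,
                         run = row$run, group = row$group,
                         target_bsr = row$target_bsr,
                         achieved_bsr = compute_bsr(sim$pattern),
                         pattern = sim$pattern,
                         true_intervals = sim$intervals,
                         eeg = eeg, bold = bold)
  }
  records
}
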
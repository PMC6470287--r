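# small shared builders; everything is generated in code at test time

tiny_regions <- function(n) sprintf("P%03d", seq_len(n))

# a noise-only BOLD parameter set (no coupling, no blocks, no nuisance signal)
null_bold_params <- function(n_parcels = 20, n_volumes = 100) {
  bold_sim_params(n_parcels = n_parcels, n_volumes = n_volumes,
                  coupling_betas = rep(0, n_parcels), latent_blocks = list(),
                  nuisance_gain = rep(0, 8), noise_sd = 1,
                  regions = tiny_regions(n_parcels))
}

# quick run wrapper around simulate_bold_run for SW noise runs
null_run <- function(params, subject = "O", seed = 1) {
  simulate_bold_run(NULL, params, subject, "SW", seed)
}

# a deterministic bold_run built from an explicit matrix
manual_run <- function(data, tr = 2, subject = "O", group = "SW",
                       nuisance = NULL) {
  if (is.null(nuisance)) {
    # deterministic low-discrepancy filler that leaves the RNG stream alone
    k <- seq_len(ncol(data) * 8)
    u <- (k * (sqrt(5) - 1) / 2) %% 1
    nuisance <- matrix(qnorm(0.001 + 0.998 * u), ncol(data), 8,
                       dimnames = list(NULL, bsfc:::nuisance_names()))
  }
  bold_run(data, tiny_regions(nrow(data)), tr, subject, group, nuisance)
}

# two-lobe partition over 6 regions, 3 regions each (hand-checkable geometry)
two_lobe_partition <- function() {
  data.frame(region = tiny_regions(6),
             lobe = rep(c("A", "B"), each = 3))
}
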
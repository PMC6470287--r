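#' Default 94-region parcellation with lobe assignments
#'
#' A Regional-Map-style cortical parcellation (41 areas per hemisphere, 82
#' cortical regions) plus 12 subcortical regions, each assigned to one of nine
#' lobes: OFC, PFC, cingulate, motor_somatosensory, insula, temporal,
#' parietal, occipital, subcortical. The table is generated in code and fully
#' user-replaceable; any data frame with columns `region` and `lobe` covering
#' the parcels of a cohort works wherever a partition is required.
#'
#' @return data.frame with columns `region`, `hemisphere`, `lobe` (94 rows).
#' @export
default_parcellation <- function() {
  areas <- list(
    OFC = c("OFCm", "OFCl", "OFCp"),
    PFC = c("PFCdl", "PFCdm", "PFCvl", "PFCpol", "PFCcl", "FEF", "PrCO"),
    cingulate = c("ACC", "MCC", "PCC", "RSC"),
    motor_somatosensory = c("M1", "PMd", "PMv", "SMA", "S1", "S2"),
    insula = c("Ia", "Ip"),
    temporal = c("A1", "A2", "STG", "STSd", "STSv", "ITG", "TCpol"),
    parietal = c("PCip", "PCs", "PCm", "IPL", "SPL", "PCun"),
    occipital = c("V1", "V2", "V3", "V4", "MT", "VACd")
  )
  sub <- c("Thal", "Put", "Cd", "GP", "Hip", "Amy")
  rows <- list()
  for (hemi in c("L", "R")) {
    for (lobe in names(areas)) {
      rows[[length(rows) + 1]] <- data.frame(
        region = paste(hemi, areas[[lobe]], sep = "_"),
        hemisphere = hemi, lobe = lobe
      )
    }
    rows[[length(rows) + 1]] <- data.frame(
      region = paste(hemi, sub, sep = "_"),
      hemisphere = hemi, lobe = "subcortical"
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seed specification
#'
#' @param seed_regions region labels forming the seed (averaged together).
#' @param name display name.
#' @export
seed_spec <- function(seed_regions, name = paste(seed_regions, collapse = "+")) {
  if (length(seed_regions) == 0) stop("seed must contain at least one region")
  list(seed_regions = seed_regions, name = name)
}

#' Canonical seeds of the default parcellation
#'
#' Bilateral posterior cingulate cortex (the default-mode anchor) and
#' bilateral thalamus.
#'
#' @return Named list of [seed_spec()] objects `PCC` and `thalamus`.
#' @export
default_seeds <- function() {
  list(
    PCC = seed_spec(c("L_PCC", "R_PCC"), "PCC"),
    thalamus = seed_spec(c("L_Thal", "R_Thal"), "thalamus")
  )
}
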
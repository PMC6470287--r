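#' @name bsfc-io
#' @title Text-format readers and writers
#' @description
#' All artifacts are exchanged as delimiter-separated text for auditability:
#' EEG as one column per channel with a YAML sidecar carrying the sampling
#' rate and channel names; suppression intervals as 3-column text (onset s,
#' offset s, label); binary patterns and volume regressors as single-column
#' tables; parcel-by-time and FC matrices as TSV with region-label headers.
#' Every writer/reader pair round-trips with numeric fidelity better than
#' 1e-12.
NULL

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' @rdname bsfc-io
#' @param eeg an [eeg_recording].
#' @param path output file; the sidecar is written next to it as
#'   `<path>.yaml`.
#' @export
write_eeg <- function(eeg, path) {
  df <- as.data.frame(t(eeg$data))
  names(df) <- eeg$channels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(sample_rate = eeg$sample_rate,
                        channels = as.list(eeg$channels)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname bsfc-io
#' @export
read_eeg <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- utils::read.delim(path, check.names = FALSE)
  eeg_recording(t(as.matrix(df)), meta$sample_rate,
                unlist(meta$channels))
}

#' @rdname bsfc-io
#' @param intervals two-column (onset, offset) matrix in seconds.
#' @param label interval label written in the third column.
#' @export
write_intervals <- function(intervals, path, label = "suppression") {
  intervals <- as_intervals(intervals)
  df <- data.frame(onset = fmt_num(intervals[, 1]),
                   offset = fmt_num(intervals[, 2]),
                   label = rep(label, nrow(intervals)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname bsfc-io
#' @export
read_intervals <- function(path) {
  df <- utils::read.delim(path)
  if (!all(c("onset", "offset") %in% names(df))) {
    stop("malformed interval file (need onset/offset columns): ", path)
  }
  ivals <- as_intervals(cbind(df$onset, df$offset))
  check_disjoint(ivals)
  ivals
}

#' @rdname bsfc-io
#' @param regressor a `volume_regressor`.
#' @export
write_regressor <- function(regressor, path) {
  utils::write.table(
    data.frame(bs_regressor = fmt_num(regressor$values)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(tr = regressor$tr,
                        n_dropped_leading_volumes =
                          regressor$n_dropped_leading_volumes),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname bsfc-io
#' @export
read_regressor <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- utils::read.delim(path)
  structure(list(values = as.numeric(df$bs_regressor), tr = meta$tr,
                 n_dropped_leading_volumes = meta$n_dropped_leading_volumes),
            class = "volume_regressor")
}

#' @rdname bsfc-io
#' @param m a parcels-by-volumes matrix with region rownames, or an
#'   `fc_matrix`. Parcel matrices are stored volumes-by-parcels with the
#'   region labels as header.
#' @export
write_parcel_matrix <- function(m, path) {
  df <- as.data.frame(apply(t(m), 2, fmt_num))
  names(df) <- rownames(m)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname bsfc-io
#' @export
read_parcel_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df))
  storage.mode(m) <- "double"
  m
}

#' @rdname bsfc-io
#' @export
write_fc_matrix <- function(m, path) {
  labels <- rownames(m)
  df <- cbind(data.frame(region = labels),
              as.data.frame(apply(unclass(m), 2, fmt_num)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname bsfc-io
#' @export
read_fc_matrix <- function(path, scale = "r") {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- df$region
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(labels, colnames(m))) {
    stop("malformed FC matrix file (not square or labels disagree): ", path)
  }
  dimnames(m) <- list(labels, colnames(m))
  structure(m, class = c("fc_matrix", "matrix"), scale = scale)
}

#' @rdname bsfc-io
#' @param manifest data.frame with one row per run: `subject`, `session`,
#'   `run`, `group`, file path columns (`bold_file`, `nuisance_file`,
#'   optionally `eeg_file`, `intervals_file`) and `achieved_bsr`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname bsfc-io
#' @param base_dir directory against which relative manifest paths resolve.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "session", "run", "group", "bold_file")
  if (!all(need %in% names(mf))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(mf[c("subject", "session", "run")])) {
    stop("duplicate (subject, session, run) keys in manifest")
  }
  path_cols <- intersect(c("bold_file", "nuisance_file", "eeg_file",
                           "intervals_file"), names(mf))
  for (col in path_cols) {
    vals <- mf[[col]]
    vals[is.na(vals)] <- ""
    mf[[col]] <- as.character(vals)
    p <- file.path(base_dir, mf[[col]])
    missing <- !file.exists(p) & nzchar(mf[[col]])
    if (any(missing)) {
      stop("manifest references missing file(s): ",
           paste(mf[[col]][missing], collapse = ", "))
    }
    mf[[col]] <- p
  }
  mf
}

#' Write a simulated cohort to a directory
#'
#' Materializes the records of [simulate_cohort()] as text files (BOLD
#' parcel matrices, nuisance tables, optional EEG and true suppression
#' intervals) plus a manifest mirroring the physiology-table layout.
#'
#' @param records output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param with_eeg write EEG files as well (large; default FALSE).
#' @return Path of the manifest file.
#' @export
write_cohort <- function(records, dir, with_eeg = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    stem <- sprintf("%s_s%s_r%s", r$subject, r$session, r$run)
    bold_file <- paste0(stem, "_bold.tsv")
    nuis_file <- paste0(stem, "_nuisance.tsv")
    write_parcel_matrix(r$bold$data, file.path(dir, bold_file))
    nu <- r$bold$nuisance
    utils::write.table(as.data.frame(apply(nu, 2, fmt_num)),
                       file.path(dir, nuis_file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    iv_file <- paste0(stem, "_suppression.tsv")
    write_intervals(r$true_intervals, file.path(dir, iv_file))
    eeg_file <- ""
    if (with_eeg && !is.null(r$eeg)) {
      eeg_file <- paste0(stem, "_eeg.tsv")
      write_eeg(r$eeg, file.path(dir, eeg_file))
    }
    data.frame(subject = r$subject, session = r$session, run = r$run,
               group = r$group, target_bsr = r$target_bsr,
               achieved_bsr = r$achieved_bsr, bold_file = bold_file,
               nuisance_file = nuis_file, intervals_file = iv_file,
               eeg_file = eeg_file, tr = r$bold$tr)
  })
  mf_path <- file.path(dir, "manifest.tsv")
  write_manifest(do.call(rbind, rows), mf_path)
  mf_path
}

#' Read a cohort directory back into memory
#'
#' @param manifest_path path to a manifest written by [write_cohort()].
#' @return List of records with `bold` ([bold_run]) and `true_intervals`.
#' @export
read_cohort <- function(manifest_path) {
  mf <- read_manifest(manifest_path)
  lapply(seq_len(nrow(mf)), function(i) {
    row <- mf[i, ]
    data <- read_parcel_matrix(row$bold_file)
    nu <- as.matrix(utils::read.delim(row$nuisance_file))
    run <- bold_run(data, rownames(data), row$tr, row$subject, row$group,
                    nuisance = nu)
    ivals <- if (nzchar(row$intervals_file) && file.exists(row$intervals_file)) {
      read_intervals(row$intervals_file)
    }
    list(subject = row$subject, session = row$session, run = row$run,
         group = row$group, target_bsr = row$target_bsr,
         achieved_bsr = row$achieved_bsr, bold = run,
         true_intervals = ivals, pattern = NULL, eeg = NULL)
  })
}
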
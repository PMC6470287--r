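#' Multichannel EEG recording
#'
#' Lightweight container: a channels-by-samples numeric matrix plus sampling
#' rate and channel names.
#'
#' @param data channels x samples matrix (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param channels optional channel names; defaults to `ch01..chNN`.
#' @export
eeg_recording <- function(data, sample_rate, channels = NULL) {
  data <- as.matrix(data)
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channels) != nrow(data)) stop("one name per channel required")
  rownames(data) <- channels
  structure(list(data = data, sample_rate = sample_rate, channels = channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s), %.1f s @ %g Hz\n",
              nrow(x$data), ncol(x$data) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Suppression-detection parameters
#'
#' Defaults chosen to make detection deterministic and auditable: a 0.25 s
#' moving-RMS envelope per channel, normalized by the channel's 90th
#' percentile (a robust estimate of burst-level amplitude), summed across
#' channels; samples whose mean normalized envelope falls below
#' `threshold_fraction` are suppression candidates. Suppression runs shorter
#' than `min_suppression` are discarded and non-suppression gaps shorter than
#' `min_burst_gap` are merged into the surrounding suppression.
#'
#' @param envelope_window moving-RMS window (s).
#' @param threshold_fraction fraction of the robust burst level below which a
#'   sample counts as suppressed, in (0, 1).
#' @param min_suppression minimum suppression duration retained (s).
#' @param min_burst_gap maximum non-suppression gap merged away (s).
#' @export
detection_params <- function(envelope_window = 0.25, threshold_fraction = 0.25,
                             min_suppression = 0.5, min_burst_gap = 0.2) {
  p <- list(envelope_window = envelope_window,
            threshold_fraction = threshold_fraction,
            min_suppression = min_suppression,
            min_burst_gap = min_burst_gap)
  if (any(unlist(p) <= 0)) stop("all detection parameters must be positive")
  if (threshold_fraction >= 1) stop("threshold_fraction must be below 1")
  p
}

# centered moving RMS; edges padded by replicating the nearest valid value
moving_rms <- function(x, window_samples) {
  w <- max(1L, as.integer(window_samples))
  y <- stats::filter(x^2, rep(1 / w, w), sides = 2)
  y <- as.numeric(y)
  ok <- which(!is.na(y))
  y[seq_len(ok[1] - 1)] <- y[ok[1]]
  y[seq(ok[length(ok)] + 1, length.out = length(y) - ok[length(ok)])] <-
    y[ok[length(ok)]]
  sqrt(pmax(y, 0))
}

#' Detect suppression epochs in an EEG recording
#'
#' Implements amplitude-threshold suppression detection: each channel's
#' moving-RMS envelope is normalized by its own robust burst level (90th
#' percentile), envelopes are averaged across channels, and samples below
#' `threshold_fraction` of the burst level are marked suppressed.
#' Normalization makes the detector invariant to global amplitude rescaling
#' and to inter-channel gain differences. Short suppressions are discarded
#' and short non-suppression gaps merged, in that order. Because the coarse
#' moving-RMS window biases threshold crossings towards the burst regime by
#' a fixed fraction of the window, each retained onset/offset is then
#' refined on a five-times-finer envelope by a step fit around the
#' mid-power level between the local burst and suppression amplitudes,
#' which is unbiased to first order.
#'
#' @param eeg an [eeg_recording].
#' @param params a [detection_params()] list.
#' @return Two-column matrix of half-open suppression intervals
#'   `[onset, offset)` in seconds, sorted and disjoint (possibly zero rows).
#' @export
detect_suppressions <- function(eeg, params = detection_params()) {
  stopifnot(inherits(eeg, "eeg_recording"))
  fs <- eeg$sample_rate
  n <- ncol(eeg$data)
  if (params$envelope_window >= n / fs) {
    stop("envelope_window must be shorter than the recording")
  }
  sds <- apply(eeg$data, 1, stats::sd)
  if (all(sds == 0)) stop("no amplitude contrast: flat (zero-variance) recording")
  w <- max(2L, round(params$envelope_window * fs))
  wf <- max(2L, round(w / 5))
  env <- matrix(0, nrow(eeg$data), n)
  env_fine <- matrix(0, nrow(eeg$data), n)
  for (i in seq_len(nrow(eeg$data))) {
    e <- moving_rms(eeg$data[i, ], w)
    ref <- stats::quantile(e, 0.9, names = FALSE)
    if (ref == 0) ref <- 1
    env[i, ] <- e / ref
    env_fine[i, ] <- moving_rms(eeg$data[i, ], wf) / ref
  }
  summed <- colMeans(env)
  fine <- colMeans(env_fine)
  suppressed <- as.integer(summed >= params$threshold_fraction) # 0 = suppression

  # the coarse moving-RMS envelope crosses the threshold only once the burst
  # fraction of the window falls below threshold_fraction^2 (in power), which
  # shrinks every suppression run by ~w * (1/2 - threshold^2) per edge;
  # dilate by that known bias so the duration filters see unbiased lengths
  d <- round(w * (0.5 - params$threshold_fraction^2))
  suppressed <- dilate_zeros(suppressed, d)

  # drop suppression runs shorter than min_suppression
  suppressed <- drop_short_runs(suppressed, value = 0L,
                                min_len = round(params$min_suppression * fs))
  # merge non-suppression gaps shorter than min_burst_gap (only gaps between
  # suppressions, not the leading/trailing burst segments)
  suppressed <- merge_short_gaps(suppressed,
                                 max_gap = round(params$min_burst_gap * fs))
  refine_edges(suppressed, fine, w, fs)
}

# step-fit refinement: around each coarse edge, place the transition where
# the fine envelope is best separated by the mid-power level between the
# burst level (robustly ~1 after normalization) and the local suppression
# level; minimizing misclassified samples is insensitive to envelope noise
refine_edges <- function(suppressed, fine, w, fs) {
  n <- length(suppressed)
  ivals <- values_to_intervals(suppressed, 1)  # in samples (0-based)
  if (nrow(ivals) == 0) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("onset", "offset"))))
  }
  burst_level <- stats::median(fine[suppressed == 1L])
  out <- matrix(0, nrow(ivals), 2)
  for (k in seq_len(nrow(ivals))) {
    i0 <- ivals[k, 1] + 1L  # first suppressed sample, 1-based
    i1 <- ivals[k, 2]       # last suppressed sample, 1-based
    supp_level <- stats::median(fine[i0:i1])
    mid <- sqrt((burst_level^2 + supp_level^2) / 2)
    lo <- max(1L, i0 - w); hi <- min(i1, i0 + w)
    out[k, 1] <- step_fit(fine[lo:hi] < mid, falling = TRUE) + lo - 1L
    lo2 <- max(i0, i1 - w); hi2 <- min(n, i1 + w)
    out[k, 2] <- step_fit(fine[lo2:hi2] < mid, falling = FALSE) + lo2 - 1L
  }
  # refinement cannot create overlaps under the min-gap constraint, but
  # guard against pathological envelopes
  out[, 1] <- pmin(out[, 1], out[, 2])
  keep <- out[, 2] > out[, 1]
  out <- out[keep, , drop = FALSE]
  if (nrow(out) > 1) {
    for (k in 2:nrow(out)) out[k, 1] <- max(out[k, 1], out[k - 1, 2])
  }
  out <- out[out[, 2] > out[, 1], , drop = FALSE]
  out <- out / fs
  colnames(out) <- c("onset", "offset")
  out
}

# best split index (1-based, samples >= index are "after") of a logical
# step: falling = TRUE fits FALSE...TRUE, otherwise TRUE...FALSE
step_fit <- function(below, falling) {
  m <- length(below)
  # cost(j) = misclassified samples if the transition is placed before j
  pre <- c(0, cumsum(if (falling) below else !below))
  post <- rev(c(0, cumsum(rev(if (falling) !below else below))))
  which.min(pre[seq_len(m + 1)] + post[seq_len(m + 1)]) - 1L
}

# widen every zero run by d samples on each side
dilate_zeros <- function(x, d) {
  if (d <= 0 || !any(x == 0L)) return(x)
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- x
  for (k in which(r$values == 0L)) {
    out[max(1, starts[k] - d):min(n, ends[k] + d)] <- 0L
  }
  out
}

drop_short_runs <- function(x, value, min_len) {
  r <- rle(x)
  short <- r$values == value & r$lengths < min_len
  r$values[short] <- 1L - value
  inverse.rle(r)
}

merge_short_gaps <- function(x, max_gap) {
  r <- rle(x)
  k <- length(r$lengths)
  if (k >= 3) {
    interior <- which(r$values == 1L & seq_len(k) > 1 & seq_len(k) < k)
    fill <- interior[r$lengths[interior] < max_gap]
    r$values[fill] <- 0L
  }
  inverse.rle(r)
}
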
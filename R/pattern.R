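#' Binary burst-suppression pattern
#'
#' A `bs_pattern` holds the binary suppression series derived from EEG
#' (0 = suppression, 1 = non-suppression, i.e. burst or continuous activity)
#' on a uniform time grid, together with the equivalent list of suppression
#' intervals in seconds. Sample `i` (0-based) covers the half-open interval
#' `[i/sample_rate, (i+1)/sample_rate)`.
#'
#' @param values integer/numeric vector of 0s and 1s, one element per sample.
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `bs_pattern` with fields `values`,
#'   `sample_rate`, `duration` (seconds) and `intervals` (two-column matrix
#'   of half-open suppression intervals `[onset, offset)` in seconds).
#' @export
bs_pattern <- function(values, sample_rate) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  values <- as.integer(values)
  if (length(values) == 0L) stop("pattern must contain at least one sample")
  if (!all(values %in% c(0L, 1L))) stop("pattern values must be 0 or 1")
  structure(
    list(
      values = values,
      sample_rate = sample_rate,
      duration = length(values) / sample_rate,
      intervals = values_to_intervals(values, sample_rate)
    ),
    class = "bs_pattern"
  )
}

#' @export
print.bs_pattern <- function(x, ...) {
  cat(sprintf(
    "<bs_pattern> %.1f s @ %g Hz, %d suppression interval(s), BSR %.2f%%\n",
    x$duration, x$sample_rate, nrow(x$intervals), compute_bsr(x)
  ))
  invisible(x)
}

# run-length encode the zero runs of a binary vector into second intervals
values_to_intervals <- function(values, sample_rate) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 0L
  cbind(onset = starts[keep] / sample_rate, offset = ends[keep] / sample_rate)
}

#' Build a binary pattern from suppression intervals
#'
#' Inverse of the interval extraction: marks every sample whose midpoint time
#' grid index falls inside a suppression interval with 0, all others with 1.
#' The round trip intervals -> pattern -> intervals is the identity for
#' intervals aligned to the sample grid.
#'
#' @param intervals two-column matrix (onset, offset) in seconds, half-open,
#'   sorted and non-overlapping; may have zero rows.
#' @param duration total duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @return A [bs_pattern].
#' @export
make_binary_pattern <- function(intervals, duration, sample_rate) {
  intervals <- as_intervals(intervals)
  if (duration <= 0 || sample_rate <= 0) stop("duration and sample_rate must be positive")
  if (nrow(intervals) > 0) {
    if (any(intervals[, 1] < 0) || any(intervals[, 2] > duration + 1e-9)) {
      stop("intervals must lie within [0, duration)")
    }
    check_disjoint(intervals)
  }
  n <- round(duration * sample_rate)
  values <- rep(1L, n)
  for (k in seq_len(nrow(intervals))) {
    i0 <- round(intervals[k, 1] * sample_rate)      # 0-based first sample
    i1 <- round(intervals[k, 2] * sample_rate) - 1  # 0-based last sample
    if (i1 >= i0) values[(i0 + 1):min(i1 + 1, n)] <- 0L
  }
  bs_pattern(values, sample_rate)
}

as_intervals <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("onset", "offset"))))
  }
  x <- matrix(as.numeric(as.matrix(x)), ncol = 2)
  colnames(x) <- c("onset", "offset")
  if (any(x[, 2] <= x[, 1])) stop("interval offsets must exceed onsets")
  x[order(x[, 1]), , drop = FALSE]
}

check_disjoint <- function(intervals) {
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] < intervals[-nrow(intervals), 2] - 1e-12)) {
    stop("intervals overlap")
  }
  invisible(intervals)
}

#' Burst-suppression ratio
#'
#' BSR is the percentage of recording time spent in suppression:
#' `100 * (#suppressed samples / #samples)`.
#'
#' @param pattern a [bs_pattern].
#' @return BSR in percent, in `[0, 100]`.
#' @export
compute_bsr <- function(pattern) {
  stopifnot(inherits(pattern, "bs_pattern"))
  100 * mean(pattern$values == 0L)
}

#' Temporal Jaccard overlap of two interval sets
#'
#' Utility for comparing detected suppression intervals against ground truth:
#' total intersection length divided by total union length of the two sets.
#'
#' @param a,b two-column (onset, offset) matrices in seconds.
#' @return Jaccard index in `[0, 1]`; 1 when both sets are empty.
#' @export
interval_jaccard <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  len <- function(m) if (nrow(m)) sum(m[, 2] - m[, 1]) else 0
  inter <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    inter <- inter + sum(pmax(hi - lo, 0))
  }
  uni <- len(a) + len(b) - inter
  if (uni == 0) 1 else inter / uni
}

#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates the standard canonical HRF — a positive gamma-density lobe minus
#' a delayed undershoot lobe — on `[0, kernel_length]` at step `dt`, scaled so
#' the peak value is 1:
#' `h(t) = g(t; peak_delay, peak_dispersion) -
#'         g(t; undershoot_delay, undershoot_dispersion) / peak_undershoot_ratio`
#' where `g` is the gamma density with shape `delay/dispersion` and scale
#' `dispersion`.
#'
#' @param params list of HRF parameters; see [hrf_params()] for defaults
#'   (peak at 6 s, undershoot at 16 s, dispersions 1 s, ratio 6, 32 s kernel).
#' @param dt sampling step in seconds.
#' @return Numeric vector of kernel samples at `t = 0, dt, 2 dt, ...`.
#' @export
canonical_hrf <- function(params = hrf_params(), dt) {
  if (dt <= 0) stop("dt must be positive")
  p <- params
  t <- seq(0, p$kernel_length, by = dt)
  h <- stats::dgamma(t, shape = p$peak_delay / p$peak_dispersion,
                     scale = p$peak_dispersion) -
    stats::dgamma(t, shape = p$undershoot_delay / p$undershoot_dispersion,
                  scale = p$undershoot_dispersion) / p$peak_undershoot_ratio
  h / max(h)
}

#' HRF parameter set
#'
#' @param peak_delay,undershoot_delay delays of the positive and undershoot
#'   lobes (s).
#' @param peak_dispersion,undershoot_dispersion lobe dispersions (s).
#' @param peak_undershoot_ratio ratio of peak to undershoot amplitude.
#' @param kernel_length kernel support (s).
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  p <- list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
            peak_dispersion = peak_dispersion,
            undershoot_dispersion = undershoot_dispersion,
            peak_undershoot_ratio = peak_undershoot_ratio,
            kernel_length = kernel_length)
  if (any(unlist(p) <= 0)) stop("all HRF parameters must be positive")
  if (kernel_length < undershoot_delay) {
    stop("kernel_length must cover the undershoot delay")
  }
  p
}

# causal convolution of x with kernel k (both at step dt), scaled by dt so the
# result approximates the continuous-time convolution integral
convolve_causal <- function(x, k, dt) {
  n <- length(x)
  y <- stats::convolve(c(x, rep(0, length(k))), rev(k), type = "open")
  y[seq_len(n)] * dt
}

#' Hemodynamically convolved burst-suppression regressor
#'
#' Convolves the binary BS pattern with the canonical HRF at the pattern's own
#' sampling rate (preserving sub-TR timing of suppression onsets), samples the
#' result at volume onsets `t = k * tr` (k = 0, 1, ...), drops the first
#' `n_drop` volumes, and mean-centers.
#'
#' @param pattern a [bs_pattern] covering at least `n_volumes * tr` seconds.
#' @param tr repetition time (s).
#' @param n_volumes total acquired volumes.
#' @param n_drop leading volumes discarded before analysis (default 10).
#' @param hrf HRF parameters, see [hrf_params()].
#' @return List of class `volume_regressor`: `values` (length
#'   `n_volumes - n_drop`), `tr`, `n_dropped_leading_volumes`.
#' @export
build_bs_regressor <- function(pattern, tr, n_volumes, n_drop = 10,
                               hrf = hrf_params()) {
  stopifnot(inherits(pattern, "bs_pattern"))
  if (tr <= 0) stop("tr must be positive")
  if (n_drop < 0 || n_drop >= n_volumes) stop("invalid n_drop")
  if (pattern$duration < (n_volumes - 1) * tr) {
    stop("pattern does not cover the acquisition: need ",
         (n_volumes - 1) * tr, " s, have ", pattern$duration, " s")
  }
  fs <- pattern$sample_rate
  kern <- canonical_hrf(hrf, dt = 1 / fs)
  conv <- convolve_causal(pattern$values, kern, dt = 1 / fs)
  idx <- round((0:(n_volumes - 1)) * tr * fs) + 1
  v <- conv[idx]
  if (n_drop > 0) v <- v[-seq_len(n_drop)]
  structure(
    list(values = v - mean(v), tr = tr, n_dropped_leading_volumes = n_drop),
    class = "volume_regressor"
  )
}

# volume-grid sampling of the convolved pattern without dropping/centering;
# used by the generator as the injected coupling time course
convolved_pattern_at_volumes <- function(pattern, tr, n_volumes,
                                         hrf = hrf_params()) {
  fs <- pattern$sample_rate
  kern <- canonical_hrf(hrf, dt = 1 / fs)
  conv <- convolve_causal(pattern$values, kern, dt = 1 / fs)
  idx <- round((0:(n_volumes - 1)) * tr * fs) + 1
  if (max(idx) > length(conv)) stop("pattern does not cover the acquisition")
  conv[idx]
}
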
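#' Mean absolute value of a segment
#'
#' The tremor-intensity measure: the arithmetic mean of the absolute
#' sample values of a preprocessed acceleration segment.  Analyses use it
#' on the natural-log scale (`ln_mav()`), since raw intensities are
#' heavily right-skewed across patients.
#'
#' @param segment A `tremor_segment` or a numeric vector.
#' @return MAV in the units of the input (m/s^2 for accelerations).
#' @export
mav <- function(segment) {
  x <- if (inherits(segment, "tremor_segment")) segment$samples else segment
  if (!length(x)) stop("empty segment")
  mean(abs(x))
}

#' @rdname mav
#' @export
ln_mav <- function(segment) {
  m <- mav(segment)
  if (m <= 0) return(NA_real_)  # flagged missing, never -Inf
  log(m)
}

new_spectrum <- function(kind, frequencies, values) {
  structure(list(kind = kind,
                 frequencies = frequencies,
                 values = values,
                 resolution = frequencies[2] - frequencies[1]),
            class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate:%s> %d bins, 0-%.1f Hz, resolution %.4f Hz\n",
              x$kind, length(x$frequencies), max(x$frequencies), x$resolution))
  invisible(x)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Welch averaged-periodogram power spectral density
#'
#' Hann-windowed, overlapping, mean-removed blocks, zero-padded so the
#' frequency grid is finer than 0.1 Hz.  One-sided density scaling: the
#' integral of the PSD over frequency equals the windowed signal variance
#' (Parseval contract).
#'
#' @param segment A `tremor_segment` or numeric vector.
#' @param sampling_rate Required when `segment` is a bare vector.
#' @param window_length_s Block length in seconds (default 10); capped at
#'   the segment length.
#' @param overlap_fraction Block overlap (default 0.5).
#' @param nfft FFT length; defaults to the next power of two at least
#'   `20 * sampling_rate` samples long (grid step <= 0.05 Hz).
#' @return A `spectrum_estimate` of kind `"PSD"`.
#' @export
psd_welch <- function(segment, sampling_rate = NULL,
                      window_length_s = 10, overlap_fraction = 0.5,
                      nfft = NULL) {
  if (inherits(segment, "tremor_segment")) {
    x <- segment$samples
    fs <- segment$sampling_rate
  } else {
    x <- segment
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for a bare vector")
  }
  n <- length(x)
  nwin <- as.integer(round(window_length_s * fs))
  if (nwin > n) stop("Welch window longer than the segment")
  if (nwin < 2) stop("Welch window too short")
  step <- max(1L, as.integer(round(nwin * (1 - overlap_fraction))))
  if (is.null(nfft)) nfft <- next_pow2(max(nwin, 20 * fs))
  w <- hann_window(nwin)
  starts <- seq(1L, n - nwin + 1L, by = step)
  nf <- nfft %/% 2 + 1L
  acc <- numeric(nf)
  scale <- 1 / (fs * sum(w^2))
  for (s in starts) {
    blk <- x[s:(s + nwin - 1L)]
    blk <- (blk - mean(blk)) * w
    X <- stats::fft(c(blk, numeric(nfft - nwin)))
    p <- (Mod(X[1:nf])^2) * scale
    # one-sided: double everything except DC and Nyquist
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  freq <- (0:(nf - 1L)) * fs / nfft
  new_spectrum("PSD", freq, acc / length(starts))
}

#' Biased third-order cumulant estimate
#'
#' `C(k, l) = (1/M) * sum_n x(n) x(n+k) x(n+l)` over the valid range of
#' `n`, for all lags `|k|, |l| <= max_lag`.  The biased (1/M)
#' normalisation tapers the estimate towards large lags, which combines
#' well with the Hann lag window used by [bispectrum_diag()].  The
#' estimator satisfies `C(k, l) == C(l, k)` exactly.
#'
#' @param segment A `tremor_segment` or numeric vector (assumed
#'   zero-mean; preprocessed segments are).
#' @param max_lag Maximum lag L in samples; must be < segment length.
#' @return A `(2L+1) x (2L+1)` matrix, row/column index running
#'   over lags `-L..L`.
#' @export
third_order_cumulant <- function(segment, max_lag) {
  x <- if (inherits(segment, "tremor_segment")) segment$samples else segment
  if (max_lag >= length(x)) stop("max lag L must be smaller than the segment length")
  third_order_cumulant_cpp(as.numeric(x), as.integer(max_lag))
}

#' Diagonal slice of the bispectrum (indirect estimate)
#'
#' Estimates the bispectrum as the 2-D Fourier transform of the
#' Hann-lag-windowed third-order cumulant and returns the magnitude of
#' its diagonal slice `|B(f, f)|`.  Along the diagonal the 2-D transform
#' collapses to a 1-D transform of the anti-diagonal sums of the windowed
#' cumulant, which is what is computed (identical values, far cheaper).
#' Quadratic phase coupling between a fundamental and its harmonics makes
#' the diagonal peak at the fundamental; a Gaussian signal leaves the
#' whole slice near zero.
#'
#' @inheritParams psd_welch
#' @param max_lag Cumulant maximum lag in samples (default 100, i.e. 1 s
#'   at 100 Hz).
#' @param nfft Transform length (default: next power of two giving a grid
#'   step <= 0.05 Hz).
#' @return A `spectrum_estimate` of kind `"BISPECTRUM_DIAG"`.
#' @export
bispectrum_diag <- function(segment, sampling_rate = NULL, max_lag = 100,
                            nfft = NULL) {
  if (inherits(segment, "tremor_segment")) {
    x <- segment$samples
    fs <- segment$sampling_rate
  } else {
    x <- segment
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for a bare vector")
  }
  x <- x - mean(x)
  L <- as.integer(max_lag)
  if (is.null(nfft)) nfft <- next_pow2(max(4 * L + 1, 20 * fs))
  if (nfft < 4 * L + 1) stop("nfft too small for the requested max_lag")
  C <- third_order_cumulant(x, L)
  w <- 0.5 * (1 + cos(pi * (-L:L) / (L + 1)))
  Cw <- C * outer(w, w)
  # anti-diagonal sums: d(m) = sum_{k+l=m} Cw(k, l), m = -2L..2L
  m_idx <- as.vector(outer(-L:L, -L:L, "+"))
  d <- as.vector(rowsum(as.vector(Cw), m_idx))  # ordered -2L..2L
  v <- numeric(nfft)
  mm <- -(2 * L):(2 * L)
  v[(mm %% nfft) + 1L] <- d
  B <- stats::fft(v)
  nf <- nfft %/% 2 + 1L
  freq <- (0:(nf - 1L)) * fs / nfft
  out <- new_spectrum("BISPECTRUM_DIAG", freq, Mod(B[1:nf]))
  # complex slice kept alongside: averaging it across segments (before
  # taking the magnitude) is what distinguishes quadratic phase coupling
  # (bispectrum phase locked at zero) from independent tones (uniform
  # phase, cancels in the mean)
  out$complex_values <- B[1:nf]
  out
}

#' Full 2-D bispectrum magnitude on a coarse grid
#'
#' Direct 2-D transform of the Hann-lag-windowed cumulant; mainly for
#' inspection and for verifying the `B(f1, f2) = B(f2, f1)` symmetry and
#' the equivalence with the fast diagonal slice.  Use a modest `nfft`.
#'
#' @inheritParams bispectrum_diag
#' @return List with `frequencies` (length-`nfft/2+1` axis) and the
#'   magnitude `matrix` over that grid.
#' @export
bispectrum_2d <- function(segment, sampling_rate = NULL, max_lag = 32,
                          nfft = 256) {
  if (inherits(segment, "tremor_segment")) {
    x <- segment$samples
    fs <- segment$sampling_rate
  } else {
    x <- segment
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for a bare vector")
  }
  x <- x - mean(x)
  L <- as.integer(max_lag)
  if (nfft < 2 * L + 1) stop("nfft too small for the requested max_lag")
  C <- third_order_cumulant(x, L)
  w <- 0.5 * (1 + cos(pi * (-L:L) / (L + 1)))
  Cw <- C * outer(w, w)
  V <- matrix(0, nfft, nfft)
  kk <- ((-L:L) %% nfft) + 1L
  V[kk, kk] <- Cw
  B <- stats::fft(V)
  nf <- nfft %/% 2 + 1L
  list(frequencies = (0:(nf - 1L)) * fs / nfft,
       magnitude = Mod(B[1:nf, 1:nf]))
}

#' Dominant frequency of a spectrum estimate
#'
#' The frequency of the maximal spectrum value within a band; ties are
#' broken towards the lowest qualifying frequency.
#'
#' @param spectrum A `spectrum_estimate`.
#' @param band Frequency band in Hz (default the tremor band, 1-20 Hz).
#' @return Frequency in Hz, or `NA_real_` if the spectrum is identically
#'   zero (or missing) on the band.
#' @export
dominant_frequency <- function(spectrum, band = c(1, 20)) {
  stopifnot(inherits(spectrum, "spectrum_estimate"))
  sel <- spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2]
  if (!any(sel)) stop("spectrum does not cover the requested band")
  f <- spectrum$frequencies[sel]
  v <- spectrum$values[sel]
  if (all(!is.finite(v)) || all(v == 0)) return(NA_real_)
  f[which.max(v)]  # which.max takes the first maximum: low-frequency tie-break
}

#' Extract the per-segment feature table
#'
#' Applies the intensity and frequency descriptors to every preprocessed
#' segment: MAV and ln(MAV); dominant frequency of the Welch PSD; and
#' dominant frequency of the bispectrum diagonal slice.  One row per
#' segment, with full provenance; rows with flagged missing values are
#' carried, not dropped.
#'
#' @param segments List of `tremor_segment` objects.
#' @param welch_window_s,welch_overlap Welch parameters (see
#'   [psd_welch()]); the window is capped at the segment length.
#' @param max_lag Cumulant maximum lag (see [bispectrum_diag()]); capped
#'   at segment length - 1.
#' @param band Dominant-frequency search band in Hz.
#' @return A `data.frame` with columns `subject_id, group, stage,
#'   posture, segment_index, segment_length_s, mav, ln_mav, domfreq_psd,
#'   domfreq_bispec`.
#' @export
extract_features <- function(segments, welch_window_s = 10,
                             welch_overlap = 0.5, max_lag = 100,
                             band = c(1, 20)) {
  rows <- lapply(segments, function(seg) {
    p <- seg$provenance
    m <- mav(seg)
    win <- min(welch_window_s, seg$length_s)
    psd <- psd_welch(seg, window_length_s = win,
                     overlap_fraction = welch_overlap)
    L <- min(max_lag, length(seg$samples) - 1L)
    bis <- bispectrum_diag(seg, max_lag = L)
    data.frame(subject_id = p$subject_id %||% NA_character_,
               group = p$group %||% NA_character_,
               stage = p$stage %||% NA_character_,
               posture = p$posture %||% NA_character_,
               segment_index = p$segment_index %||% NA_integer_,
               segment_length_s = seg$length_s,
               mav = m,
               ln_mav = if (m > 0) log(m) else NA_real_,
               domfreq_psd = dominant_frequency(psd, band),
               domfreq_bispec = dominant_frequency(bis, band),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a feature table as CSV
#'
#' @param feature_table A feature table from [extract_features()].
#' @param path File path.
#' @return `read_feature_table` returns the table; `write_feature_table`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(feature_table, path) {
  utils::write.csv(feature_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
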
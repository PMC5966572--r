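#' @useDynLib tremordiff, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Expand a polynomial from its (possibly complex) roots.
# Returns coefficients in decreasing power order, leading coefficient 1.
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0 + 0i) - c(0 + 0i, p * ri)
  p
}

#' Design a digital Butterworth bandpass filter
#'
#' Designs an order-`order` Butterworth bandpass filter (so `2 * order`
#' poles in the digital filter) by the standard analog-prototype /
#' bandpass-transform / bilinear-transform route with frequency
#' pre-warping, matching the band edges exactly.
#'
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Prototype lowpass order (default 2).
#' @return A list with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @export
butter_bandpass <- function(low, high, fs, order = 2) {
  stopifnot(low > 0, high > low, high < fs / 2, order >= 1)
  # pre-warped analog edge frequencies (rad/s)
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # lowpass -> bandpass: each pole splits in two, zeros at s = 0
  ps <- p_lp * bw / 2
  p_bp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  k_bp <- bw^order
  # bilinear transform
  fs2 <- 2 * fs
  pd <- (fs2 + p_bp) / (fs2 - p_bp)
  zd <- c((fs2 + z_bp) / (fs2 - z_bp), rep(-1 + 0i, length(p_bp) - length(z_bp)))
  kd <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

#' Design a second-order IIR notch filter
#'
#' Classic biquad notch with a true zero on the unit circle at the notch
#' frequency, so the rejection at the exact centre frequency is complete.
#'
#' @param f0 Notch centre frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param q Quality factor; the -3 dB bandwidth is `f0 / q`.
#' @return A list with `b` and `a` coefficients.
#' @export
iir_notch <- function(f0, fs, q = 35) {
  stopifnot(f0 > 0, f0 < fs / 2, q > 0)
  w0 <- 2 * pi * f0 / fs
  bw <- w0 / q
  b0 <- 1 / (1 + tan(bw / 2))
  list(b = b0 * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * b0 * cos(w0), 2 * b0 - 1))
}

#' Complex frequency response of a digital filter
#'
#' @param b,a Filter coefficients.
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex response values; take `Mod()` for the amplitude gain.
#' @export
filter_response <- function(b, a, f, fs) {
  zb <- exp(-1i * 2 * pi * outer(f, seq_along(b) - 1) / fs)
  za <- exp(-1i * 2 * pi * outer(f, seq_along(a) - 1) / fs)
  as.vector((zb %*% b) / (za %*% a))
}

# Steady-state initial conditions for iir_filter_cpp, scaled for unit
# step input (same construction as scipy.signal.lfilter_zi).
lfilter_zi <- function(b, a) {
  n <- length(a) - 1
  if (n == 0) return(numeric(0))
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(comp), B)
}

# Single-pass IIR filtering with steady-state initial conditions scaled
# to the first sample (suppresses the start-up transient for signals
# that begin near steady state).
iir_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]
  a <- a / a[1]
  if (is.null(zi)) zi <- lfilter_zi(b, a) * x[1]
  y <- iir_filter_cpp(b, a, x, zi)
  attr(y, "zf") <- NULL
  y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forwards and then backwards so the net phase
#' response is zero and the amplitude response is the squared single-pass
#' magnitude.  The signal is extended at both ends by odd reflection
#' before filtering and trimmed afterwards, and each pass starts from
#' matched steady-state initial conditions, so edge transients and DC
#' start-up artefacts are suppressed.
#'
#' @param b,a Filter coefficients.
#' @param x Input signal.
#' @param padlen Number of reflected samples at each end (default
#'   `3 * length(b)`, capped at `length(x) - 1`).
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = 3 * length(b)) {
  filtfilt_cascade(list(list(b = b, a = a)), x, padlen)
}

#' @rdname filtfilt
#' @param sections List of `list(b, a)` filter sections, applied as a
#'   cascade inside a single padded forward-backward pass (equivalent to
#'   chaining [filtfilt()] over the sections, without re-padding).
#' @export
filtfilt_cascade <- function(sections, x, padlen = NULL) {
  n <- length(x)
  if (n < 2) stop("signal too short to filter")
  if (is.null(padlen)) padlen <- 3 * max(vapply(sections, function(s) length(s$b), 0L))
  padlen <- min(padlen, n - 1)
  sections <- lapply(sections, function(s) {
    b <- s$b / s$a[1]
    a <- s$a / s$a[1]
    list(b = b, a = a, zi = lfilter_zi(b, a))
  })
  y <- if (padlen > 0) {
    c(2 * x[1] - x[(padlen + 1):2],
      x,
      2 * x[n] - x[(n - 1):(n - padlen)])
  } else {
    x
  }
  for (s in sections) y <- iir_filter_cpp(s$b, s$a, y, s$zi * y[1])
  y <- rev(y)
  for (s in sections) y <- iir_filter_cpp(s$b, s$a, y, s$zi * y[1])
  y <- rev(y)
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  as.numeric(y)
}
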
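## Zero-phase Butterworth filtering.
##
## Filtering must not shift signals in time: the ISC machinery depends on
## exact temporal alignment across subjects, so all filtering is
## forward-backward ("filtfilt") with odd-reflection edge padding.  The
## design is a classic bilinear-transform Butterworth; only the cutoffs are
## scientifically meaningful, the realization is an implementation choice.

## Polynomial with given (complex) roots, leading coefficient 1,
## coefficients in descending powers.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - ri * c(0, p)
  p
}

polyval <- function(coef, z) {
  acc <- 0 * z
  for (c_i in coef) acc <- acc * z + c_i
  acc
}

#' Design a digital Butterworth filter
#'
#' Bilinear-transform Butterworth design (low- or high-pass).  Returns
#' transfer-function coefficients normalized so the passband reference
#' gain (DC for low-pass, Nyquist for high-pass) is exactly 1.
#'
#' @param order Filter order (poles).
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numerator `b` and denominator `a` (descending powers,
#'   `a[1] == 1`).
#' @export
butter_design <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, cutoff > 0, cutoff < fs / 2)
  Wc <- cutoff / (fs / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP unit circle
  W <- 4 * tan(pi * Wc / 2)                                  # prewarped (fs = 2)
  if (type == "low") {
    poles_a <- W * proto
    zeros_d <- rep(-1 + 0i, order)
    ref_z <- 1 + 0i
  } else {
    poles_a <- W / proto
    zeros_d <- rep(1 + 0i, order)
    ref_z <- -1 + 0i
  }
  poles_d <- (4 + poles_a) / (4 - poles_a)                   # bilinear map
  b <- poly_from_roots(zeros_d)
  a <- poly_from_roots(poles_d)
  a <- Re(a) / Re(a)[1]
  g <- polyval(a, ref_z) / polyval(b, ref_z)
  list(b = Re(b * g), a = a)
}

## Direct-form IIR filter (single pass, causal).
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xx <- c(rep(0, nb - 1), x)
  v <- stats::filter(xx, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[(nb - 1) + seq_along(x)]
  if (length(a) > 1)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  v
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward with odd-reflection padding so
#' the net result has zero phase and squared magnitude response.
#'
#' @param b,a Transfer-function coefficients from [butter_design()].
#' @param x Numeric signal.
#' @param pad Reflection-padding length in samples; must comfortably cover
#'   the filter's step-response transient (default `3 * (order)`, which is
#'   enough only for cutoffs well inside the band -- [bandpass()] passes a
#'   cutoff-scaled value).
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_ba <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- 3 * (max(length(a), length(b)) - 1)
  pad <- min(pad, n - 1)
  xe <- if (pad > 0)
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  else x
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[pad + seq_len(n)]
}

#' Effective gain of a zero-phase filter at given frequencies
#'
#' The forward-backward application squares the magnitude response; this
#' returns that effective gain, used as the analytic oracle for the
#' filtering tests.
#'
#' @param b,a Coefficients as from [butter_design()].
#' @param f Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of gains.
#' @export
filter_gain <- function(b, a, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  Mod(polyval(b, z) / polyval(a, z))^2
}

## Zero-phase band-pass: 4th-order high-pass then 4th-order low-pass.
## Padding scales with the high-pass cutoff: the step-response transient
## of the 1 Hz section is a few hundred ms, so pad by ~3 cutoff periods.
bandpass_vector <- function(x, hp, lp, fs, order = 4L) {
  hpf <- butter_design(order, hp, fs, "high")
  lpf <- butter_design(order, lp, fs, "low")
  pad <- ceiling(3 * fs / hp)
  x <- x - mean(x)   # the high-pass removes DC anyway; doing it up front
                     # avoids a step transient at the padded edges
  filtfilt_ba(lpf$b, lpf$a, filtfilt_ba(hpf$b, hpf$a, x, pad), pad)
}
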
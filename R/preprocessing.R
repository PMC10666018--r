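#' Digital low-pass Butterworth coefficients
#'
#' Designs an order-`order` low-pass Butterworth filter by bilinear transform
#' of the analog prototype with cutoff prewarping, so the -3 dB point falls
#' exactly at `cutoff`. Equivalent to the classical `butter()` design found in
#' signal-processing toolboxes.
#'
#' @param order Filter order (>= 1).
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param fs Sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
butter_coefficients <- function(order = 3, cutoff = 5, fs = 30) {
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, fs/2): got ", cutoff, " Hz at fs = ", fs, " Hz")
  warped <- tan(pi * cutoff / fs)          # prewarped analog cutoff (rad/sample scale)
  k <- seq_len(order)
  # analog Butterworth poles on the left half unit circle, scaled to cutoff
  p_a <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # bilinear transform z = (1 + s) / (1 - s)
  p_z <- (1 + p_a) / (1 - p_a)
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))   # 'order' zeros at z = -1
  # normalize to unit DC gain
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

# monic polynomial coefficients from roots, highest power first
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# complex frequency response of (b, a) at digital frequency f (Hz) / fs
iir_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  zp <- function(coef) vapply(z, function(zi)
    sum(coef * zi ^ (seq_along(coef) - 1)), complex(1))
  zp(b) / zp(a)
}

#' Analytic magnitude of the implemented Butterworth filter
#'
#' Exact steady-state amplitude ratio of the digital (bilinear-designed)
#' filter at frequency `f`. Because of bilinear frequency warping this equals
#' the textbook analog magnitude `1/sqrt(1 + (f/cutoff)^(2*order))` only
#' approximately in the passband and exactly at `f = cutoff` (where both give
#' `1/sqrt(2)`); near Nyquist the digital filter attenuates considerably more
#' than the analog formula suggests.
#'
#' @inheritParams butter_coefficients
#' @param f Frequency (Hz), vectorized.
#' @return Magnitude(s) in \[0, 1\].
#' @export
butter_gain <- function(f, order = 3, cutoff = 5, fs = 30) {
  1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * cutoff / fs))^(2 * order))
}

#' Low-pass Butterworth filtering of a series
#'
#' Causal single-pass IIR filtering by default, so the operation is realizable
#' online for real-time feedback; set `zero_phase = TRUE` for an offline
#' forward-backward pass (squared magnitude, no phase lag). Initial conditions
#' are set to the steady state for the first sample value, which removes the
#' start-up transient for signals that begin near rest.
#'
#' @param x Numeric vector (the series values).
#' @param fs Sampling rate in Hz.
#' @param order Filter order, default 3.
#' @param cutoff Cutoff frequency in Hz, default 5.
#' @param zero_phase Apply forward-backward filtering (default `FALSE`).
#' @return Filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 3, by = 1/30)
#' x <- sin(2 * pi * 1 * t) + 0.2 * sin(2 * pi * 12 * t)
#' y <- butterworth_lowpass(x, fs = 30)
butterworth_lowpass <- function(x, fs, order = 3, cutoff = 5,
                                zero_phase = FALSE) {
  if (!all(is.finite(x))) stop("series values must be finite")
  if (length(x) < 3 * order)
    stop("series too short to filter: need at least ", 3 * order, " samples")
  co <- butter_coefficients(order, cutoff, fs)
  run <- function(v) iir_filter(co$b, co$a, v)
  y <- run(x)
  if (zero_phase) y <- rev(run(rev(y)))
  y
}

# direct-form causal IIR with steady-state-at-x[1] initial conditions:
# filter x - x[1] from zero state (its steady state), then add back x[1]
# (valid because DC gain is 1)
iir_filter <- function(b, a, x) {
  x0 <- x[1]
  u <- x - x0
  v <- as.numeric(stats::filter(u, b, method = "convolution", sides = 1))
  # stats::filter leaves the first length(b)-1 outputs NA; the zero
  # prehistory of u makes them plain truncated convolutions
  for (i in seq_len(min(length(b) - 1, length(u))))
    v[i] <- sum(b[1:i] * u[i:1])
  y <- stats::filter(v, -a[-1], method = "recursive")
  as.numeric(y) + x0
}

#' Low-frequency group delay of the Butterworth filter
#'
#' The causal filter delays in-band (slow) components by a near-constant
#' group delay. Scoring compensates this known latency by shifting the
#' filtered series back in time, so repetition boundaries and template
#' alignment are not biased by the filter. Computed at DC:
#' `sum(k b_k)/sum(b_k) - sum(k a_k)/sum(a_k)` samples.
#'
#' @inheritParams butter_coefficients
#' @return Delay in seconds.
#' @export
butter_group_delay <- function(order = 3, cutoff = 5, fs = 30) {
  co <- butter_coefficients(order, cutoff, fs)
  k_b <- seq_along(co$b) - 1; k_a <- seq_along(co$a) - 1
  (sum(k_b * co$b) / sum(co$b) - sum(k_a * co$a) / sum(co$a)) / fs
}

# shift a uniformly sampled series earlier by tau seconds (x(t) -> x(t + tau)),
# linear interpolation, edge-held
compensate_delay <- function(x, fs, tau) {
  if (tau == 0 || length(x) < 2) return(x)
  t <- (seq_along(x) - 1) / fs
  stats::approx(t, x, xout = t + tau, rule = 2)$y
}

#' Resample a series onto a uniform grid
#'
#' Linear interpolation onto a uniform grid at `target_fs` spanning the
#' original time support `[0, (n-1)/fs]`.
#'
#' @param x Numeric vector sampled uniformly at `fs`.
#' @param fs Original sampling rate (Hz).
#' @param target_fs Target sampling rate (Hz, > 0).
#' @return Numeric vector on the new grid.
#' @export
resample_uniform <- function(x, fs, target_fs) {
  if (target_fs <= 0) stop("target_fs must be > 0")
  if (length(x) < 2) stop("need at least 2 samples to resample")
  t_old <- (seq_along(x) - 1) / fs
  t_new <- seq(0, t_old[length(t_old)], by = 1 / target_fs)
  stats::approx(t_old, x, xout = t_new)$y
}
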
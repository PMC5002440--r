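#' Band-pass filter specification
#'
#' Analysis defaults follow the reference recording pipeline: third-order
#' Butterworth, applied forward-backward (zero phase).  Standard bands:
#' analysis 100-14,250 Hz (the upper edge is 95% of the Nyquist frequency at
#' 30 kHz), detection 500-14,250 Hz, and an alternative 100-5,000 Hz band for
#' recordings with high-frequency noise.
#'
#' @param low_hz,high_hz band edges, Hz; 0 < low < high < rate/2 at use time.
#' @param order filter order (default 3).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 100, high_hz = 14250, order = 3) {
  if (!(low_hz > 0 && high_hz > low_hz)) stop("need 0 < low_hz < high_hz")
  if (order < 1) stop("order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 mode = "forward-backward"),
            class = "filter_spec")
}

#' Detection-stage band (500-14,250 Hz)
#' @export
detection_band <- function() filter_spec(500, 14250, 3)

#' Alternative low band (100-5,000 Hz) for noisy recordings
#' @export
alt_band <- function() filter_spec(100, 5000, 3)

#' Fraction of the Nyquist frequency
#'
#' @param rate_hz sampling rate, Hz.
#' @param fraction fraction in (0, 1].
#' @return frequency in Hz: `fraction * rate_hz / 2`.
#' @examples
#' nyquist_fraction(30000, 0.95)  # 14250
#' @export
nyquist_fraction <- function(rate_hz, fraction) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  fraction * rate_hz / 2
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Forward-backward application of a Butterworth band-pass designed with
#' [signal::butter()].  Each channel is filtered independently.  Edge
#' transients are controlled by odd-reflection padding before the forward
#' pass: the pad length is 3x the filter length or fifteen time constants of
#' the slowest pole, whichever is longer (a 100-Hz corner at 30 kHz rings for
#' hundreds of samples, and the zero-state startup transient must decay
#' within the pad).  The padding is discarded afterwards, so the output
#' has the same shape as the input, zero group delay and no DC component.
#' Intended for whole recordings, not short extracted windows.
#'
#' @param x numeric vector (single channel) or channels x time matrix.
#' @param spec a [filter_spec()].
#' @param rate_hz sampling rate, Hz.
#' @return filtered trace, same shape as `x`.
#' @export
bandpass_filtfilt <- function(x, spec = filter_spec(), rate_hz = 30000) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- rate_hz / 2
  if (spec$high_hz >= nyq)
    stop("high_hz (", spec$high_hz, ") must be below Nyquist (", nyq, " Hz)")
  if (spec$high_hz >= 0.95 * nyq)
    message("band edge at or above 95% of Nyquist; design checked for stability")
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  if (any(!is.finite(bf$b)) || any(!is.finite(bf$a)))
    stop("unstable filter design for this band/rate")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  # padding must outlast the slowest pole's transient (the low corner can sit
  # within 1% of the unit circle), not just the recursion length
  rmax <- max(Mod(polyroot(rev(bf$a))))
  pad <- max(3L * max(length(bf$b), length(bf$a)),
             ceiling(15 / max(1 - rmax, 1e-3)))
  if (ncol(m) <= pad)
    stop("trace too short to filter: ", ncol(m), " samples <= padding length ",
         pad, " (need more samples)")
  out <- t(apply(m, 1, .filtfilt_odd, b = bf$b, a = bf$a, pad = pad))
  if (vec) as.numeric(out) else out
}

# Forward-backward IIR pass with odd-reflection (antisymmetric) padding, the
# padding scheme that keeps a step at the boundary from ringing into the data.
.filtfilt_odd <- function(x, b, a, pad) {
  n <- length(x)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Noise standard deviation of a filtered trace
#'
#' Plain standard deviation by default (the convention the detection
#' thresholds are defined against).  The robust variant estimates sigma from
#' the median absolute deviation (Gaussian-consistent scaling), which resists
#' contamination by large spikes.
#'
#' @param x single-channel numeric trace (at least 100 samples).
#' @param robust use the MAD-based estimate instead of the plain SD.
#' @return estimated standard deviation, same units as `x`.
#' @export
estimate_noise_sd <- function(x, robust = FALSE) {
  if (length(x) < 100) stop("need >= 100 samples to estimate noise, got ", length(x))
  if (robust) stats::mad(x) else stats::sd(x)
}
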
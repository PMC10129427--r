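#' @include accessors.R
NULL

# Second-order IIR notch (RBJ biquad) with quality factor Q.
.notchCoef <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

.butterBand <- function(band, fs, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  list(b = bf$b, a = bf$a)
}

.filtfiltMat <- function(x, co) {
  t(apply(x, 1, function(ch) signal::filtfilt(co$b, co$a, ch)))
}

#' Notch and band-pass preprocessing
#'
#' Removes power-line interference with a second-order IIR notch (quality
#' factor 30) and restricts the recording to an analysis band with a
#' fourth-order Butterworth band-pass. Both filters are applied
#' forward-backward (zero phase), so no group delay is introduced --
#' essential for the phase-based connectivity metrics downstream.
#'
#' @param rec an [EEGRecording-class].
#' @param notchHz notch frequency in Hz (default 50, mains interference);
#'   `NULL` disables the notch.
#' @param band band-pass edges in Hz, default `c(0.5, 40)`.
#' @param notchQ notch quality factor.
#' @return A filtered [EEGRecording-class] of identical shape and rate.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 5000), 2), 250, c("C3", "C4"))
#' clean <- preprocessRecording(rec)
#' @export
preprocessRecording <- function(rec, notchHz = 50, band = c(0.5, 40),
                                notchQ = 30) {
  fs <- rec@rate
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] || band[2] >= fs / 2)
    stop("parameter error: need 0 < lo < hi < rate/2, got band [",
         paste(band, collapse = ", "), "] at rate ", fs)
  if (!is.null(notchHz) && notchHz >= fs / 2)
    stop("parameter error: notch frequency must be below the Nyquist frequency")
  # forward-backward order-4 band-pass: ~9 coefficients; require a margin of
  # three filter lengths so edge transients cannot dominate
  minLen <- 3L * (2L * 4L + 1L) * 2L
  if (ncol(rec@samples) < minLen)
    stop("too-short error: recording has ", ncol(rec@samples),
         " samples; at least ", minLen, " are required for stable filtering")
  x <- rec@samples
  if (!is.null(notchHz)) x <- .filtfiltMat(x, .notchCoef(notchHz, fs, notchQ))
  x <- .filtfiltMat(x, .butterBand(band, fs))
  EEGRecording(x, rate = fs, labels = rec@labels,
               meta = c(rec@meta, list(preprocessed = list(
                 notch_hz = if (is.null(notchHz)) NA_real_ else notchHz,
                 band = band))))
}

#' Zero-phase band-pass filter of a recording
#'
#' Fourth-order Butterworth applied forward-backward on each channel of the
#' continuous recording. Used to isolate a frequency band before computing
#' band-limited connectivity.
#'
#' @inheritParams preprocessRecording
#' @return A filtered [EEGRecording-class].
#' @export
bandpassFilter <- function(rec, band) {
  fs <- rec@rate
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] || band[2] >= fs / 2)
    stop("parameter error: band edges must satisfy 0 < lo < hi < rate/2")
  EEGRecording(.filtfiltMat(rec@samples, .butterBand(band, fs)),
               rate = fs, labels = rec@labels, meta = rec@meta)
}

# Analytic-signal instantaneous phase via the frequency-domain Hilbert
# transform of a band-limited real trace.
.instantPhase <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  Arg(fft(fft(x) * h, inverse = TRUE) / n)
}

.instantPhaseMat <- function(x) t(apply(x, 1, .instantPhase))
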
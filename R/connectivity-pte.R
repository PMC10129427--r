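#' @include accessors.R preprocess.R epochs.R connectivity-pearson.R
NULL

#' Phase-transfer-entropy estimator parameters
#'
#' Defaults: the prediction delay is half an average oscillation cycle of
#' the band, `round(rate / mean(band) / 2)` samples (at least 1); the
#' phase-histogram bin count is `ceiling(sqrt(n))` capped at 16 bins.
#' The cap keeps the three-dimensional phase histogram well populated --
#' with finer binning the plug-in entropy estimates overfit and the
#' resulting occupancy bias can dominate true phase coupling.
#'
#' @param band analysis band `c(lo, hi)` in Hz.
#' @param rate sampling rate in Hz.
#' @param nSamples samples per analysis segment (drives the bin default).
#' @param delay prediction lag in samples; `NULL` for the default.
#' @param bins histogram bins; `NULL` for the default.
#' @return A [PTEParams-class].
#' @export
pteParams <- function(band, rate, nSamples, delay = NULL, bins = NULL) {
  if (is.null(delay)) delay <- max(1L, as.integer(round(rate / mean(band) / 2)))
  if (is.null(bins)) bins <- min(16L, as.integer(ceiling(sqrt(nSamples))))
  new("PTEParams", delay = as.integer(delay), bins = as.integer(bins),
      band = as.numeric(band))
}

.binPhases <- function(ph, bins) {
  b <- matrix(pmin(bins, floor((ph + pi) / (2 * pi) * bins) + 1L), nrow(ph))
  storage.mode(b) <- "integer"
  b
}

.checkPhaseDegenerate <- function(x, labels) {
  amp <- apply(x, 1, function(ch) max(ch) - min(ch))
  if (any(amp == 0))
    stop("degenerate-channel error: constant signal in channel ",
         paste(labels[amp == 0], collapse = ", "))
}

#' Phase transfer entropy connectivity
#'
#' Directed phase-information flow per channel pair: the band-limited
#' signal's instantaneous phase (analytic signal of the zero-phase filtered
#' trace) is binned, and PTE(x -> y) = H(Yp, Xp) + H(Yf, Yp) - H(Yp) -
#' H(Yf, Yp, Xp), where Yf is the target phase `delay` samples ahead.
#' Entropies are plug-in estimates with Miller-Madow bias correction by
#' default. The diagonal is zero by convention, and negative values
#' (possible residual estimator noise) are clipped to zero, counting the
#' clips in `params(...)$n_clipped`.
#'
#' For the [EEGRecording-class] method, filtering and phase extraction run
#' on the continuous recording and the entropy accumulates over the
#' supplied artifact-free `runs` (default: the whole recording as one
#' segment), combined by a length-weighted average. The [EpochSet-class]
#' method filters and scores each epoch independently; prefer the recording
#' method for narrow low-frequency bands, where 2-s epochs are shorter than
#' the filter transients and the short-segment histogram bias is large.
#'
#' @param x an [EEGRecording-class] or [EpochSet-class].
#' @param band analysis band `c(lo, hi)` in Hz.
#' @param params a [PTEParams-class]; `NULL` for defaults.
#' @param bandName band label stored in the result.
#' @param runs optional data.frame (`start`, `length`, in samples) of
#'   artifact-free segments for the recording method.
#' @param mmCorrect apply the Miller-Madow entropy correction.
#' @return A directed [ConnMatrix-class] (metric "pte").
#' @examples
#' rec <- simulatePhaseCoupledPair(rate = 250, durationS = 10, kappa = 1,
#'                                 seed = 1)
#' pteConnectivity(rec, band = c(8, 13))
#' @export
setGeneric("pteConnectivity",
  function(x, band, params = NULL, bandName = NULL, runs = NULL,
           mmCorrect = TRUE)
    standardGeneric("pteConnectivity"))

#' @rdname pteConnectivity
#' @export
setMethod("pteConnectivity", "EEGRecording",
  function(x, band, params = NULL, bandName = NULL, runs = NULL,
           mmCorrect = TRUE) {
    if (band[2] >= x@rate / 2)
      stop("parameter error: band must lie below the Nyquist frequency")
    if (is.null(runs))
      runs <- data.frame(start = 1L, length = ncol(x@samples))
    if (is.null(params))
      params <- pteParams(band, x@rate, max(runs$length))
    if (params@delay >= min(runs$length))
      stop("parameter error: delay (", params@delay,
           " samples) must be shorter than every analysis segment")
    .checkPhaseDegenerate(x@samples, x@labels)
    filt <- bandpassFilter(x, band)
    ph <- .instantPhaseMat(filt@samples)
    .pteFromPhases(ph, x@labels, params, runs, mmCorrect,
                   bandName %||% paste0(band[1], "-", band[2]))
  })

#' @rdname pteConnectivity
#' @export
setMethod("pteConnectivity", "EpochSet",
  function(x, band, params = NULL, bandName = NULL, runs = NULL,
           mmCorrect = TRUE) {
    if (band[2] >= x@rate / 2)
      stop("parameter error: band must lie below the Nyquist frequency")
    len <- ncol(x@epochs[[1]])
    if (is.null(params)) params <- pteParams(band, x@rate, len)
    if (params@delay >= len)
      stop("parameter error: delay (", params@delay,
           " samples) must be shorter than the epoch length")
    co <- .butterBand(band, x@rate)
    phs <- lapply(x@epochs, function(ep) {
      .checkPhaseDegenerate(ep, x@labels)
      .instantPhaseMat(.filtfiltMat(ep, co))
    })
    nEp <- length(phs)
    ph <- do.call(cbind, phs)
    runs <- data.frame(start = (seq_len(nEp) - 1L) * len + 1L,
                       length = rep(len, nEp))
    .pteFromPhases(ph, x@labels, params, runs, mmCorrect,
                   bandName %||% paste0(band[1], "-", band[2]))
  })

.pteFromPhases <- function(ph, labels, params, runs, mmCorrect, bandName) {
  B <- .binPhases(ph, params@bins)
  v <- pte_matrix_core(B, as.integer(runs$start), as.integer(runs$length),
                       params@delay, params@bins, mmCorrect)
  nClip <- sum(v < 0 & row(v) != col(v))
  v[v < 0] <- 0
  diag(v) <- 0
  .connMatrix(v, "pte", bandName, TRUE, labels,
              list(delay = params@delay, bins = params@bins,
                   band = params@band, mm_correct = mmCorrect,
                   n_segments = nrow(runs), n_clipped = nClip))
}
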
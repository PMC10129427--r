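#' @include accessors.R preprocess.R epochs.R
NULL

.connMatrix <- function(values, metric, band, directed, labels, params = list()) {
  dimnames(values) <- list(labels, labels)
  new("ConnMatrix", values = values, metric = metric, band = band,
      directed = directed, params = params)
}

#' Band-limited Pearson correlation connectivity
#'
#' Pearson product-moment correlation between channel pairs, computed per
#' epoch and averaged over epochs. For the [EpochSet-class] method each
#' epoch is zero-phase band-pass filtered first (if a band is given); for
#' the [EEGRecording-class] method the continuous recording is filtered
#' once and then epoched, which avoids per-epoch filter transients for
#' narrow low-frequency bands.
#'
#' @param x an [EpochSet-class] or [EEGRecording-class].
#' @param band `c(lo, hi)` in Hz, or `NULL` for broadband (no extra filter).
#' @param bandName label stored in the result ("broadband" when `band` is
#'   `NULL`; otherwise defaults to "lo-hi").
#' @param epochLength epoching used by the recording method, in seconds.
#' @param mask optional rejection mask for the recording method (as from
#'   [keptMask()]); by default all epochs are used.
#' @return A symmetric [ConnMatrix-class] with unit diagonal.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 5000), 2), 250, c("C3", "C4"))
#' pearsonConnectivity(epochAndReject(rec, 2, 1e6), band = c(8, 13))
#' @export
setGeneric("pearsonConnectivity",
  function(x, band = NULL, bandName = NULL, epochLength = 2, mask = NULL)
    standardGeneric("pearsonConnectivity"))

#' @rdname pearsonConnectivity
#' @export
setMethod("pearsonConnectivity", "EpochSet",
  function(x, band = NULL, bandName = NULL, epochLength = 2, mask = NULL) {
    if (length(x@labels) < 2) stop("parameter error: need at least 2 channels")
    co <- if (!is.null(band)) {
      if (band[2] >= x@rate / 2)
        stop("parameter error: band must lie below the Nyquist frequency")
      .butterBand(band, x@rate)
    }
    acc <- matrix(0, length(x@labels), length(x@labels))
    for (ep in x@epochs) {
      m <- if (is.null(co)) ep else .filtfiltMat(ep, co)
      sds <- apply(m, 1, sd)
      if (any(sds == 0))
        stop("degenerate-channel error: zero variance in channel ",
             paste(x@labels[sds == 0], collapse = ", "))
      acc <- acc + cor(t(m))
    }
    v <- acc / length(x@epochs)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    .connMatrix(v, "pearson",
                bandName %||% if (is.null(band)) "broadband"
                  else paste0(band[1], "-", band[2]),
                FALSE, x@labels,
                list(band = band, n_epochs = length(x@epochs)))
  })

#' @rdname pearsonConnectivity
#' @export
setMethod("pearsonConnectivity", "EEGRecording",
  function(x, band = NULL, bandName = NULL, epochLength = 2, mask = NULL) {
    filtered <- if (is.null(band)) x else bandpassFilter(x, band)
    len <- as.integer(round(epochLength * x@rate))
    nEpoch <- ncol(x@samples) %/% len
    if (is.null(mask)) mask <- rep(TRUE, nEpoch)
    eps <- .epochsFromMask(filtered, mask, len)
    out <- pearsonConnectivity(eps, band = NULL,
                               bandName = bandName %||%
                                 if (is.null(band)) "broadband"
                                 else paste0(band[1], "-", band[2]))
    out@params$band <- band
    out
  })

`%||%` <- function(a, b) if (is.null(a)) b else a
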
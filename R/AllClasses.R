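#' @include eegconn-package.R
NULL

# ---------------------------------------------------------------------------
# Core data containers. All classes validate their invariants eagerly so that
# malformed objects fail at construction, not deep inside an estimator.
# ---------------------------------------------------------------------------

#' Multichannel EEG recording
#'
#' Container for a continuous multichannel recording: a channels-by-timepoints
#' sample matrix in microvolts, the sampling rate in Hz, ordered channel
#' labels (10-20 system), and free-form provenance metadata.
#'
#' @slot samples numeric matrix, channels x timepoints, in microvolts.
#' @slot rate sampling frequency in Hz.
#' @slot labels character vector of channel names, one per sample row.
#' @slot meta list of provenance fields (source file, subject id, group tag,
#'   flagged non-standard labels, ...).
#'
#' @seealso [EEGRecording()] for the user-facing constructor,
#'   [readRecording()] to read from disk.
#' @export
setClass("EEGRecording",
  representation(samples = "matrix", rate = "numeric", labels = "character",
                 meta = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive finite number")
    if (nrow(object@samples) != length(object@labels))
      msg <- c(msg, "number of labels must equal number of sample rows")
    if (anyDuplicated(object@labels))
      msg <- c(msg, sprintf("duplicate channel labels: %s",
        paste(unique(object@labels[duplicated(object@labels)]), collapse = ", ")))
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "all sample values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Scalp region and hemisphere assignment for 10-20 channels
#'
#' Maps channel names to the five scalp regions (frontal, central, temporal,
#' parietal, occipital) and to hemispheres. Hemisphere follows the 10-20
#' convention: odd digit = left, even digit = right, trailing "z" = midline.
#'
#' @slot assignment named character vector, channel name -> region.
#' @slot hemisphere named character vector, channel name -> one of
#'   "left", "right", "midline".
#'
#' @seealso [standardRegionMap()]
#' @export
setClass("RegionMap",
  representation(assignment = "character", hemisphere = "character"),
  validity = function(object) {
    msg <- NULL
    regions <- c("frontal", "central", "temporal", "parietal", "occipital")
    if (!all(object@assignment %in% regions))
      msg <- c(msg, "regions must be frontal/central/temporal/parietal/occipital")
    if (!all(object@hemisphere %in% c("left", "right", "midline")))
      msg <- c(msg, "hemisphere must be left/right/midline")
    if (!identical(sort(names(object@assignment)), sort(names(object@hemisphere))))
      msg <- c(msg, "assignment and hemisphere must cover the same channels")
    if (is.null(msg)) TRUE else msg
  })

#' Set of equal-length epochs cut from a recording
#'
#' @slot epochs list of channels-x-samples matrices, all of identical shape.
#' @slot rate sampling frequency in Hz.
#' @slot labels channel labels shared by all epochs.
#' @slot epochLength epoch duration in seconds.
#' @slot keptMask logical vector over the raw consecutive epochs; `TRUE`
#'   entries correspond (in order) to the retained matrices in `epochs`.
#'
#' @seealso [epochAndReject()]
#' @export
setClass("EpochSet",
  representation(epochs = "list", rate = "numeric", labels = "character",
                 epochLength = "numeric", keptMask = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@epochs)) {
      dims <- vapply(object@epochs, dim, integer(2))
      if (any(dims[1, ] != length(object@labels)) || length(unique(dims[2, ])) != 1L)
        msg <- c(msg, "all epochs must share channel count and length")
    }
    if (sum(object@keptMask) != length(object@epochs))
      msg <- c(msg, "keptMask must select exactly the retained epochs")
    if (is.null(msg)) TRUE else msg
  })

#' Welch power spectral density table
#'
#' @slot freqs frequency grid in Hz, strictly increasing, spanning
#'   0 .. rate/2.
#' @slot psd channels-x-frequencies matrix of power density (uV^2/Hz).
#' @slot params list of Welch settings (window seconds, overlap fraction,
#'   window shape, rate).
#'
#' @seealso [welchPsd()]
#' @export
setClass("SpectrumTable",
  representation(freqs = "numeric", psd = "matrix", params = "list"),
  validity = function(object) {
    msg <- NULL
    if (any(object@psd < 0)) msg <- c(msg, "psd must be non-negative")
    if (is.unsorted(object@freqs, strictly = TRUE))
      msg <- c(msg, "freqs must be strictly increasing")
    if (ncol(object@psd) != length(object@freqs))
      msg <- c(msg, "psd columns must match the frequency grid")
    if (is.null(msg)) TRUE else msg
  })

#' Band and region power summary of one recording
#'
#' Absolute band power per channel, regional power, band and region power
#' ratios (each summing to one over their respective sets), and DTABR, the
#' (delta + theta) / (alpha + beta) power ratio.
#'
#' @slot bandPower bands-x-channels matrix of absolute band power.
#' @slot regionPower named numeric, absolute power per region (region
#'   channels summed over the union of the four bands).
#' @slot bandRatio named numeric, share of each band in the four-band total.
#' @slot regionRatio named numeric, share of each region in the five-region
#'   total.
#' @slot dtabr numeric, (delta + theta) / (alpha + beta).
#' @slot meta list.
#'
#' @seealso [summarizePower()]
#' @export
setClass("PowerSummary",
  representation(bandPower = "matrix", regionPower = "numeric",
                 bandRatio = "numeric", regionRatio = "numeric",
                 dtabr = "numeric", meta = "list"),
  validity = function(object) {
    msg <- NULL
    if (abs(sum(object@bandRatio) - 1) > 1e-9)
      msg <- c(msg, "band ratios must sum to 1")
    if (abs(sum(object@regionRatio) - 1) > 1e-9)
      msg <- c(msg, "region ratios must sum to 1")
    if (object@dtabr < 0) msg <- c(msg, "dtabr must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Connectivity matrix for one metric and band
#'
#' Channel-by-channel connectivity values. Pearson matrices are symmetric
#' with unit diagonal and entries in \[-1, 1\]; Granger-causality and phase
#' transfer entropy matrices are directed with zero diagonal and entry
#' (i, j) quantifying influence i -> j. Failed pairs are `NA`, never zero.
#'
#' @slot values n x n numeric matrix with channel dimnames.
#' @slot metric one of "pearson", "granger", "pte", or "granger_binary".
#' @slot band band name or "broadband".
#' @slot directed logical.
#' @slot params list of estimator settings used.
#'
#' @export
setClass("ConnMatrix",
  representation(values = "matrix", metric = "character", band = "character",
                 directed = "logical", params = "list"),
  validity = function(object) {
    msg <- NULL
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    ok <- is.finite(v)
    if (object@metric == "pearson") {
      if (object@directed) msg <- c(msg, "pearson matrices are undirected")
      if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12, check.attributes = FALSE)))
        msg <- c(msg, "pearson matrix must be symmetric")
      if (any(abs(v[ok]) > 1 + 1e-12)) msg <- c(msg, "pearson entries must lie in [-1, 1]")
      if (any(abs(diag(v) - 1) > 1e-12, na.rm = TRUE))
        msg <- c(msg, "pearson diagonal must be 1")
    } else if (object@metric %in% c("granger", "pte", "granger_binary")) {
      if (!object@directed) msg <- c(msg, sprintf("%s matrices are directed", object@metric))
      if (any(v[ok] < 0)) msg <- c(msg, "directed metric entries must be >= 0")
      if (any(diag(v) != 0, na.rm = TRUE)) msg <- c(msg, "directed metric diagonal must be 0")
    } else msg <- c(msg, sprintf("unknown metric '%s'", object@metric))
    if (is.null(msg)) TRUE else msg
  })

#' Fitted bivariate vector autoregression
#'
#' @slot order selected lag order.
#' @slot coefficients list of `order` 2x2 lag matrices (row = target).
#' @slot intercept length-2 numeric.
#' @slot residCov 2x2 innovation covariance (maximum-likelihood).
#' @slot criterion named numeric, BIC per candidate order.
#' @slot stable logical, companion-matrix spectral radius < 1.
#' @slot channels the two channel labels (x, y).
#'
#' @seealso [fitVAR()]
#' @export
setClass("VARModel",
  representation(order = "integer", coefficients = "list", intercept = "numeric",
                 residCov = "matrix", criterion = "numeric", stable = "logical",
                 channels = "character"))

#' Parameters of the phase-transfer-entropy estimator
#'
#' @slot delay prediction lag in samples (>= 1).
#' @slot bins number of phase-histogram bins (>= 2).
#' @slot band numeric band edges in Hz.
#'
#' @seealso [pteParams()], [pteConnectivity()]
#' @export
setClass("PTEParams",
  representation(delay = "integer", bins = "integer", band = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@delay < 1L) msg <- c(msg, "delay must be >= 1")
    if (object@bins < 2L) msg <- c(msg, "bins must be >= 2")
    if (is.null(msg)) TRUE else msg
  })

#' Mann-Whitney U group-comparison result
#'
#' @slot u Mann-Whitney U statistic for the first group.
#' @slot z tie-corrected, continuity-corrected normal deviate (signed:
#'   negative when the first group ranks lower).
#' @slot p two-sided p value (exact enumeration or normal approximation,
#'   see `mode`).
#' @slot n1,n2 group sizes.
#' @slot mode "exact" or "normal".
#' @slot pooling value-pooling mode when derived from connectivity matrices
#'   ("per_edge_pooled", "per_subject_mean", or "none").
#' @slot degenerate `TRUE` when all values were identical across groups.
#'
#' @seealso [mannWhitney()]
#' @export
setClass("GroupTestResult",
  representation(u = "numeric", z = "numeric", p = "numeric",
                 n1 = "integer", n2 = "integer", mode = "character",
                 pooling = "character", degenerate = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@u < 0 || object@u > object@n1 * as.numeric(object@n2))
      msg <- c(msg, "U must lie in [0, n1*n2]")
    if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' ROC curve with AUC and Hanley-McNeil confidence interval
#'
#' @slot thresholds decision thresholds of the sweep (score >= threshold is
#'   called positive).
#' @slot tpr,fpr true- and false-positive rates along the sweep.
#' @slot auc trapezoidal area under the curve.
#' @slot ciLow,ciHigh 95% interval bounds (Hanley-McNeil standard error).
#' @slot n1,n2 positive and negative class sizes.
#'
#' @seealso [rocAuc()]
#' @export
setClass("ROCCurve",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 n1 = "integer", n2 = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
    if (object@ciLow > object@auc + 1e-12 || object@ciHigh < object@auc - 1e-12)
      msg <- c(msg, "CI must bracket the AUC")
    if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
      msg <- c(msg, "tpr and fpr must be nondecreasing along the sweep")
    if (is.null(msg)) TRUE else msg
  })

#' Specification of a synthetic multichannel recording
#'
#' Defines the generative model of one synthetic subject: band-structured
#' spectra per region, a directed lagged coupling graph (a structural VAR),
#' a shared band-limited alpha source producing undirected coupling, and
#' additive white noise. Stability of the implied VAR (companion spectral
#' radius < 1) is checked at construction.
#'
#' @slot labels channel labels.
#' @slot rate sampling rate in Hz.
#' @slot durationS recording duration in seconds.
#' @slot bandWeights regions-x-bands matrix of relative power weights.
#' @slot couplingGraph data.frame with columns source, target, lag (samples),
#'   strength.
#' @slot sharedAlphaGain gain of the common alpha-band source.
#' @slot noiseSd additive white-noise standard deviation (relative units).
#' @slot amplitudeUv target mean channel RMS in microvolts.
#' @slot seed random seed.
#' @slot profile profile name ("cg_like", "doc_like", or "custom").
#'
#' @seealso [makeProfile()], [simulateRecording()]
#' @export
setClass("SyntheticSpec",
  representation(labels = "character", rate = "numeric", durationS = "numeric",
                 bandWeights = "matrix", couplingGraph = "data.frame",
                 sharedAlphaGain = "numeric", noiseSd = "numeric",
                 amplitudeUv = "numeric", seed = "integer", profile = "character"),
  validity = function(object) {
    msg <- NULL
    if (any(object@bandWeights < 0)) msg <- c(msg, "band weights must be >= 0")
    g <- object@couplingGraph
    if (nrow(g)) {
      if (!all(c("source", "target", "lag", "strength") %in% names(g)))
        msg <- c(msg, "couplingGraph needs columns source, target, lag, strength")
      else {
        if (any(g$lag < 1)) msg <- c(msg, "coupling lags must be >= 1")
        if (!all(c(g$source, g$target) %in% object@labels))
          msg <- c(msg, "coupling endpoints must be channel labels")
        rho <- .companionRadius(g, object@labels)
        if (rho >= 1)
          msg <- c(msg, sprintf("unstable coupling graph (companion spectral radius %.3f >= 1)", rho))
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Ground truth accompanying a synthetic recording
#'
#' @slot trueEdges the directed coupling edges used to generate the data.
#' @slot bandDominance named character, dominant band per region.
#' @slot expectedDtabrOrder expected between-group DTABR ordering.
#'
#' @export
setClass("GroundTruth",
  representation(trueEdges = "data.frame", bandDominance = "character",
                 expectedDtabrOrder = "character"))
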
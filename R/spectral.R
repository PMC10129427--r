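#' @include accessors.R regions.R epochs.R
NULL

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Averaged modified periodogram of one channel over the supplied segments.
# Periodic Hann window, per-segment constant detrend, one-sided density
# scaling: the integral of the PSD over [0, fs/2] approximates the signal
# variance (Parseval).
.welchChannel <- function(segments, fs, nwin, step) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / nwin)
  U <- sum(w^2)
  nf <- nwin %/% 2 + 1L
  acc <- numeric(nf)
  count <- 0L
  for (seg in segments) {
    starts <- seq(1L, length(seg) - nwin + 1L, by = step)
    for (s in starts) {
      x <- seg[s:(s + nwin - 1L)]
      x <- x - mean(x)
      p <- Mod(fft(x * w)[1:nf])^2 / (fs * U)
      if (nwin %% 2 == 0) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
      else p[2:nf] <- 2 * p[2:nf]
      acc <- acc + p
      count <- count + 1L
    }
  }
  acc / count
}

#' Welch power spectral density
#'
#' Per-channel averaged modified periodogram (Hann window, constant
#' detrend per segment) with density normalization: the trapezoidal
#' integral of the PSD over the one-sided grid approximates the signal
#' variance. For an [EpochSet-class], windows are taken within each kept
#' epoch and averaged across all epochs.
#'
#' @param x an [EpochSet-class] or [EEGRecording-class].
#' @param windowS window length in seconds (default 2).
#' @param overlap window overlap fraction in `[0, 1)` (default 0.5).
#' @return A [SpectrumTable-class] with the frequency grid spanning
#'   0 .. rate/2.
#' @examples
#' rec <- EEGRecording(matrix(sin(2 * pi * 10 * (1:2560) / 256), 1), 256, "Cz")
#' sp <- welchPsd(rec)
#' @export
setGeneric("welchPsd", function(x, windowS = 2, overlap = 0.5)
  standardGeneric("welchPsd"))

#' @rdname welchPsd
#' @export
setMethod("welchPsd", "EpochSet", function(x, windowS = 2, overlap = 0.5) {
  .welchCore(x@epochs, x@rate, x@labels, windowS, overlap)
})

#' @rdname welchPsd
#' @export
setMethod("welchPsd", "EEGRecording", function(x, windowS = 2, overlap = 0.5) {
  .welchCore(list(x@samples), x@rate, x@labels, windowS, overlap)
})

.welchCore <- function(epochList, fs, labels, windowS, overlap) {
  if (overlap < 0 || overlap >= 1)
    stop("parameter error: overlap must lie in [0, 1)")
  nwin <- as.integer(round(windowS * fs))
  segLen <- min(vapply(epochList, ncol, integer(1)))
  if (nwin > segLen)
    stop("parameter error: Welch window (", nwin,
         " samples) longer than epoch (", segLen, " samples)")
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  psd <- t(vapply(seq_along(labels), function(ch) {
    .welchChannel(lapply(epochList, function(m) m[ch, ]), fs, nwin, step)
  }, numeric(nwin %/% 2 + 1L)))
  rownames(psd) <- labels
  new("SpectrumTable", freqs = seq(0, nwin %/% 2) / nwin * fs, psd = psd,
      params = list(window_s = windowS, overlap = overlap, window = "hann",
                    rate = fs))
}

#' Band, region and DTABR power summary
#'
#' Band power is the trapezoidal integral of the PSD over the closed band
#' interval on the frequency grid, summed over channels. Band ratios are
#' shares of the four-band total (the gap frequencies between bands are not
#' part of the denominator). Region power sums each region's channels over
#' the union of the four bands, and region ratios are shares of the
#' five-region total. DTABR is (delta + theta) / (alpha + beta).
#'
#' @param spec a [SpectrumTable-class].
#' @param bands named list of band edges, see [defaultBands()].
#' @param regions a [RegionMap-class], see [standardRegionMap()].
#' @return A [PowerSummary-class].
#' @export
summarizePower <- function(spec, bands = defaultBands(),
                           regions = standardRegionMap()) {
  .checkBands(bands)
  f <- spec@freqs
  labels <- rownames(spec@psd)
  if (max(vapply(bands, max, 0)) > max(f))
    stop("parameter error: band edges outside the frequency grid")
  bandPower <- t(vapply(bands, function(b) {
    ix <- which(f >= b[1] & f <= b[2])
    if (length(ix) < 2)
      stop("parameter error: band [", b[1], ", ", b[2],
           "] covers fewer than two grid frequencies")
    apply(spec@psd[, ix, drop = FALSE], 1, function(p) .trapz(f[ix], p))
  }, numeric(nrow(spec@psd))))
  colnames(bandPower) <- labels
  regionNames <- sort(unique(regions@assignment))
  channelTotal <- colSums(bandPower)   # four-band union, per channel
  regionPower <- vapply(regionNames, function(rg) {
    chans <- intersect(names(regions@assignment)[regions@assignment == rg], labels)
    if (!length(chans)) {
      expected <- names(regions@assignment)[regions@assignment == rg]
      stop("missing-channel error: region '", rg, "' has no channels in the ",
           "spectrum (expected any of: ", paste(expected, collapse = ", "), ")")
    }
    sum(channelTotal[chans])
  }, numeric(1))
  bandTotal <- rowSums(bandPower)
  if (sum(bandTotal) == 0) {
    bandRatio <- setNames(rep(0, length(bands)), names(bands))
    bandRatio[1] <- 1   # degenerate all-zero spectrum: put mass on first band
    regionRatio <- regionPower
    regionRatio[] <- 1 / length(regionPower)
    dt <- 0
  } else {
    bandRatio <- bandTotal / sum(bandTotal)
    regionRatio <- regionPower / sum(regionPower)
    ab <- bandTotal["alpha"] + bandTotal["beta"]
    dt <- if (ab == 0) Inf else
      unname((bandTotal["delta"] + bandTotal["theta"]) / ab)
    if (bandTotal["delta"] + bandTotal["theta"] == 0) dt <- 0
  }
  new("PowerSummary", bandPower = bandPower, regionPower = regionPower,
      bandRatio = bandRatio, regionRatio = regionRatio, dtabr = dt,
      meta = list(bands = bands))
}

#' Cohort-level power table
#'
#' Long-format per-group summary of band ratios, region ratios and DTABR.
#' By default each subject contributes its own ratios and the group value
#' is their mean; with `pooled = TRUE` absolute powers are summed across
#' subjects first and ratios (and DTABR) recomputed from the pooled totals.
#'
#' @param summaries list of [PowerSummary-class] objects.
#' @param groupLabels character vector, one group label per summary.
#' @param pooled pool absolute power across subjects before forming ratios.
#' @return data.frame with columns `group`, `quantity`, `value`.
#' @export
cohortPowerTable <- function(summaries, groupLabels, pooled = FALSE) {
  if (length(summaries) != length(groupLabels))
    stop("label error: one group label per summary is required")
  if (!length(summaries)) stop("label error: no summaries given")
  groups <- unique(groupLabels)
  rows <- list()
  for (g in groups) {
    ss <- summaries[groupLabels == g]
    if (pooled) {
      bp <- Reduce(`+`, lapply(ss, function(s) rowSums(s@bandPower)))
      rp <- Reduce(`+`, lapply(ss, function(s) s@regionPower))
      br <- bp / sum(bp)
      rr <- rp / sum(rp)
      dt <- (bp["delta"] + bp["theta"]) / (bp["alpha"] + bp["beta"])
    } else {
      br <- rowMeans(vapply(ss, function(s) s@bandRatio,
                            numeric(length(ss[[1]]@bandRatio))))
      rr <- rowMeans(vapply(ss, function(s) s@regionRatio,
                            numeric(length(ss[[1]]@regionRatio))))
      dt <- mean(vapply(ss, function(s) s@dtabr, numeric(1)))
    }
    rows[[g]] <- data.frame(
      group = g,
      quantity = c(paste0("band_ratio.", names(br)),
                   paste0("region_ratio.", names(rr)), "dtabr"),
      value = unname(c(br, rr, dt)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
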
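#' @include accessors.R regions.R preprocess.R
NULL

# Spectral radius of the companion matrix implied by a directed lagged
# coupling graph; < 1 guarantees a stable structural VAR.
.companionRadius <- function(graph, labels) {
  if (!nrow(graph)) return(0)
  n <- length(labels)
  L <- max(graph$lag)
  A <- lapply(seq_len(L), function(l) matrix(0, n, n))
  for (k in seq_len(nrow(graph))) {
    i <- match(graph$target[k], labels)
    j <- match(graph$source[k], labels)
    A[[graph$lag[k]]][i, j] <- A[[graph$lag[k]]][i, j] + graph$strength[k]
  }
  C <- matrix(0, n * L, n * L)
  for (l in seq_len(L)) C[1:n, ((l - 1) * n + 1):(l * n)] <- A[[l]]
  if (L > 1) C[(n + 1):(n * L), 1:(n * (L - 1))] <- diag(n * (L - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Construct a synthetic recording specification
#'
#' @param labels channel labels (default: the 19-channel 10-20 montage).
#' @param rate sampling rate in Hz.
#' @param durationS duration in seconds.
#' @param bandWeights regions-x-bands matrix of relative power weights
#'   (rownames = regions, colnames = band names).
#' @param couplingGraph data.frame of directed edges with columns `source`,
#'   `target`, `lag` (samples), `strength`.
#' @param sharedAlphaGain gain of the common alpha-band source shared by
#'   all channels (undirected coupling).
#' @param noiseSd additive white-noise SD relative to unit-variance band
#'   components.
#' @param amplitudeUv target mean channel RMS in microvolts.
#' @param seed random seed.
#' @param profile profile tag.
#' @return A [SyntheticSpec-class]; construction fails if the coupling
#'   graph implies an unstable VAR.
#' @export
syntheticSpec <- function(labels = standardChannels19(), rate = 250,
                          durationS = 120, bandWeights,
                          couplingGraph = data.frame(source = character(),
                            target = character(), lag = integer(),
                            strength = numeric()),
                          sharedAlphaGain = 0, noiseSd = 0.3,
                          amplitudeUv = 8, seed = 1, profile = "custom") {
  new("SyntheticSpec", labels = labels, rate = rate, durationS = durationS,
      bandWeights = bandWeights, couplingGraph = couplingGraph,
      sharedAlphaGain = sharedAlphaGain, noiseSd = noiseSd,
      amplitudeUv = amplitudeUv, seed = as.integer(seed), profile = profile)
}

.profileEdges <- function(name) {
  if (name == "cg_like") {
    g <- read.table(text = "
Cz Fz 6\nCz C3 4\nCz C4 4\nCz Pz 5
C3 C4 6\nC4 C3 8\nC3 F3 5\nC4 F4 5\nC3 T3 7\nC4 T4 7
Pz P3 4\nPz P4 4\nP3 P4 6\nP4 P3 8\nP3 O1 5\nP4 O2 5\nP3 T5 7\nP4 T6 7
F3 Fp1 5\nF4 Fp2 5\nF3 F4 9\nFz F3 4\nFz F4 4\nO1 O2 6",
      col.names = c("source", "target", "lag"))
    g$strength <- 0.45
  } else {
    g <- read.table(text = "F3 T3 6\nC3 T3 7\nF4 T4 6\nC4 T4 7\nP3 T5 8",
                    col.names = c("source", "target", "lag"))
    g$strength <- 0.2
  }
  g
}

#' Cohort profiles for synthetic recordings
#'
#' Two generative profiles mirroring the qualitative group contrasts of a
#' control cohort versus a cohort with prolonged disorders of
#' consciousness:
#'
#' * `cg_like` -- alpha-dominant spectra weighted toward frontal channels,
#'   a dense directed coupling graph (24 lagged edges, including
#'   cross-hemisphere pairs, with information flow centered on central and
#'   parietal channels), and a strong shared alpha source.
#' * `doc_like` -- delta-dominant spectra with the occipital share
#'   inflated and the frontal share suppressed, a sparse coupling graph
#'   (5 weak edges, all directed toward temporal channels, none crossing
#'   hemispheres), and a weak shared source.
#'
#' Both profiles use identical channel labels and sampling rate, so every
#' between-group difference downstream is attributable to the spectral and
#' coupling structure.
#'
#' @param name "cg_like" or "doc_like".
#' @param durationS recording duration in seconds (default 120).
#' @param seed random seed.
#' @return A [SyntheticSpec-class].
#' @examples
#' makeProfile("doc_like")
#' @export
makeProfile <- function(name = c("cg_like", "doc_like"), durationS = 120,
                        seed = 1) {
  name <- match.arg(name)
  bandNames <- names(defaultBands())
  regions <- c("frontal", "central", "temporal", "parietal", "occipital")
  if (name == "cg_like") {
    bandProfile <- c(delta = 0.21, theta = 0.11, alpha = 0.55, beta = 0.13)
    regionGain <- c(frontal = 1.8, central = 1, temporal = 1, parietal = 1,
                    occipital = 1)
    shared <- 0.8
  } else {
    bandProfile <- c(delta = 0.56, theta = 0.27, alpha = 0.15, beta = 0.02)
    regionGain <- c(frontal = 0.5, central = 1, temporal = 1, parietal = 1,
                    occipital = 6)
    shared <- 0.2
  }
  W <- outer(regionGain[regions], bandProfile[bandNames])
  dimnames(W) <- list(regions, bandNames)
  syntheticSpec(bandWeights = W, couplingGraph = .profileEdges(name),
                sharedAlphaGain = shared, durationS = durationS, seed = seed,
                profile = name)
}

#' Simulate a recording from a specification
#'
#' Each channel's innovation is a sum of band-limited unit-variance noise
#' components scaled by the square root of the channel's region/band
#' weight, plus a shared alpha-band source scaled by `sharedAlphaGain`,
#' plus white noise. The directed coupling graph then acts as a structural
#' VAR: at every time step each target channel additionally receives
#' `strength` times the lagged value of its source channel. The result is
#' rescaled so the mean channel RMS equals `amplitudeUv`. Deterministic
#' given the spec's seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param regions a [RegionMap-class] used to place channels in regions.
#' @return list with `recording` (an [EEGRecording-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' sim <- simulateRecording(makeProfile("cg_like", durationS = 10))
#' sim$recording
#' @export
simulateRecording <- function(spec, regions = standardRegionMap()) {
  set.seed(spec@seed)
  fs <- spec@rate
  N <- as.integer(round(spec@durationS * fs))
  labels <- spec@labels
  n <- length(labels)
  bands <- defaultBands()[colnames(spec@bandWeights)]
  filts <- lapply(bands, .butterBand, fs = fs)
  reg <- regionOf(regions, labels, strict = FALSE)
  # channels outside the weight table (or unmapped) use its first row
  reg[is.na(reg) | !(reg %in% rownames(spec@bandWeights))] <-
    rownames(spec@bandWeights)[1]
  innov <- matrix(0, n, N)
  sharedAlpha <- if ("alpha" %in% names(bands)) {
    s <- signal::filtfilt(filts$alpha$b, filts$alpha$a, rnorm(N))
    s / sd(s)
  }
  for (ci in seq_len(n)) {
    acc <- rnorm(N, 0, spec@noiseSd)
    for (b in names(bands)) {
      z <- signal::filtfilt(filts[[b]]$b, filts[[b]]$a, rnorm(N))
      acc <- acc + sqrt(spec@bandWeights[reg[ci], b]) * (z / sd(z))
    }
    if (!is.null(sharedAlpha))
      acc <- acc + spec@sharedAlphaGain *
        sqrt(spec@bandWeights[reg[ci], "alpha"]) * sharedAlpha
    innov[ci, ] <- acc
  }
  X <- innov
  g <- spec@couplingGraph
  if (nrow(g)) {
    src <- match(g$source, labels); tgt <- match(g$target, labels)
    lag <- as.integer(g$lag); s <- g$strength
    for (t in (max(lag) + 1L):N) {
      for (e in seq_along(src))
        X[tgt[e], t] <- X[tgt[e], t] + s[e] * X[src[e], t - lag[e]]
    }
  }
  X <- X * (spec@amplitudeUv / mean(apply(X, 1, sd)))
  rec <- EEGRecording(X, rate = fs, labels = labels,
    meta = list(profile = spec@profile, seed = spec@seed, synthetic = TRUE))
  dominance <- apply(spec@bandWeights, 1, function(w)
    colnames(spec@bandWeights)[which.max(w)])
  truth <- new("GroundTruth", trueEdges = g, bandDominance = dominance,
               expectedDtabrOrder = "doc_like > cg_like")
  list(recording = rec, truth = truth)
}

#' Simulate a delayed phase-coupled oscillator pair
#'
#' Two noisy oscillators at the band's center frequency. The second
#' oscillator's phase increment pulls toward the first oscillator's phase
#' from `delay` samples earlier with strength `kappa` (in units of the
#' angular step per sample), plus phase noise; `kappa = 0` yields
#' independent oscillators. Supports validation of directed phase-metric
#' recovery with a known coupling direction X -> Y.
#'
#' @param rate sampling rate in Hz.
#' @param durationS duration in seconds.
#' @param band oscillation band `c(lo, hi)` in Hz (center frequency used).
#' @param delay coupling delay in samples.
#' @param kappa coupling strength (>= 0).
#' @param phaseNoise phase-noise SD as a fraction of the angular step.
#' @param seed random seed.
#' @return An [EEGRecording-class] with channels "X" (driver) and "Y"
#'   (receiver).
#' @export
simulatePhaseCoupledPair <- function(rate = 250, durationS = 20,
                                     band = c(8, 13), delay = 10, kappa = 1,
                                     phaseNoise = 0.3, seed = 1) {
  if (kappa < 0) stop("parameter error: kappa must be >= 0")
  N <- as.integer(round(durationS * rate))
  if (delay >= N) stop("parameter error: delay must be shorter than the recording")
  set.seed(as.integer(seed))
  w <- 2 * pi * mean(band) / rate
  thx <- cumsum(w + rnorm(N, 0, phaseNoise * w))
  thy <- numeric(N)
  thy[seq_len(delay)] <- cumsum(w + rnorm(delay, 0, phaseNoise * w))
  ny <- rnorm(N, 0, phaseNoise * w)
  for (t in (delay + 1L):N)
    thy[t] <- thy[t - 1] + w + kappa * w * sin(thx[t - delay] - thy[t - 1]) +
      ny[t]
  EEGRecording(rbind(sin(thx), sin(thy)), rate = rate, labels = c("X", "Y"),
               meta = list(synthetic = TRUE, kappa = kappa, delay = delay,
                           band = band, seed = as.integer(seed)))
}

#' Generate two synthetic cohorts
#'
#' Builds `nCg` control-like and `nDoc` patient-like subjects. Per-subject
#' seeds and a multiplicative weight jitter (uniform within `1 +/- jitter`
#' per region/band cell) are derived deterministically from the master
#' seed before any simulation, so the cohort is identical regardless of
#' generation order.
#'
#' @param nCg,nDoc cohort sizes (defaults 9 and 11).
#' @param seed master seed.
#' @param durationS per-subject duration in seconds.
#' @param jitter relative weight jitter (default 0.1, i.e. +/- 10%).
#' @return list with elements `cg` and `doc`, each a list of
#'   `list(recording, truth, spec)` per subject.
#' @examples
#' coh <- makeCohorts(2, 2, seed = 1, durationS = 10)
#' length(coh$doc)
#' @export
makeCohorts <- function(nCg = 9, nDoc = 11, seed = 1, durationS = 120,
                        jitter = 0.1) {
  if (nCg < 1 || nDoc < 1) stop("parameter error: cohort sizes must be >= 1")
  set.seed(as.integer(seed))
  total <- nCg + nDoc
  subjSeeds <- sample.int(2147483646L, total)
  base <- list(cg = makeProfile("cg_like", durationS = durationS),
               doc = makeProfile("doc_like", durationS = durationS))
  nW <- length(base$cg@bandWeights)
  jitters <- lapply(seq_len(total), function(i)
    matrix(runif(nW, 1 - jitter, 1 + jitter), nrow(base$cg@bandWeights)))
  buildSubject <- function(profile, idx, subjectNo) {
    spec <- base[[profile]]
    spec@bandWeights <- spec@bandWeights * jitters[[idx]]
    spec@seed <- subjSeeds[idx]
    sim <- simulateRecording(spec)
    sim$recording@meta$subject <-
      sprintf("%s_%02d", if (profile == "cg") "cg" else "doc", subjectNo)
    sim$recording@meta$group <- if (profile == "cg") "CG" else "DOC"
    c(sim, list(spec = spec))
  }
  list(cg = lapply(seq_len(nCg), function(i) buildSubject("cg", i, i)),
       doc = lapply(seq_len(nDoc), function(i)
         buildSubject("doc", nCg + i, i)))
}
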
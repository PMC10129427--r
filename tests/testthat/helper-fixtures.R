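# Shared fixtures and independent oracles, all built in code at test time.

toyRecording <- function(nchan = 2, n = 5000, fs = 250, seed = 1,
                         labels = c("C3", "C4", "F3", "F4", "O1", "O2")[seq_len(nchan)]) {
  set.seed(seed)
  EEGRecording(matrix(rnorm(nchan * n), nchan), fs, labels)
}

sineRecording <- function(freq, fs = 250, durationS = 20, label = "Cz",
                          amplitude = 1) {
  t <- seq(0, durationS - 1 / fs, by = 1 / fs)
  EEGRecording(matrix(amplitude * sin(2 * pi * freq * t), 1), fs, label)
}

# Two-channel synthetic spec with an optional single directed edge; the
# workhorse for directed-coupling recovery checks. bandWeight = 0 gives
# white innovations (the canonical Granger textbook setting); positive
# weights add band-limited (colored) structure.
pairSpec <- function(strength = 0.7, lag = 3, durationS = 20, seed = 1,
                     noiseSd = 1, bandWeight = 0.25) {
  W <- matrix(bandWeight, 1, 4, dimnames = list("central",
                                                names(defaultBands())))
  graph <- if (strength > 0)
    data.frame(source = "C3", target = "C4", lag = lag, strength = strength)
  else
    data.frame(source = character(), target = character(), lag = integer(),
               strength = numeric())
  syntheticSpec(labels = c("C3", "C4"), durationS = durationS,
                bandWeights = W, couplingGraph = graph, noiseSd = noiseSd,
                seed = seed)
}

# Independent Mann-Whitney oracle: U by pairwise counting (not rank sums),
# exact two-sided p by enumeration of group assignments, again via pairwise
# counting. Only feasible for small n.
bruteMannWhitney <- function(a, b) {
  uOf <- function(x, y) {
    u <- 0
    for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
    u
  }
  u <- uOf(a, b)
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  uAll <- apply(idx, 2, function(k) uOf(pool[k], pool[-k]))
  p <- min(1, 2 * min(mean(uAll <= u + 1e-9), mean(uAll >= u - 1e-9)))
  list(u = u, p = p)
}

# PTE of one ordered pair from binned phases (plug-in + Miller-Madow),
# written independently of the C++ kernel.
refPTE <- function(bx, by, delay, bins, mm = TRUE) {
  n <- length(bx)
  yf <- by[(1 + delay):n]; yp <- by[1:(n - delay)]; xp <- bx[1:(n - delay)]
  ent <- function(idx, k) {
    cnt <- tabulate(idx, k); cnt <- cnt[cnt > 0]
    p <- cnt / sum(cnt)
    h <- -sum(p * log(p))
    if (mm) h + (length(cnt) - 1) / (2 * sum(cnt)) else h
  }
  b <- bins
  ent(yp + (xp - 1L) * b, b * b) + ent(yf + (yp - 1L) * b, b * b) -
    ent(yp, b) - ent(yf + (yp - 1L) * b + (xp - 1L) * b * b, b * b * b)
}

binPhases <- function(ph, bins) {
  pmin(bins, floor((ph + pi) / (2 * pi) * bins) + 1L)
}
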
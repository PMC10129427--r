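#' @include accessors.R
NULL

#' Mann-Whitney U test with midranks, exact enumeration and tie-corrected
#' normal approximation
#'
#' U is computed from rank sums with midranks for ties. In exact mode the
#' two-sided p value is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the observed (possibly tied)
#' ranks: p = min(1, 2 * min(P(U <= u), P(U >= u))). In normal mode the
#' tie-corrected variance and a 0.5 continuity correction give
#' Z = (U - n1 n2 / 2 -/+ 0.5) / sd and p = 2 * pnorm(-|Z|). Z is negative
#' when the first group ranks lower. The reported Z is always the normal
#' approximation, also in exact mode.
#'
#' @param a,b numeric value vectors for the two groups.
#' @param mode "exact" (requires n1 + n2 <= 20), "normal", or "auto"
#'   (exact when n1 + n2 <= 20).
#' @param pooling tag recorded in the result (used by
#'   [contrastConnectivity()]).
#' @return A [GroupTestResult-class]. When all values are identical across
#'   both groups the result is flagged degenerate with Z = 0, p = 1.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4), mode = "exact")  # U = 0, p = 1/3
#' @export
mannWhitney <- function(a, b, mode = c("auto", "exact", "normal"),
                        pooling = "none") {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("parameter error: both groups must be non-empty")
  if (anyNA(c(a, b))) stop("parameter error: missing values are not allowed")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (mode == "auto") mode <- if (n <= 20) "exact" else "normal"
  if (mode == "exact" && n > 20)
    stop("precondition error: exact mode requires n1 + n2 <= 20")
  r <- rank(c(a, b))   # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  degenerate <- length(unique(c(a, b))) == 1L
  # tie-corrected normal approximation
  mu <- n1 * n2 / 2
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tieAdj / (n * (n - 1)))
  if (degenerate || v <= 0) {
    z <- 0; pNorm <- 1
  } else {
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
    if (u == mu) z <- 0
    pNorm <- 2 * pnorm(-abs(z))
  }
  if (mode == "exact" && !degenerate) {
    cmb <- combn(n, n1)
    uAll <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(uAll <= u + 1e-9), mean(uAll >= u - 1e-9)))
  } else p <- pNorm
  new("GroupTestResult", u = u, z = z, p = min(1, p), n1 = n1, n2 = n2,
      mode = mode, pooling = pooling, degenerate = degenerate)
}

#' Normal quantile-quantile pairing with a linearity score
#'
#' Sample quantiles against standard-normal quantiles at plotting positions
#' (i - 0.5) / n, plus the squared Pearson correlation of the pairing as a
#' linearity score (values near 1 indicate compatibility with normality).
#'
#' @param values numeric vector, at least 3 distinct values.
#' @return list with `theoretical`, `sample`, and `linearity`.
#' @examples
#' qqNormal(rnorm(50))$linearity
#' @export
qqNormal <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("precondition error: need at least 3 values")
  if (length(unique(values)) == 1L)
    stop("degeneracy error: constant input has no quantile spread")
  n <- length(values)
  theo <- qnorm((seq_len(n) - 0.5) / n)
  samp <- sort(values)
  list(theoretical = theo, sample = samp, linearity = cor(theo, samp)^2)
}
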
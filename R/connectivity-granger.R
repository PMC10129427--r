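#' @include accessors.R epochs.R
NULL

# ---------------------------------------------------------------------------
# Bivariate Granger causality via least-squares VAR fits. All nested models
# (both targets, every candidate order, restricted and full predictor sets)
# are derived from a single Gram matrix of the maximally lagged design, so
# order selection and both F-tests cost one crossprod per channel pair.
# Lagged rows never cross epoch boundaries: each epoch is embedded
# separately and treated as an independent realization sharing coefficients.
# ---------------------------------------------------------------------------

# Stacked lag embedding: columns [x_t, x_{t-1}, ..., x_{t-maxp}]
.lagStack <- function(seriesList, maxp) {
  do.call(rbind, lapply(seriesList, function(s) stats::embed(s, maxp + 1L)))
}

.gramPair <- function(Ex, Ey, maxp) {
  M <- cbind(1, Ex[, 2:(maxp + 1L), drop = FALSE],
             Ey[, 2:(maxp + 1L), drop = FALSE], Ex[, 1L], Ey[, 1L])
  list(G = crossprod(M), n = nrow(M),
       ic = 1L, xl = 1L + seq_len(maxp), yl = 1L + maxp + seq_len(maxp),
       tx = 2L * maxp + 2L, ty = 2L * maxp + 3L)
}

.gramRSS <- function(gp, target, predictors) {
  G <- gp$G
  cf <- solve(G[predictors, predictors], G[predictors, target])
  rss <- G[target, target] - drop(G[target, predictors, drop = FALSE] %*% cf)
  list(rss = rss, coef = cf)
}

# BIC over candidate orders from the joint (two-target) regression.
.selectOrder <- function(gp, maxOrder) {
  bic <- setNames(numeric(maxOrder), seq_len(maxOrder))
  for (p in seq_len(maxOrder)) {
    pr <- c(gp$ic, gp$xl[seq_len(p)], gp$yl[seq_len(p)])
    tt <- c(gp$tx, gp$ty)
    Sxy <- gp$G[pr, tt]
    R <- gp$G[tt, tt] - crossprod(Sxy, solve(gp$G[pr, pr], Sxy))
    bic[p] <- log(det(R / gp$n)) + log(gp$n) / gp$n * (4 * p + 2)
  }
  bic
}

.companionFromCoef <- function(A) {
  p <- length(A); d <- nrow(A[[1]])
  C <- matrix(0, d * p, d * p)
  for (l in seq_len(p)) C[1:d, ((l - 1) * d + 1):(l * d)] <- A[[l]]
  if (p > 1) C[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  C
}

.spectralRadius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

#' Fit a bivariate vector autoregression
#'
#' Least-squares VAR fit on one channel pair, epochs treated as independent
#' realizations sharing coefficients. The lag order is chosen by the
#' Bayesian information criterion over `1..maxOrder`; among candidate
#' orders only stable models (companion spectral radius < 1) are accepted.
#'
#' @param epochs an [EpochSet-class].
#' @param channels the two channels (labels or indices).
#' @param maxOrder maximum candidate lag order (default 6).
#' @return A [VARModel-class].
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 5000), 2), 250, c("C3", "C4"))
#' fitVAR(epochAndReject(rec, 2, 1e6), c("C3", "C4"))
#' @export
fitVAR <- function(epochs, channels, maxOrder = 6) {
  maxOrder <- as.integer(maxOrder)
  if (length(channels) != 2) stop("parameter error: channels must name a pair")
  if (is.character(channels)) channels <- match(channels, epochs@labels)
  if (anyNA(channels)) stop("parameter error: unknown channel")
  epLen <- ncol(epochs@epochs[[1]])
  if (epLen <= 10L * maxOrder)
    stop("precondition error: epochs of ", epLen,
         " samples are too short for max order ", maxOrder,
         " (need > ", 10L * maxOrder, ")")
  xs <- lapply(epochs@epochs, function(m) m[channels[1], ])
  ys <- lapply(epochs@epochs, function(m) m[channels[2], ])
  gp <- .gramPair(.lagStack(xs, maxOrder), .lagStack(ys, maxOrder), maxOrder)
  bic <- tryCatch(.selectOrder(gp, maxOrder), error = function(e)
    stop("degeneracy error: singular regressor matrix (",
         conditionMessage(e), ")"))
  for (p in order(bic)) {
    pr <- c(gp$ic, gp$xl[seq_len(p)], gp$yl[seq_len(p)])
    fx <- .gramRSS(gp, gp$tx, pr)
    fy <- .gramRSS(gp, gp$ty, pr)
    A <- lapply(seq_len(p), function(l)
      rbind(c(fx$coef[1 + l], fx$coef[1 + p + l]),
            c(fy$coef[1 + l], fy$coef[1 + p + l])))
    if (.spectralRadius(.companionFromCoef(A)) < 1) {
      # ML residual covariance including the cross term
      tt <- c(gp$tx, gp$ty)
      Sxy <- gp$G[pr, tt]
      R <- (gp$G[tt, tt] - crossprod(Sxy, solve(gp$G[pr, pr], Sxy))) / gp$n
      labs <- epochs@labels[channels]
      dimnames(R) <- list(labs, labs)
      return(new("VARModel", order = as.integer(p), coefficients = A,
                 intercept = c(fx$coef[1], fy$coef[1]), residCov = R,
                 criterion = bic, stable = TRUE, channels = labs))
    }
  }
  stop("instability error: no stable VAR found at any order up to ", maxOrder)
}

# GC and F-test for both directions of one pair, at the BIC-selected order.
.gcPairFromGram <- function(gp, maxOrder) {
  bic <- .selectOrder(gp, maxOrder)
  p <- which.min(bic)
  full <- c(gp$ic, gp$xl[seq_len(p)], gp$yl[seq_len(p)])
  dfDen <- gp$n - (2 * p + 1)
  res <- list(order = p)
  for (dir in c("xy", "yx")) {   # xy: x -> y (target y)
    target <- if (dir == "xy") gp$ty else gp$tx
    own <- if (dir == "xy") gp$yl[seq_len(p)] else gp$xl[seq_len(p)]
    rssF <- .gramRSS(gp, target, full)$rss
    rssR <- .gramRSS(gp, target, c(gp$ic, own))$rss
    if (rssF <= 0) stop("degeneracy error: zero residual variance")
    gc <- max(0, log(rssR / rssF))
    Fst <- ((rssR - rssF) / p) / (rssF / dfDen)
    res[[paste0("gc_", dir)]] <- gc
    res[[paste0("p_", dir)]] <- pf(Fst, p, dfDen, lower.tail = FALSE)
  }
  res
}

#' Pairwise Granger causality over all channel pairs
#'
#' For every ordered channel pair (i, j), GC(i -> j) =
#' ln(sigma2_restricted / sigma2_full), where the restricted model predicts
#' j from its own lags only and the full model adds the lags of i; the lag
#' order is selected per pair by BIC over `1..maxOrder`. The binary matrix
#' is the F-test of the restriction at level `alpha`. Negative values
#' arising from numerical noise are clipped to zero. Pairs whose fit fails
#' (e.g. duplicated channels giving a singular design) are reported as `NA`
#' in both matrices and listed in `params(...)$failed`, never silently zero.
#'
#' @param x an [EpochSet-class] or [EEGRecording-class] (the latter is
#'   treated as a single realization; `runs` may give artifact-free
#'   segments as a data.frame with columns `start`, `length` in samples).
#' @param maxOrder maximum VAR order (default 6).
#' @param alpha significance level of the binary decision (default 0.05).
#' @param runs optional segment table for the recording method.
#' @return list with elements `gc` (a directed [ConnMatrix-class] of GC
#'   values), `binary` (0/1 decisions, metric "granger_binary"), and
#'   `pvalues` (numeric matrix).
#' @export
setGeneric("grangerPairwise", function(x, maxOrder = 6, alpha = 0.05,
                                       runs = NULL)
  standardGeneric("grangerPairwise"))

#' @rdname grangerPairwise
#' @export
setMethod("grangerPairwise", "EpochSet",
  function(x, maxOrder = 6, alpha = 0.05, runs = NULL) {
    series <- lapply(seq_along(x@labels), function(ch)
      lapply(x@epochs, function(m) m[ch, ]))
    .grangerCore(series, x@labels, as.integer(maxOrder), alpha,
                 ncol(x@epochs[[1]]))
  })

#' @rdname grangerPairwise
#' @export
setMethod("grangerPairwise", "EEGRecording",
  function(x, maxOrder = 6, alpha = 0.05, runs = NULL) {
    if (is.null(runs))
      runs <- data.frame(start = 1L, length = ncol(x@samples))
    series <- lapply(seq_len(nrow(x@samples)), function(ch)
      lapply(seq_len(nrow(runs)), function(r)
        x@samples[ch, runs$start[r]:(runs$start[r] + runs$length[r] - 1L)]))
    .grangerCore(series, x@labels, as.integer(maxOrder), alpha,
                 min(runs$length))
  })

.grangerCore <- function(series, labels, maxOrder, alpha, segLen) {
  n <- length(labels)
  if (n < 2) stop("parameter error: need at least 2 channels")
  if (segLen <= 10L * maxOrder)
    stop("precondition error: segments of ", segLen,
         " samples are too short for max order ", maxOrder)
  lagged <- lapply(series, .lagStack, maxp = maxOrder)
  gc <- matrix(0, n, n); pv <- matrix(NA_real_, n, n); bin <- matrix(0, n, n)
  failed <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      gp <- .gramPair(lagged[[i]], lagged[[j]], maxOrder)
      r <- tryCatch(.gcPairFromGram(gp, maxOrder), error = function(e) e)
      if (inherits(r, "error")) {
        gc[i, j] <- gc[j, i] <- NA_real_
        bin[i, j] <- bin[j, i] <- NA_real_
        failed <- c(failed, sprintf("%s~%s: %s", labels[i], labels[j],
                                    conditionMessage(r)))
      } else {
        gc[i, j] <- r$gc_xy; pv[i, j] <- r$p_xy; bin[i, j] <- as.numeric(r$p_xy < alpha)
        gc[j, i] <- r$gc_yx; pv[j, i] <- r$p_yx; bin[j, i] <- as.numeric(r$p_yx < alpha)
      }
    }
  }
  dimnames(pv) <- list(labels, labels)
  params <- list(max_order = maxOrder, alpha = alpha, failed = failed)
  list(gc = .connMatrix(gc, "granger", "broadband", TRUE, labels, params),
       binary = .connMatrix(bin, "granger_binary", "broadband", TRUE, labels,
                            params),
       pvalues = pv)
}
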
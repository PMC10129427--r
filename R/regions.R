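#' @include AllClasses.R
NULL

# Canonical 10-20 capitalization, keyed by upper-cased label. The montage
# dialect with T7/T8/P7/P8 is accepted and mapped onto the classical
# T3/T4/T5/T6 names, which are canonical here.
.canonical1020 <- local({
  canon <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
             "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz", "Oz",
             "Fpz", "A1", "A2")
  m <- setNames(canon, toupper(canon))
  m[c("T7", "T8", "P7", "P8")] <- c("T3", "T4", "T5", "T6")
  m
})

#' Normalize channel labels to canonical 10-20 form
#'
#' Case-insensitive matching against the 10-20 inventory; the T7/T8/P7/P8
#' dialect is mapped to the canonical T3/T4/T5/T6. Unknown labels are
#' preserved unchanged and reported.
#'
#' @param labels character vector of raw channel names.
#' @return list with `labels` (normalized) and `unknown` (original names not
#'   recognized as 10-20 positions).
#' @export
normalizeLabels <- function(labels) {
  up <- toupper(trimws(labels))
  hit <- .canonical1020[up]
  unknown <- labels[is.na(hit)]
  hit[is.na(hit)] <- labels[is.na(hit)]
  list(labels = unname(hit), unknown = unknown)
}

.hemisphereOfLabel <- function(labels) {
  digit <- sub("^[A-Za-z]+", "", labels)
  ifelse(grepl("z$", labels, ignore.case = TRUE), "midline",
    ifelse(digit != "" & as.integer(digit) %% 2 == 1, "left",
      ifelse(digit != "", "right", "midline")))
}

#' Standard scalp region map
#'
#' The five-region partition of the 10-20 montage used throughout:
#' frontal (Fp1, Fp2, F3, Fz, F4, F7, F8), central (C3, Cz, C4),
#' temporal (T3, T4, T5, T6), parietal (P3, Pz, P4), occipital (O1, Oz, O2).
#' Hemisphere is derived from the label suffix (odd = left, even = right,
#' z = midline).
#'
#' @return A [RegionMap-class].
#' @examples
#' rm <- standardRegionMap()
#' regionOf(rm, c("Fp1", "Cz", "T5"))
#' @export
standardRegionMap <- function() {
  assignment <- c(
    Fp1 = "frontal", Fp2 = "frontal", F3 = "frontal", Fz = "frontal",
    F4 = "frontal", F7 = "frontal", F8 = "frontal",
    C3 = "central", Cz = "central", C4 = "central",
    T3 = "temporal", T4 = "temporal", T5 = "temporal", T6 = "temporal",
    P3 = "parietal", Pz = "parietal", P4 = "parietal",
    O1 = "occipital", Oz = "occipital", O2 = "occipital")
  new("RegionMap", assignment = assignment,
      hemisphere = setNames(.hemisphereOfLabel(names(assignment)),
                            names(assignment)))
}

#' Region and hemisphere lookups
#'
#' @param map a [RegionMap-class].
#' @param labels channel labels.
#' @param strict error on unmapped labels (default) instead of returning `NA`.
#' @return character vector of regions or hemispheres.
#' @export
regionOf <- function(map, labels, strict = TRUE) {
  r <- map@assignment[labels]
  if (strict && anyNA(r))
    stop("unmapped channel labels: ", paste(labels[is.na(r)], collapse = ", "))
  unname(r)
}

#' @rdname regionOf
#' @export
hemisphereOf <- function(map, labels, strict = TRUE) {
  h <- map@hemisphere[labels]
  if (anyNA(h)) {
    # fall back to the suffix rule for labels outside the stored inventory
    miss <- is.na(h)
    known <- grepl("^[A-Za-z]+([0-9]+|z|Z)$", labels[miss])
    h[miss][known] <- .hemisphereOfLabel(labels[miss][known])
    if (strict && anyNA(h))
      stop("cannot derive hemisphere for: ", paste(labels[is.na(h)], collapse = ", "))
  }
  unname(h)
}

#' The standard 19-channel 10-20 montage
#'
#' @return character vector of the 19 classical electrode names.
#' @export
standardChannels19 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

#' Default frequency bands
#'
#' delta 1-3 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz. Bands are
#' closed intervals on the Welch frequency grid and do not overlap.
#'
#' @return named list of `c(lo, hi)` pairs in Hz.
#' @export
defaultBands <- function() {
  list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30))
}

.checkBands <- function(bands) {
  if (!length(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stop("bands must be a named list of c(lo, hi) pairs")
  edges <- t(vapply(bands, function(b) {
    if (length(b) != 2 || b[1] >= b[2]) stop("each band needs lo < hi")
    as.numeric(b)
  }, numeric(2)))
  o <- order(edges[, 1])
  if (any(edges[o, 1][-1] < edges[o, 2][-nrow(edges)]))
    stop("bands must not overlap")
  invisible(bands)
}
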
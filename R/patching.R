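# Centroid-anchored patch extraction and the training-area filter. Each
# sub-compartment contributes a single fixed-size window (default 5 x 5
# pixels, i.e. 50 m x 50 m at 10 m resolution) centered on the pixel nearest
# its anchor point.

#' Anchor point of a sub-compartment polygon
#'
#' The geometric centroid when it falls inside the polygon, otherwise a
#' guaranteed-interior representative point (concave sub-compartments can
#' place their centroid outside; an interior anchor is what keeps the window
#' away from neighboring units).
#'
#' @param ring polygon ring, n x 2 matrix of map coordinates.
#' @return Length-2 numeric (x, y) inside the polygon.
#' @export
anchorPoint <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3L) stop("empty geometry")
  interiorPoint(ring)
}

# map coordinate -> 0-based (row, col) of the nearest pixel center; ties
# toward smaller indices (round-half-down on the fractional index).
.mapToPixel <- function(pt, transform) {
  x0 <- transform[1]; y0 <- transform[2]; px <- transform[3]
  colf <- (pt[1] - x0) / px - 0.5
  rowf <- (y0 - pt[2]) / px - 0.5
  c(row = ceiling(rowf - 0.5), col = ceiling(colf - 0.5))
}

# 0-based pixel -> map coordinate of the pixel center
.pixelToMap <- function(rowcol, transform) {
  c(transform[1] + (rowcol[2] + 0.5) * transform[3],
    transform[2] - (rowcol[1] + 0.5) * transform[3])
}

#' Extract the centroid-anchored patch for one sub-compartment
#'
#' @param scene a [MultispectralScene-class].
#' @param ring polygon ring in map coordinates.
#' @param size odd window edge length in pixels (default 5).
#' @return A list of class `PatchSample`: `window` (size x size x nbands),
#'   `centerRowcol` (0-based), `valid`, `reason` (when invalid) and
#'   `centerInside`.
#' @export
extractPatch <- function(scene, ring, size = 5L) {
  stopifnot(size %% 2L == 1L, size >= 1L)
  anchor <- anchorPoint(ring)
  rc <- .mapToPixel(anchor, scene@transform)
  d <- dim(scene@bands)
  half <- size %/% 2L
  if (rc[1] < half || rc[2] < half ||
      rc[1] > d[1] - 1L - half || rc[2] > d[2] - 1L - half)
    stop("patch window crosses the raster edge (center pixel ",
         rc[1], ",", rc[2], ")")
  rr <- (rc[1] - half):(rc[1] + half) + 1L  # to 1-based
  cc <- (rc[2] - half):(rc[2] + half) + 1L
  win <- scene@bands[rr, cc, , drop = FALSE]
  maskHit <- any(scene@nodataMask[rr, cc])
  centerInside <- pointInPolygon(.pixelToMap(rc, scene@transform), ring)
  valid <- !maskHit && centerInside
  reason <- if (maskHit) "window intersects nodata"
            else if (!centerInside) "center pixel outside polygon"
            else NA_character_
  structure(list(window = win, centerRowcol = unname(rc),
                 bandNames = scene@bandNames, epoch = scene@epoch,
                 valid = valid, reason = reason,
                 centerInside = centerInside),
            class = "PatchSample")
}

#' Partition sub-compartments by the training-area threshold
#'
#' Strictly-greater-than comparison: a unit is training-eligible iff its area
#' exceeds `minAreaM2`. Small units are not discarded; they are flagged
#' out-of-distribution and kept for prediction/testing.
#'
#' @param areas numeric areas in m^2.
#' @param minAreaM2 threshold, default 3000.
#' @return list(eligible=, outOfDistribution=) of indices; the two partitions
#'   are disjoint and exhaustive.
#' @export
splitByArea <- function(areas, minAreaM2 = 3000) {
  eligible <- which(areas > minAreaM2)
  list(eligible = eligible,
       outOfDistribution = which(areas <= minAreaM2))
}

#' Stratified train/test split
#'
#' Splits the in-distribution samples into training and testing subsets,
#' stratified by class; out-of-distribution samples always go to the test
#' side. A class with fewer than 2 in-distribution samples is kept whole in
#' training, with a warning.
#'
#' @param labels character class labels, one per sample.
#' @param inDistribution logical, TRUE for training-eligible samples.
#' @param trainFraction fraction of in-distribution samples used for
#'   training (default 0.8).
#' @param seed integer seed; identical seeds give identical partitions.
#' @return list(train=, test=) of sample indices.
#' @export
trainTestSplit <- function(labels, inDistribution = rep(TRUE, length(labels)),
                           trainFraction = 0.8, seed = 1L) {
  if (sum(inDistribution) < 5L)
    stop("need at least 5 in-distribution samples")
  set.seed(seed)
  train <- integer()
  for (cl in unique(labels[inDistribution])) {
    idx <- which(inDistribution & labels == cl)
    if (length(idx) < 2L) {
      warning("class ", cl, " has fewer than 2 in-distribution samples; ",
              "kept whole in training")
      train <- c(train, idx)
      next
    }
    nTrain <- round(trainFraction * length(idx))
    nTrain <- min(max(nTrain, 1L), length(idx) - 1L)
    train <- c(train, sort(sample(idx, nTrain)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
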
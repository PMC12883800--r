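#' @import methods
NULL

#' Canonical vegetation cover class order
#'
#' Fixed ordering used everywhere for label encoding, probability columns,
#' confusion and transition matrices, and argmax tie-breaking.
#'
#' @return Character vector of the five cover types.
#' @export
vegClasses <- function() c("Arbor", "Shrub", "Bamboo", "Bare", "Other")

#' All supported band names, in canonical order
#' @return Character vector of band labels.
#' @export
allBands <- function() c("B2", "B3", "B4", "B8", "B11", "B12")

#' MultispectralScene: one epoch of georeferenced reflectance
#'
#' Holds a rows x cols x nbands reflectance stack for one epoch together with
#' an axis-aligned, north-up affine transform (map x of the left edge, map y
#' of the top edge, pixel size in meters), a CRS descriptor and a nodata
#' mask. Pixel indices are 0-based row/col with pixel-center registration.
#'
#' @slot bands numeric array rows x cols x nbands.
#' @slot bandNames character, unique, subset of [allBands()]; B2, B3, B4 and
#'   B8 must be present.
#' @slot transform numeric length 3: (x0, y0, pixelSize); map x = x0 +
#'   (col + 0.5) * pixelSize, map y = y0 - (row + 0.5) * pixelSize.
#' @slot crs list with elements `id` (e.g. "EPSG:32648") and `units` (must be
#'   "m": the area filters need meters).
#' @slot nodataMask logical rows x cols, TRUE where pixels are invalid.
#' @slot epoch character scalar epoch label.
#' @export
setClass("MultispectralScene", representation(
  bands = "array", bandNames = "character", transform = "numeric",
  crs = "list", nodataMask = "matrix", epoch = "character"
))

setValidity("MultispectralScene", function(object) {
  msg <- character()
  d <- dim(object@bands)
  if (length(d) != 3L) msg <- c(msg, "bands must be a rows x cols x nbands array")
  if (anyDuplicated(object@bandNames)) msg <- c(msg, "band names must be unique")
  need <- c("B2", "B3", "B4", "B8")
  miss <- setdiff(need, object@bandNames)
  if (length(miss)) msg <- c(msg, paste0("missing required band(s): ",
                                         paste(miss, collapse = ", ")))
  if (length(d) == 3L && d[3] != length(object@bandNames))
    msg <- c(msg, "bandNames length must match third array dimension")
  if (length(object@transform) != 3L || object@transform[3] <= 0)
    msg <- c(msg, "transform must be (x0, y0, pixelSize>0)")
  if (!identical(dim(object@nodataMask), d[1:2]))
    msg <- c(msg, "nodata mask shape must equal band shape")
  if (!identical(object@crs$units, "m"))
    msg <- c(msg, "CRS must be meter-based (crs$units == 'm')")
  if (length(msg)) msg else TRUE
})

#' Construct a MultispectralScene
#'
#' @param bands rows x cols x nbands numeric array of reflectance.
#' @param bandNames character labels for the third dimension.
#' @param transform numeric (x0, y0, pixelSize) north-up affine.
#' @param crs list(id=, units="m").
#' @param nodataMask logical matrix; defaults to all-FALSE.
#' @param epoch epoch label.
#' @return A [MultispectralScene-class] object.
#' @export
MultispectralScene <- function(bands, bandNames, transform,
                               crs = list(id = "EPSG:32648", units = "m"),
                               nodataMask = NULL, epoch = "e1") {
  if (is.null(nodataMask))
    nodataMask <- matrix(FALSE, dim(bands)[1], dim(bands)[2])
  new("MultispectralScene", bands = bands, bandNames = bandNames,
      transform = as.numeric(transform), crs = crs,
      nodataMask = nodataMask, epoch = epoch)
}

#' @describeIn MultispectralScene band name accessor
#' @param x a MultispectralScene.
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))
#' @rdname MultispectralScene
#' @export
setMethod("bandNames", "MultispectralScene", function(x) x@bandNames)

#' Extract one band as a matrix
#' @param x a MultispectralScene.
#' @param band band label, e.g. "B8".
#' @return rows x cols numeric matrix.
#' @export
setGeneric("getBand", function(x, band) standardGeneric("getBand"))
#' @rdname getBand
#' @export
setMethod("getBand", "MultispectralScene", function(x, band) {
  k <- match(band, x@bandNames)
  if (is.na(k)) stop("band not present: ", band)
  x@bands[, , k]
})

#' @rdname MultispectralScene
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))
#' @rdname MultispectralScene
#' @export
setMethod("nodataMask", "MultispectralScene", function(x) x@nodataMask)

#' @rdname MultispectralScene
#' @export
setGeneric("sceneTransform", function(x) standardGeneric("sceneTransform"))
#' @rdname MultispectralScene
#' @export
setMethod("sceneTransform", "MultispectralScene", function(x) x@transform)

#' @rdname MultispectralScene
#' @export
setGeneric("epochLabel", function(x) standardGeneric("epochLabel"))
#' @rdname MultispectralScene
#' @export
setMethod("epochLabel", "MultispectralScene", function(x) x@epoch)

setMethod("show", "MultispectralScene", function(object) {
  d <- dim(object@bands)
  cat("MultispectralScene (epoch ", object@epoch, ")\n",
      "  ", d[1], " x ", d[2], " pixels, ", d[3], " bands: ",
      paste(object@bandNames, collapse = " "), "\n",
      "  pixel size ", object@transform[3], " m, CRS ", object@crs$id, "\n",
      "  nodata pixels: ", sum(object@nodataMask), "\n", sep = "")
})

#' FSCSet: a collection of forest sub-compartment records
#'
#' Stores polygon geometries (rings in map coordinates), declared areas and
#' the cover-type label per epoch. Labels may be NA for prediction-only
#' epochs.
#'
#' @slot fscId character identifiers, unique.
#' @slot geometry list of rings (n x 2 matrices).
#' @slot areaM2 numeric declared areas in square meters.
#' @slot labels data.frame, one column per epoch, rows aligned with fscId.
#' @export
setClass("FSCSet", representation(
  fscId = "character", geometry = "list", areaM2 = "numeric",
  labels = "data.frame"
))

setValidity("FSCSet", function(object) {
  n <- length(object@fscId)
  msg <- character()
  if (anyDuplicated(object@fscId)) msg <- c(msg, "fsc ids must be unique")
  if (length(object@geometry) != n || length(object@areaM2) != n ||
      (n > 0 && nrow(object@labels) != n))
    msg <- c(msg, "fscId, geometry, areaM2 and labels must align")
  if (any(object@areaM2 <= 0)) msg <- c(msg, "areas must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an FSCSet
#' @param fscId character ids.
#' @param geometry list of rings (n x 2 matrices, map coordinates).
#' @param areaM2 numeric areas (m^2); computed from geometry when NULL.
#' @param labels data.frame of per-epoch class labels (one column per epoch).
#' @return An [FSCSet-class].
#' @export
FSCSet <- function(fscId, geometry, areaM2 = NULL, labels = NULL) {
  if (is.null(areaM2)) areaM2 <- vapply(geometry, polygonArea, 0)
  if (is.null(labels)) labels <- data.frame(row.names = seq_along(fscId))
  new("FSCSet", fscId = as.character(fscId), geometry = geometry,
      areaM2 = areaM2, labels = labels)
}

#' @rdname FSCSet
#' @param x an FSCSet.
#' @export
setGeneric("fscIds", function(x) standardGeneric("fscIds"))
#' @rdname FSCSet
#' @export
setMethod("fscIds", "FSCSet", function(x) x@fscId)

#' @rdname FSCSet
#' @export
setGeneric("fscAreas", function(x) standardGeneric("fscAreas"))
#' @rdname FSCSet
#' @export
setMethod("fscAreas", "FSCSet", function(x) x@areaM2)

#' @rdname FSCSet
#' @export
setGeneric("fscGeometry", function(x) standardGeneric("fscGeometry"))
#' @rdname FSCSet
#' @export
setMethod("fscGeometry", "FSCSet", function(x) x@geometry)

#' @rdname FSCSet
#' @export
setGeneric("fscLabels", function(x) standardGeneric("fscLabels"))
#' @rdname FSCSet
#' @export
setMethod("fscLabels", "FSCSet", function(x) x@labels)

#' @export
setMethod("length", "FSCSet", function(x) length(x@fscId))

#' @export
setMethod("[", "FSCSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@fscId)
  new("FSCSet", fscId = x@fscId[i], geometry = x@geometry[i],
      areaM2 = x@areaM2[i], labels = x@labels[i, , drop = FALSE])
})

setMethod("show", "FSCSet", function(object) {
  cat("FSCSet with ", length(object@fscId), " sub-compartments\n",
      "  area range: ", round(min(object@areaM2)), " - ",
      round(max(object@areaM2)), " m^2\n",
      "  epochs labelled: ", paste(colnames(object@labels), collapse = " "),
      "\n", sep = "")
})

#' TransitionMatrix: class transitions between two epochs
#'
#' K x K counts with rows indexed by the earlier epoch's class and columns by
#' the later epoch's class.
#'
#' @slot counts integer matrix with dimnames = class order.
#' @slot classOrder character class labels.
#' @slot epochPair character length 2 (from, to).
#' @export
setClass("TransitionMatrix", representation(
  counts = "matrix", classOrder = "character", epochPair = "character"
))

setValidity("TransitionMatrix", function(object) {
  k <- length(object@classOrder)
  msg <- character()
  if (!all(dim(object@counts) == c(k, k)))
    msg <- c(msg, "counts must be K x K for K classes")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (length(object@epochPair) != 2L) msg <- c(msg, "epochPair must have length 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix ", object@epochPair[1], " -> ", object@epochPair[2],
      " (", sum(object@counts), " units)\n", sep = "")
  print(object@counts)
})

#' @rdname TransitionMatrix
#' @param x a TransitionMatrix.
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname TransitionMatrix
#' @export
setMethod("transitionCounts", "TransitionMatrix", function(x) x@counts)

#' TrainedClassifier: fitted vegetation cover classifier
#'
#' Virtual parent of the four model kinds. All subclasses carry the fixed
#' class order, the feature standardization constants and the training
#' feature names; [predictClasses()] dispatches on the subclass.
#'
#' @slot kind one of "RF", "SVM", "BPNN", "PSO-BPNN".
#' @slot classOrder fixed label ordering (ties break toward earlier entries).
#' @slot scaler list(center=, scale=) per-feature standardization.
#' @slot featureNames feature columns expected at prediction time.
#' @export
setClass("TrainedClassifier", representation(
  kind = "character", classOrder = "character", scaler = "list",
  featureNames = "character", "VIRTUAL"
))

#' @rdname TrainedClassifier
#' @export
setClass("RFClassifier", contains = "TrainedClassifier",
         representation(fit = "ANY"))
#' @rdname TrainedClassifier
#' @export
setClass("SVMClassifier", contains = "TrainedClassifier",
         representation(fit = "ANY"))
#' @rdname TrainedClassifier
#' @export
setClass("BPNNClassifier", contains = "TrainedClassifier",
         representation(net = "list", lossTrace = "numeric", spec = "list"))

setMethod("show", "TrainedClassifier", function(object) {
  cat(object@kind, " classifier over ", length(object@featureNames),
      " features, classes: ", paste(object@classOrder, collapse = " "),
      "\n", sep = "")
})
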
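# Spectral features: per-patch band means and ten standard vegetation
# indices. Indices are evaluated on patch band means by default (cheaper and
# deterministic; the per-pixel alternative is available as a switch in the
# feature-table builder because ratio indices differ between the two
# conventions).

#' Per-band arithmetic means of a patch window
#'
#' @param patch a `PatchSample` from [extractPatch()].
#' @return Named numeric vector, one mean per band over the window pixels.
#' @export
bandMeans <- function(patch) {
  v <- apply(patch$window, 3L, mean)
  names(v) <- patch$bandNames
  v
}

.VI_FORMULAS <- list(
  NDVI  = function(b) (b["B8"] - b["B4"]) / (b["B8"] + b["B4"]),
  EVI   = function(b) 2.5 * ((b["B8"] - b["B4"]) /
                               (b["B8"] + 6 * b["B4"] - 7.5 * b["B2"] + 1)),
  NBRI  = function(b) (b["B8"] - b["B12"]) / (b["B8"] + b["B12"]),
  SAVI  = function(b) 1.5 * ((b["B8"] - b["B4"]) / (b["B8"] + b["B4"] + 0.5)),
  RVI   = function(b) b["B8"] / b["B4"],
  DVI   = function(b) b["B8"] - b["B4"],
  NDBI  = function(b) (b["B11"] - b["B8"]) / (b["B11"] + b["B8"]),
  BGRVI = function(b) (b["B3"] - (b["B2"] + b["B4"])) /
                        (b["B3"] + (b["B2"] + b["B4"])),
  GNDVI = function(b) (b["B8"] - b["B3"]) / (b["B8"] + b["B3"]),
  NDWI  = function(b) (b["B3"] - b["B8"]) / (b["B3"] + b["B8"])
)

.VI_DENOMS <- list(
  NDVI  = function(b) b["B8"] + b["B4"],
  EVI   = function(b) b["B8"] + 6 * b["B4"] - 7.5 * b["B2"] + 1,
  NBRI  = function(b) b["B8"] + b["B12"],
  SAVI  = function(b) b["B8"] + b["B4"] + 0.5,
  RVI   = function(b) b["B4"],
  DVI   = function(b) 1,
  NDBI  = function(b) b["B11"] + b["B8"],
  BGRVI = function(b) b["B3"] + b["B2"] + b["B4"],
  GNDVI = function(b) b["B8"] + b["B3"],
  NDWI  = function(b) b["B3"] + b["B8"]
)

.VI_BANDS <- list(
  NDVI = c("B8", "B4"), EVI = c("B8", "B4", "B2"), NBRI = c("B8", "B12"),
  SAVI = c("B8", "B4"), RVI = c("B8", "B4"), DVI = c("B8", "B4"),
  NDBI = c("B11", "B8"), BGRVI = c("B3", "B2", "B4"),
  GNDVI = c("B8", "B3"), NDWI = c("B3", "B8")
)

#' Names of the supported vegetation indices
#' @return Character vector of the ten index codes.
#' @export
vegetationIndexNames <- function() names(.VI_FORMULAS)

#' Evaluate one vegetation index on band means
#'
#' Direct evaluation of the published band-ratio formulas: NDVI, EVI, NBRI,
#' SAVI (L = 0.5 with the 1.5 scaling), RVI, DVI, NDBI, BGRVI, GNDVI, NDWI.
#' A denominator below 1e-12 in magnitude yields 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param name index code, see [vegetationIndexNames()].
#' @param bands named numeric vector of band means (B2, B3, B4, B8 and, for
#'   NBRI/NDBI, B12/B11).
#' @return Numeric scalar index value.
#' @export
vegetationIndex <- function(name, bands) {
  f <- .VI_FORMULAS[[name]]
  if (is.null(f)) stop("unknown vegetation index: ", name)
  miss <- setdiff(.VI_BANDS[[name]], names(bands))
  if (length(miss))
    stop(name, " requires band(s): ", paste(miss, collapse = ", "))
  den <- .VI_DENOMS[[name]](bands)
  if (abs(den) < 1e-12)
    return(structure(0, degenerate = TRUE))
  unname(f(bands))
}

#' Evaluate all computable vegetation indices
#'
#' @param bands named numeric vector of band means.
#' @param names index codes; defaults to every index whose required bands are
#'   present.
#' @return Named numeric vector of index values.
#' @export
vegetationIndices <- function(bands, names = NULL) {
  if (is.null(names)) {
    names <- Filter(function(nm) all(.VI_BANDS[[nm]] %in% base::names(bands)),
                    vegetationIndexNames())
  }
  vapply(names, function(nm) as.numeric(vegetationIndex(nm, bands)),
         0, USE.NAMES = TRUE)
}

#' Build the per-sub-compartment feature table for one epoch
#'
#' Extracts the centroid patch of every sub-compartment, computes band means,
#' vegetation indices and GLCM texture metrics, and returns one row per unit.
#' Units whose window crosses the raster edge, intersects nodata or whose
#' center pixel falls outside the polygon are returned with `valid = FALSE`
#' and NA features.
#'
#' @param scene a [MultispectralScene-class].
#' @param fsc an [FSCSet-class].
#' @param size patch edge length in pixels.
#' @param textureBands band(s) on which GLCM metrics are computed (default
#'   "B8", the band with the strongest class signal).
#' @param glcmLevels gray-level quantization depth (default 32).
#' @param viPerPixel if TRUE, indices are computed per pixel and averaged
#'   instead of being evaluated on band means.
#' @param minAreaM2 training-area threshold used for the
#'   `in_distribution` flag.
#' @return data.frame: fsc_id, epoch, area_m2, in_distribution, valid, label
#'   (NA when the epoch is unlabeled) and one column per feature.
#' @export
featureTable <- function(scene, fsc, size = 5L, textureBands = "B8",
                         glcmLevels = 32L, viPerPixel = FALSE,
                         minAreaM2 = 3000) {
  n <- length(fsc)
  epoch <- scene@epoch
  labs <- fsc@labels
  labels <- if (epoch %in% colnames(labs)) labs[[epoch]] else rep(NA_character_, n)
  rows <- vector("list", n)
  featNames <- NULL
  for (i in seq_len(n)) {
    patch <- tryCatch(extractPatch(scene, fsc@geometry[[i]], size),
                      error = function(e) NULL)
    feats <- NULL
    valid <- FALSE
    if (!is.null(patch) && patch$valid) {
      bm <- bandMeans(patch)
      if (viPerPixel) {
        pix <- apply(patch$window, c(1, 2), function(v) {
          names(v) <- patch$bandNames
          vegetationIndices(v)
        })
        vi <- rowMeans(matrix(pix, nrow = dim(pix)[1]))
        names(vi) <- dimnames(pix)[[1]]
      } else {
        vi <- vegetationIndices(bm)
      }
      tex <- numeric()
      for (tb in textureBands) {
        q <- quantizeWindow(patch$window[, , match(tb, patch$bandNames)],
                            glcmLevels)
        tm <- textureMetrics(glcmMatrix(q, glcmLevels))
        names(tm) <- paste0("GLCM_", names(tm), "_", tb)
        tex <- c(tex, tm)
      }
      feats <- c(bm, vi, tex)
      valid <- TRUE
    }
    rows[[i]] <- list(valid = valid, feats = feats)
    if (valid && is.null(featNames)) featNames <- names(feats)
  }
  if (is.null(featNames)) stop("no valid patches in this scene/layer")
  mat <- matrix(NA_real_, n, length(featNames),
                dimnames = list(NULL, featNames))
  for (i in seq_len(n)) if (rows[[i]]$valid) mat[i, ] <- rows[[i]]$feats
  out <- data.frame(fsc_id = fsc@fscId, epoch = epoch,
                    area_m2 = fsc@areaM2,
                    in_distribution = fsc@areaM2 > minAreaM2,
                    valid = vapply(rows, function(r) r$valid, TRUE),
                    label = labels, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat))
}

#' Names of the feature columns in a feature table
#' @param tab a feature table from [featureTable()].
#' @return Character vector of feature column names.
#' @export
featureColumns <- function(tab) {
  setdiff(colnames(tab),
          c("fsc_id", "epoch", "area_m2", "in_distribution", "valid", "label"))
}
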
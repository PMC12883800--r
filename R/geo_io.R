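# Raster and vector I/O. Rasters are stored as multi-page 32-bit float TIFF
# (one page per band plus a trailing nodata-mask page) with a `.meta.json`
# sidecar carrying band names, the affine transform, the CRS and the linear
# offset/gain used to map reflectance into the [0, 1] sample range of the
# TIFF writer. Vector layers are GeoJSON; attribute tables are CSV.

.VAL_OFFSET <- -0.5
.VAL_SCALE <- 2.5  # stored = (value - offset) / scale, covers [-0.5, 2.0]

#' Write a scene to disk
#'
#' @param scene a [MultispectralScene-class].
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
writeScene <- function(scene, path) {
  arr <- scene@bands
  mask <- scene@nodataMask
  pages <- lapply(seq_along(scene@bandNames), function(k) {
    m <- arr[, , k]
    m[mask] <- .VAL_OFFSET  # placeholder under the mask
    (m - .VAL_OFFSET) / .VAL_SCALE
  })
  pages <- c(pages, list(mask * 1.0))
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write raster to ", path, ": ", attr(ok, "condition")$message)
  meta <- list(band_names = scene@bandNames,
               transform = scene@transform,
               crs = scene@crs, epoch = scene@epoch,
               value_offset = .VAL_OFFSET, value_scale = .VAL_SCALE,
               nodata = -9999)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene from disk
#'
#' Reads a raster written by [writeScene()]. Nodata pixels are set to NA and
#' recorded in the mask; reflectance values outside `[-0.1, 1.5]` are counted
#' in a validation report attached as attribute `validation`.
#'
#' @param path TIFF path with `<path>.meta.json` sidecar.
#' @param epoch optional epoch label override.
#' @return A [MultispectralScene-class] with attribute `validation`.
#' @export
readScene <- function(path, epoch = NULL) {
  if (!file.exists(path)) stop("raster not found: ", path)
  metaPath <- paste0(path, ".meta.json")
  if (!file.exists(metaPath)) stop("raster sidecar not found: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  bn <- meta$band_names
  need <- c("B2", "B3", "B4", "B8")
  miss <- setdiff(need, bn)
  if (length(miss))
    stop("raster is missing required band(s): ", paste(miss, collapse = ", "))
  if (!identical(meta$crs$units, "m"))
    stop("CRS ", meta$crs$id, " is not meter-based; area filters need meters")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(bn) + 1L)
    stop("raster has ", length(pages) - 1L, " band page(s), sidecar declares ",
         length(bn))
  mask <- pages[[length(pages)]] > 0.5
  rows <- nrow(mask); cols <- ncol(mask)
  arr <- array(0, c(rows, cols, length(bn)))
  for (k in seq_along(bn)) {
    m <- pages[[k]] * meta$value_scale + meta$value_offset
    m[mask] <- NA_real_
    arr[, , k] <- m
  }
  scene <- MultispectralScene(arr, bn, as.numeric(meta$transform),
                              crs = meta$crs, nodataMask = mask,
                              epoch = if (is.null(epoch)) meta$epoch else epoch)
  vals <- arr[!is.na(arr)]
  attr(scene, "validation") <- list(
    n_out_of_range = sum(vals < -0.1 | vals > 1.5),
    range = if (length(vals)) range(vals) else c(NA_real_, NA_real_))
  scene
}

#' Write an FSCSet as GeoJSON
#'
#' @param fsc an [FSCSet-class].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
writeFscLayer <- function(fsc, path) {
  labs <- fsc@labels
  feats <- lapply(seq_along(fsc@fscId), function(i) {
    ring <- fsc@geometry[[i]]
    coords <- rbind(ring, ring[1L, , drop = FALSE])
    props <- list(fsc_id = fsc@fscId[i], area_m2 = fsc@areaM2[i])
    for (ep in colnames(labs)) props[[paste0("class_", ep)]] <- labs[i, ep]
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(coords, row(coords))))),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an FSC polygon layer from GeoJSON
#'
#' Features must carry an `fsc_id` property. Declared `area_m2` values are
#' checked against the geometry (warning beyond 1% relative deviation, and
#' the geometry-derived area is kept); self-intersecting rings are rejected,
#' never silently kept. Rejections are reported in the `rejected` attribute
#' and via warnings.
#'
#' @param path `.geojson` path.
#' @return An [FSCSet-class]; attribute `rejected` is a data.frame of dropped
#'   features with reasons.
#' @export
readFscLayer <- function(path) {
  if (!file.exists(path)) stop("vector layer not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  ids <- character(); geoms <- list(); areas <- numeric()
  labcols <- list()
  rejected <- data.frame(fsc_id = character(), reason = character())
  for (f in feats) {
    props <- f$properties
    if (is.null(props$fsc_id)) stop("feature without fsc_id property")
    id <- as.character(props$fsc_id)
    ringRaw <- f$geometry$coordinates[[1]]
    ring <- do.call(rbind, lapply(ringRaw, function(p) c(p[[1]], p[[2]])))
    if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    if (nrow(ring) < 3L || isSelfIntersecting(ring)) {
      reason <- if (nrow(ring) < 3L) "degenerate ring" else "self-intersecting ring"
      warning("rejecting feature ", id, ": ", reason)
      rejected <- rbind(rejected, data.frame(fsc_id = id, reason = reason))
      next
    }
    gArea <- polygonArea(ring)
    dArea <- props$area_m2
    if (!is.null(dArea) && is.finite(as.numeric(dArea))) {
      dArea <- as.numeric(dArea)
      if (abs(dArea - gArea) > 0.01 * max(gArea, 1e-12))
        warning("feature ", id, ": declared area ", signif(dArea, 6),
                " deviates >1% from geometry area ", signif(gArea, 6))
    }
    ids <- c(ids, id); geoms <- c(geoms, list(ring)); areas <- c(areas, gArea)
    for (nm in names(props)) {
      if (startsWith(nm, "class_")) {
        ep <- sub("^class_", "", nm)
        labcols[[ep]] <- c(labcols[[ep]], as.character(props[[nm]]))
      }
    }
  }
  labels <- if (length(labcols))
    as.data.frame(labcols, stringsAsFactors = FALSE)
  else data.frame(row.names = seq_along(ids))
  fsc <- FSCSet(fscId = ids, geometry = geoms, areaM2 = areas, labels = labels)
  attr(fsc, "rejected") <- rejected
  fsc
}

#' Write a scene pair plus sub-compartment layer to a directory
#'
#' Emits `raster_e1.tif`, `raster_e2.tif` (with sidecars), `fsc.geojson` and
#' `labels.csv`.
#'
#' @param scenePair list as returned by [generateScenePair()].
#' @param dir output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
writeSceneFiles <- function(scenePair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("directory not writable: ", dir)
  p1 <- file.path(dir, "raster_e1.tif")
  p2 <- file.path(dir, "raster_e2.tif")
  pv <- file.path(dir, "fsc.geojson")
  pc <- file.path(dir, "labels.csv")
  writeScene(scenePair$epoch1, p1)
  writeScene(scenePair$epoch2, p2)
  writeFscLayer(scenePair$fsc, pv)
  labs <- scenePair$fsc@labels
  colnames(labs) <- paste0("class_", colnames(labs))
  utils::write.csv(
    cbind(data.frame(fsc_id = scenePair$fsc@fscId,
                     area_m2 = scenePair$fsc@areaM2), labs),
    pc, row.names = FALSE)
  invisible(c(raster_e1 = p1, raster_e2 = p2, fsc = pv, labels = pc))
}
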
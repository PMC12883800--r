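# Synthetic two-epoch scene generator. Emulates the statistical structure the
# pipeline assumes: five cover classes with distinct band reflectance and
# distinct spatial autocorrelation (hence distinct GLCM texture), an irregular
# sub-compartment tessellation with a heavy-tailed area distribution, and a
# configurable fraction of sub-compartments whose class changes between
# epochs.

#' Scene generator configuration
#'
#' @param gridShape integer length 2, raster rows and cols in pixels.
#' @param pixelSize pixel size in meters (default 10, Sentinel-2-like).
#' @param nFsc number of sub-compartment polygons.
#' @param classProportions five nonnegative fractions (Arbor, Shrub, Bamboo,
#'   Bare, Other) summing to 1. Defaults mirror a training-set composition
#'   rebalanced away from the heavy Arbor dominance of a full inventory
#'   (0.4387/0.4002/0.1397/0.0073/0.0141).
#' @param changeFraction fraction of sub-compartments whose label changes
#'   between epochs, in `[0, 1]`.
#' @param noiseSd marginal standard deviation of the reflectance noise field.
#' @param nodataFrac fraction of pixels covered by rectangular nodata holes
#'   (cloud-mask stand-in), default 0.
#' @param seed integer RNG seed; identical seeds give identical scenes.
#' @return A list of class `SceneConfig`.
#' @export
sceneConfig <- function(gridShape = c(460L, 460L), pixelSize = 10, nFsc = 2200L,
                        classProportions = c(0.4387, 0.4002, 0.1397, 0.0073, 0.0141),
                        changeFraction = 0.1, noiseSd = 0.04,
                        nodataFrac = 0, seed = 1L) {
  stopifnot(length(gridShape) == 2L, all(gridShape >= 1))
  if (abs(sum(classProportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (any(classProportions < 0)) stop("class proportions must be nonnegative")
  if (changeFraction < 0 || changeFraction > 1)
    stop("changeFraction must be in [0, 1]")
  structure(list(gridShape = as.integer(gridShape), pixelSize = pixelSize,
                 nFsc = as.integer(nFsc),
                 classProportions = classProportions,
                 changeFraction = changeFraction, noiseSd = noiseSd,
                 nodataFrac = nodataFrac, seed = as.integer(seed)),
            class = "SceneConfig")
}

#' Default class spectral/texture signatures
#'
#' Band reflectance means per class (B2, B3, B4, B8, B11, B12), a per-class
#' noise multiplier and a texture correlation length (pixels) controlling the
#' within-polygon spatial autocorrelation of the noise field. The vegetated
#' classes have NIR (B8) well above red (B4); bare ground has red at or above
#' NIR. Arbor and Bamboo are spectrally close but differ strongly in texture
#' scale, so their separation rests mainly on GLCM features.
#'
#' @return data.frame with one row per class.
#' @export
classSignatures <- function() {
  data.frame(
    class = vegClasses(),
    B2  = c(0.030, 0.050, 0.035, 0.120, 0.060),
    B3  = c(0.060, 0.090, 0.065, 0.160, 0.110),
    B4  = c(0.040, 0.080, 0.045, 0.260, 0.100),
    B8  = c(0.450, 0.320, 0.430, 0.240, 0.280),
    B11 = c(0.180, 0.220, 0.190, 0.300, 0.240),
    B12 = c(0.090, 0.130, 0.100, 0.280, 0.160),
    bandSd = c(1.0, 1.0, 1.0, 0.8, 1.0),
    textureScale = c(2.5, 1.2, 0.6, 4.0, 1.8),
    stringsAsFactors = FALSE
  )
}

# Separable Gaussian smoothing with boundary renormalization; sigma in pixels.
.gaussSmooth <- function(mat, sigma) {
  if (sigma <= 0.05) return(mat)
  smooth1 <- function(n) {
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
    K / rowSums(K)
  }
  Kr <- smooth1(nrow(mat))
  Kc <- smooth1(ncol(mat))
  Kr %*% mat %*% t(Kc)
}

# Seed-point process for the tessellation: one "macro" seed with a guaranteed
# exclusion disc (produces a cell >= ~10% of the grid), one 5-seed sliver
# construct (produces a ~1-pixel cell), and a multi-scale Neyman-Scott
# cluster process for the remainder (heavy-tailed cell areas).
.seedPoints <- function(n, W, H, px) {
  if (n < 8L) {
    return(cbind(stats::runif(n, 0, W), stats::runif(n, 0, H)))
  }
  r <- min(0.36 * sqrt(W * H), 0.45 * min(W, H))
  macro <- c(stats::runif(1, 0.40 * W, 0.60 * W),
             stats::runif(1, 0.40 * H, 0.60 * H))
  pushOut <- function(pts) {
    d <- sqrt((pts[, 1] - macro[1])^2 + (pts[, 2] - macro[2])^2)
    inside <- d < r
    if (any(inside)) {
      # project onto the exclusion circle, tiny jitter to avoid collinearity
      th <- atan2(pts[inside, 2] - macro[2], pts[inside, 1] - macro[1])
      rr <- r * (1 + stats::runif(sum(inside), 0.01, 0.10))
      pts[inside, 1] <- macro[1] + rr * cos(th)
      pts[inside, 2] <- macro[2] + rr * sin(th)
    }
    pts[, 1] <- pmin(pmax(pts[, 1], 0.2 * px), W - 0.2 * px)
    pts[, 2] <- pmin(pmax(pts[, 2], 0.2 * px), H - 0.2 * px)
    pts
  }
  # sliver construct: center + 4 cardinal neighbors at distance d -> the
  # center cell is a square of side d (area ~0.9 pixel)
  repeat {
    sc <- c(stats::runif(1, 3 * px, W - 3 * px), stats::runif(1, 3 * px, H - 3 * px))
    if (sqrt(sum((sc - macro)^2)) > r + 3 * px) break
  }
  d <- 0.95 * px
  sliver <- rbind(sc,
                  sc + c(d, 0), sc - c(d, 0),
                  sc + c(0, d), sc - c(0, d))
  # remainder: mostly uniform seeds (keeps most cells above the 3,000 m^2
  # training threshold) plus a clustered quarter for small-unit realism
  m <- n - 6L
  mClu <- round(0.15 * m)
  mUni <- m - mClu
  uni <- pushOut(cbind(stats::runif(mUni, 0, W), stats::runif(mUni, 0, H)))
  clu <- NULL
  if (mClu > 0) {
    ncl <- max(2L, round(mClu / 10))
    parents <- pushOut(cbind(stats::runif(ncl, 0, W), stats::runif(ncl, 0, H)))
    sdlo <- log(1.2 * px); sdhi <- log(0.05 * sqrt(W * H))
    clsd <- exp(stats::runif(ncl, sdlo, sdhi))
    assign <- sort(sample.int(ncl, mClu, replace = TRUE))
    clu <- pushOut(parents[assign, , drop = FALSE] +
                     cbind(stats::rnorm(mClu, 0, clsd[assign]),
                           stats::rnorm(mClu, 0, clsd[assign])))
  }
  rbind(matrix(macro, 1), sliver, uni, clu, deparse.level = 0)
}

#' Generate a two-epoch synthetic scene pair
#'
#' Tessellates the grid into Voronoi sub-compartments, assigns each a cover
#' class for epoch 1, injects `round(changeFraction * nFsc)` label changes
#' (chosen uniformly among sub-compartments larger than 3,000 m^2, with the
#' new label uniform over the other four classes) for epoch 2, and renders
#' per-epoch reflectance as the class band mean plus a spatially correlated
#' Gaussian noise field whose correlation length is class-specific.
#'
#' @param config a [sceneConfig()].
#' @param signatures class signature table, see [classSignatures()].
#' @return list with elements `epoch1`, `epoch2` ([MultispectralScene-class])
#'   and `fsc` ([FSCSet-class] with label columns `e1`, `e2`).
#' @export
generateScenePair <- function(config, signatures = classSignatures()) {
  stopifnot(inherits(config, "SceneConfig"))
  rows <- config$gridShape[1]; cols <- config$gridShape[2]
  px <- config$pixelSize
  if (config$nFsc > rows * cols)
    stop("nFsc (", config$nFsc, ") exceeds the pixel count (", rows * cols,
         "): polygons would fall below 1 pixel")
  stopifnot(all(signatures$B8[signatures$class %in% c("Arbor", "Shrub", "Bamboo")] >
                  signatures$B4[signatures$class %in% c("Arbor", "Shrub", "Bamboo")]))
  set.seed(config$seed)
  W <- cols * px; H <- rows * px
  seeds <- .seedPoints(config$nFsc, W, H, px)
  cells <- voronoiCells(seeds, c(0, 0, W, H))
  keep <- vapply(cells, nrow, 0L) >= 3L
  cells <- cells[keep]; seeds <- seeds[keep, , drop = FALSE]
  n <- length(cells)
  areas <- vapply(cells, polygonArea, 0)

  classes <- vegClasses()
  lab1 <- sample(classes, n, replace = TRUE, prob = config$classProportions)
  lab2 <- lab1
  nChange <- round(config$changeFraction * n)
  if (nChange > 0) {
    eligible <- which(areas > 3000)
    if (length(eligible) < nChange)
      stop("cannot inject ", nChange, " changes: only ", length(eligible),
           " sub-compartments exceed 3,000 m^2")
    chg <- sample(eligible, nChange)
    for (i in chg) lab2[i] <- sample(setdiff(classes, lab1[i]), 1L)
  }

  # pixel class map per epoch: nearest seed, chunked over rows; squared
  # distance via the cross-product expansion so BLAS does the heavy lifting
  cx <- (seq_len(cols) - 0.5) * px
  cy <- H - (seq_len(rows) - 0.5) * px
  nearest <- matrix(0L, rows, cols)
  s2 <- rowSums(seeds^2)
  chunk <- max(1L, floor(4e6 / (n * cols)))
  for (r0 in seq(1L, rows, by = chunk)) {
    r1 <- min(rows, r0 + chunk - 1L)
    ys <- cy[r0:r1]
    pxg <- cbind(rep(cx, each = length(ys)), rep(ys, times = cols))
    d2 <- sweep(-2 * pxg %*% t(seeds), 2, s2, "+")  # |p|^2 omitted: argmin only
    nearest[r0:r1, ] <- matrix(max.col(-d2, ties.method = "first"),
                               nrow = length(ys))
  }

  bands <- allBands()
  sig <- signatures[match(classes, signatures$class), ]
  renderEpoch <- function(lab, epoch) {
    clmap <- matrix(match(lab[nearest], classes), rows, cols)
    arr <- array(0, c(rows, cols, length(bands)))
    for (ci in seq_along(classes)) {
      idx <- clmap == ci
      if (!any(idx)) next
      for (bi in seq_along(bands)) {
        f <- .gaussSmooth(matrix(stats::rnorm(rows * cols), rows, cols),
                          sig$textureScale[ci])
        f <- (f - mean(f)) / stats::sd(f)
        plane <- arr[, , bi]
        plane[idx] <- sig[[bands[bi]]][ci] +
          config$noiseSd * sig$bandSd[ci] * f[idx]
        arr[, , bi] <- plane
      }
    }
    mask <- matrix(FALSE, rows, cols)
    if (config$nodataFrac > 0) {
      target <- config$nodataFrac * rows * cols
      while (sum(mask) < target) {
        hr <- sample.int(max(2L, rows %/% 8), 1L) + 1L
        hc <- sample.int(max(2L, cols %/% 8), 1L) + 1L
        r0 <- sample.int(rows - hr + 1L, 1L)
        c0 <- sample.int(cols - hc + 1L, 1L)
        mask[r0:(r0 + hr - 1L), c0:(c0 + hc - 1L)] <- TRUE
      }
      for (bi in seq_along(bands)) {
        plane <- arr[, , bi]; plane[mask] <- NA_real_; arr[, , bi] <- plane
      }
    }
    MultispectralScene(arr, bands, c(0, H, px), nodataMask = mask,
                       epoch = epoch)
  }
  scene1 <- renderEpoch(lab1, "e1")
  scene2 <- renderEpoch(lab2, "e2")

  fsc <- FSCSet(fscId = sprintf("fsc%05d", seq_len(n)), geometry = cells,
                areaM2 = areas,
                labels = data.frame(e1 = lab1, e2 = lab2,
                                    stringsAsFactors = FALSE))
  list(epoch1 = scene1, epoch2 = scene2, fsc = fsc)
}
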
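constantScene <- function(value = 0.3, rows = 5, cols = 5) {
  arr <- array(value, c(rows, cols, 4))
  MultispectralScene(arr, c("B2", "B3", "B4", "B8"),
                     c(0, rows * 10, 10))
}

test_that("anchor point is the centroid for convex polygons, interior otherwise", {
  square <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(anchorPoint(square), c(5, 5))
  tri <- rbind(c(0, 0), c(30, 0), c(0, 30))
  expect_equal(anchorPoint(tri), c(10, 10))
  cshape <- rbind(c(0, 0), c(10, 0), c(10, 2), c(2, 2), c(2, 8),
                  c(10, 8), c(10, 10), c(0, 10))
  p <- anchorPoint(cshape)
  expect_true(pointInPolygon(p, cshape))
  expect_error(anchorPoint(matrix(0, 0, 2)), "empty")
})

test_that("patch extraction reads the exact window and honors margins", {
  sc <- constantScene(0.3)
  ring <- rbind(c(0, 0), c(50, 0), c(50, 50), c(0, 50))  # covers the raster
  patch <- extractPatch(sc, ring, 5)
  expect_true(patch$valid)
  expect_true(all(patch$window == 0.3))
  # anchor at the raster center of a 5x5 raster: window is the whole raster
  expect_equal(patch$centerRowcol, c(2, 2))
  expect_equal(dim(patch$window), c(5, 5, 4))

  # anchor at pixel (1,1) violates the margin
  small <- rbind(c(0, 30), c(20, 30), c(20, 50), c(0, 50))  # centroid (10,40)
  expect_error(extractPatch(sc, small, 5), "edge")
})

test_that("patch values equal the raster block at the anchor pixel", {
  rows <- 20; cols <- 20
  arr <- array(seq_len(rows * cols * 4) / (rows * cols * 4),
               c(rows, cols, 4))
  sc <- MultispectralScene(arr, c("B2", "B3", "B4", "B8"), c(0, 200, 10))
  ring <- rbind(c(40, 40), c(120, 40), c(120, 120), c(40, 120))
  patch <- extractPatch(sc, ring, 5)
  # anchor (80,80) -> pixel row = 200-80 = y offset 120 -> row 11.5 -> 0-based
  rc <- patch$centerRowcol
  expect_equal(patch$window,
               arr[(rc[1] - 2):(rc[1] + 2) + 1, (rc[2] - 2):(rc[2] + 2) + 1, ,
                   drop = FALSE])
})

test_that("windows touching nodata are flagged invalid, not imputed", {
  sc <- constantScene(0.3, 9, 9)
  sc@nodataMask[5, 5] <- TRUE
  ring <- rbind(c(0, 0), c(90, 0), c(90, 90), c(0, 90))
  patch <- extractPatch(sc, ring, 5)
  expect_false(patch$valid)
  expect_match(patch$reason, "nodata")
})

test_that("area split uses a strict threshold and is exhaustive", {
  sp <- splitByArea(c(2999, 3000, 3001))
  expect_identical(sp$eligible, 3L)
  expect_identical(sp$outOfDistribution, c(1L, 2L))
  sp2 <- splitByArea(c(4000, 5000))
  expect_length(sp2$outOfDistribution, 0)
  pair <- testScenePair(seed = 3)
  sp3 <- splitByArea(fscAreas(pair$fsc))
  expect_equal(length(sp3$eligible) + length(sp3$outOfDistribution),
               length(pair$fsc))
  expect_length(intersect(sp3$eligible, sp3$outOfDistribution), 0)
})

test_that("train/test split is stratified, seeded and keeps OOD out of training", {
  labels <- rep(c("Arbor", "Shrub"), each = 50)
  sp <- trainTestSplit(labels, seed = 4)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_equal(sum(labels[sp$train] == "Arbor"), 40)  # 1:1 preserved
  sp2 <- trainTestSplit(labels, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- trainTestSplit(labels, seed = 5)
  expect_false(identical(sp$train, sp3$train))

  inDist <- c(rep(TRUE, 60), rep(FALSE, 40))
  sp4 <- trainTestSplit(labels, inDist, seed = 4)
  expect_true(all(inDist[sp4$train]))
  expect_true(all(which(!inDist) %in% sp4$test))

  expect_warning(trainTestSplit(c(rep("a", 10), "b"),
                                trainFraction = 0.8, seed = 1),
                 "fewer than 2")
})

test_that("large polygons keep the whole window inside the polygon", {
  pair <- testScenePair(seed = 3)
  areas <- fscAreas(pair$fsc)
  big <- which(areas > 10000)  # > 1 ha
  inside <- vapply(big, function(i) {
    ring <- fscGeometry(pair$fsc)[[i]]
    patch <- tryCatch(extractPatch(pair$epoch1, ring, 5),
                      error = function(e) NULL)
    if (is.null(patch)) return(NA)
    rc <- patch$centerRowcol
    tr <- sceneTransform(pair$epoch1)
    corners <- expand.grid(r = c(rc[1] - 2, rc[1] + 2),
                           c = c(rc[2] - 2, rc[2] + 2))
    all(apply(corners, 1, function(k) {
      xy <- c(tr[1] + (k[2] + 0.5) * tr[3], tr[2] - (k[1] + 0.5) * tr[3])
      pointInPolygon(xy, ring)
    }))
  }, NA)
  inside <- inside[!is.na(inside)]
  expect_gte(mean(inside), 0.95)
})

test_that("every valid patch is nodata-free with its center inside the polygon", {
  cfg <- sceneConfig(gridShape = c(100, 100), nFsc = 60, nodataFrac = 0.08,
                     seed = 17)
  pair <- generateScenePair(cfg)
  for (i in seq_len(length(pair$fsc))) {
    patch <- tryCatch(extractPatch(pair$epoch1, fscGeometry(pair$fsc)[[i]]),
                      error = function(e) NULL)
    if (is.null(patch) || !patch$valid) next
    rc <- patch$centerRowcol
    expect_false(any(nodataMask(pair$epoch1)[(rc[1] - 2):(rc[1] + 2) + 1,
                                             (rc[2] - 2):(rc[2] + 2) + 1]))
    expect_true(patch$centerInside)
    expect_false(anyNA(patch$window))
  }
})
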
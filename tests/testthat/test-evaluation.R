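test_that("confusion counts enumerate reference/prediction pairs", {
  ref <- c("Arbor", "Arbor", "Shrub", "Bare")
  cm <- confusionCounts(ref, ref)
  expect_equal(sum(diag(cm)), 4)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  # construct pairs yielding [[40,10],[5,45]]
  ref2 <- c(rep("A", 50), rep("B", 50))
  pred2 <- c(rep("A", 40), rep("B", 10), rep("A", 5), rep("B", 45))
  cm2 <- confusionCounts(ref2, pred2, classes = c("A", "B"))
  expect_identical(unname(cm2), matrix(c(40L, 10L, 5L, 45L), 2, byrow = TRUE))

  expect_error(confusionCounts(character(), character()), "empty")
  expect_error(confusionCounts(c("A", "B"), "A"), "length")
})

test_that("metrics match the hand evaluation on the toy matrix", {
  cm <- matrix(c(40L, 10L, 5L, 45L), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  m <- classificationMetrics(cm)
  expect_equal(m$OA, 0.85)
  expect_equal(m$Pe, 0.5)
  expect_equal(m$kappa, 0.70)
  # perfect diagonal
  mp <- classificationMetrics(diag(7L, 3))
  expect_equal(mp$OA, 1); expect_equal(mp$kappa, 1); expect_equal(mp$F1, 1)
  # one-class predictor against balanced truth: chance-level kappa
  cm1 <- matrix(c(50L, 0L, 50L, 0L), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(classificationMetrics(cm1)$kappa, 0)
})

test_that("metrics agree with the per-cell oracle on random matrices", {
  set.seed(14)
  for (k in 1:30) {
    cm <- matrix(rpois(25, 12) + diag(5) * rpois(5, 40), 5,
                 dimnames = list(vegClasses(), vegClasses()))
    storage.mode(cm) <- "integer"
    m <- classificationMetrics(cm)
    o <- oracleMetrics(cm)
    expect_equal(m$OA, o$OA, tolerance = 1e-12)
    expect_equal(m$precision, o$precision, tolerance = 1e-12)
    expect_equal(m$recall, o$recall, tolerance = 1e-12)
    expect_equal(m$F1, o$F1, tolerance = 1e-12)
    expect_equal(m$kappa, o$kappa, tolerance = 1e-12)
  }
})

test_that("kappa is 1 only for perfect agreement and 0 under independence", {
  set.seed(15)
  for (k in 1:10) {
    cm <- matrix(rpois(25, 10) + diag(5) * 30L, 5,
                 dimnames = list(vegClasses(), vegClasses()))
    m <- classificationMetrics(cm)
    expect_lt(m$kappa, 1)
    expect_lt(m$OA, 1)
  }
  # independent predictions: kappa near 0 by simulation
  set.seed(16)
  n <- 20000
  ref <- sample(c("A", "B", "C"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  pred <- sample(c("A", "B", "C"), n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  m <- classificationMetrics(confusionCounts(ref, pred, c("A", "B", "C")))
  expect_lt(abs(m$kappa), 0.02)
})

test_that("never-predicted classes get flagged zero precision", {
  cm <- matrix(c(5L, 0L, 3L, 0L), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  m <- classificationMetrics(cm)
  expect_equal(m$perClass$precision[2], 0)
  expect_match(m$flags, "B")
})

test_that("detection accounting conserves the reference set", {
  r <- detectionRate(as.character(1:329), as.character(1:273))
  expect_equal(r$detected, 273)
  expect_equal(r$missed, 56)
  expect_equal(r$rate, 273 / 329)
  expect_equal(r$detected + r$missed, 329)

  full <- detectionRate(c("a", "b"), c("b", "a", "c"))
  expect_equal(full$rate, 1); expect_equal(full$missed, 0)
  none <- detectionRate(c("a", "b"), c("x"))
  expect_equal(none$rate, 0)
  expect_error(detectionRate(character(), "a"), "empty")
})

test_that("NNI matches the lattice closed form and flags coincident points", {
  s <- 10
  g <- expand.grid(x = (0:9) * s, y = (0:9) * s)
  r <- nearestNeighborIndex(as.matrix(g), area = 100 * s^2)
  expect_equal(r$NNI, 2.0, tolerance = 1e-6)
  expect_gt(r$z, 0)

  co <- nearestNeighborIndex(matrix(5, 4, 2), area = 100)
  expect_equal(co$NNI, 0)
  expect_true(attr(co, "degenerate"))
  expect_error(nearestNeighborIndex(matrix(0, 1, 2), 10), "2 points")
})

test_that("uniform random points score near 1 under CSR", {
  inBand <- 0
  for (seed in 1:10) {
    set.seed(seed)
    pts <- cbind(runif(500, 0, 1000), runif(500, 0, 1000))
    r <- nearestNeighborIndex(pts, 1000 * 1000)
    if (r$NNI >= 0.9 && r$NNI <= 1.1) inBand <- inBand + 1
  }
  expect_gte(inBand, 9)
})

test_that("clustered points score well below 1", {
  set.seed(30)
  centers <- cbind(runif(6, 100, 900), runif(6, 100, 900))
  idx <- sample(6, 300, replace = TRUE)
  pts <- centers[idx, ] + matrix(rnorm(600, 0, 12), 300, 2)
  r <- nearestNeighborIndex(pts, 1000 * 1000)
  expect_lt(r$NNI, 0.6)
  expect_lt(r$p, 0.001)
})
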
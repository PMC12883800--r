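test_that("epoch comparison flags exactly the differing units", {
  l1 <- c(a = "Arbor", b = "Shrub", c = "Bamboo")
  rec <- compareEpochs(l1, l1)
  expect_false(any(rec$changed))
  l2 <- l1; l2["a"] <- "Bare"
  rec2 <- compareEpochs(l1, l2)
  expect_equal(sum(rec2$changed), 1)
  expect_identical(rec2$fsc_id[rec2$changed], "a")
  expect_identical(rec2$to_class[rec2$changed], "Bare")
  expect_error(compareEpochs(l1, l2[-1]), "mismatch")
})

test_that("generator ground truth is recovered exactly from oracle labels", {
  pair <- testScenePair(seed = 3)
  labs <- fscLabels(pair$fsc)
  l1 <- setNames(labs$e1, fscIds(pair$fsc))
  l2 <- setNames(labs$e2, fscIds(pair$fsc))
  rec <- compareEpochs(l1, l2)
  expect_equal(sum(rec$changed), round(0.1 * length(pair$fsc)))
})

test_that("transition matrix counts and conserves", {
  rec <- data.frame(fsc_id = c("1", "2", "3"),
                    from_class = c("Arbor", "Shrub", "Arbor"),
                    to_class = c("Shrub", "Arbor", "Arbor"),
                    changed = c(TRUE, TRUE, FALSE))
  tm <- transitionMatrix(rec, classOrder = c("Arbor", "Shrub"))
  expect_identical(unname(transitionCounts(tm)),
                   matrix(c(1L, 1L, 1L, 0L), 2, byrow = TRUE))
  expect_equal(sum(transitionCounts(tm)), nrow(rec))

  same <- data.frame(fsc_id = c("1", "2"), from_class = c("Arbor", "Bare"),
                     to_class = c("Arbor", "Bare"), changed = FALSE)
  tm2 <- transitionMatrix(same)
  expect_equal(sum(transitionCounts(tm2)) , sum(diag(transitionCounts(tm2))))

  bad <- data.frame(fsc_id = "1", from_class = "Lake", to_class = "Arbor",
                    changed = TRUE)
  expect_error(transitionMatrix(bad), "unknown class")
})

test_that("records with missing labels are excluded and reported", {
  rec <- data.frame(fsc_id = c("1", "2"),
                    from_class = c("Arbor", NA),
                    to_class = c("Arbor", "Shrub"),
                    changed = c(FALSE, NA))
  tm <- transitionMatrix(rec)
  expect_equal(sum(transitionCounts(tm)), 1)
  expect_equal(attr(tm, "n_excluded"), 1)
})

test_that("retention and conversion rates follow the row normalization", {
  k <- 3
  idm <- diag(5L, k); dimnames(idm) <- list(LETTERS[1:k], LETTERS[1:k])
  tm <- new("TransitionMatrix", counts = idm, classOrder = LETTERS[1:k],
            epochPair = c("e1", "e2"))
  for (cl in LETTERS[1:k]) expect_equal(retentionRate(tm, cl), 100)

  counts <- matrix(c(8L, 2L, 1L, 9L), 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("A", "B")))
  tm2 <- new("TransitionMatrix", counts = counts, classOrder = c("A", "B"),
             epochPair = c("e1", "e2"))
  expect_equal(retentionRate(tm2, "A"), 80)
  expect_equal(conversionRate(tm2, "A", "B"), 20)
  expect_equal(conversionRate(tm2, "B", "B"), retentionRate(tm2, "B"))
  # retention + all conversions = 100 per class
  expect_equal(retentionRate(tm2, "A") +
                 conversionRate(tm2, "A", "B"), 100)
  expect_equal(conversionRate(tm2, "A", "A"), retentionRate(tm2, "A"))
})

test_that("county-wide printed table reproduces the reported rates", {
  tm <- paperTransitionMatrix("2019_2020")
  expect_equal(sum(transitionCounts(tm)), 340588)
  expect_equal(round(retentionRate(tm, "Arbor"), 2), 99.70)
  expect_equal(round(retentionRate(tm, "Bamboo"), 2), 99.23)
  expect_equal(round(conversionRate(tm, "Bamboo", "Arbor"), 2), 0.18)
  expect_equal(round(conversionRate(tm, "Shrub", "Arbor"), 2), 0.15)
  # row sums equal the study-area class counts
  comp <- read.csv(system.file("extdata", "fsc_composition.csv",
                               package = "fscchange"))
  expect_equal(unname(rowSums(transitionCounts(tm))),
               comp$study_area_count[match(rownames(transitionCounts(tm)),
                                           comp$class)])
})

test_that("change layer export emits one feature per changed unit", {
  pair <- testScenePair(seed = 3)
  labs <- fscLabels(pair$fsc)
  rec <- compareEpochs(setNames(labs$e1, fscIds(pair$fsc)),
                       setNames(labs$e2, fscIds(pair$fsc)))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "chg.geojson")
  exportChangeLayer(rec, pair$fsc, p)
  gj <- jsonlite::read_json(p)
  expect_length(gj$features, sum(rec$changed))
  props <- gj$features[[1]]$properties
  expect_true(all(c("fsc_id", "from_class", "to_class") %in% names(props)))
  # re-read as a layer: geometry round-trips
  back <- readFscLayer(p)
  expect_equal(length(back), sum(rec$changed))

  # zero changes -> empty collection
  rec0 <- rec; rec0$changed <- FALSE
  p0 <- file.path(dir, "none.geojson")
  exportChangeLayer(rec0, pair$fsc, p0)
  expect_length(jsonlite::read_json(p0)$features, 0)
})
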
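# Shared fixtures. Scenes are cached per (seed, size) so several test files
# can reuse one generation.

.sceneCache <- new.env(parent = emptyenv())

testScenePair <- function(seed = 3L, gridShape = c(140L, 140L), nFsc = 220L,
                          changeFraction = 0.1, ...) {
  key <- paste(seed, paste(gridShape, collapse = "x"), nFsc, changeFraction,
               sep = "_")
  if (is.null(.sceneCache[[key]])) {
    cfg <- sceneConfig(gridShape = gridShape, nFsc = nFsc,
                       changeFraction = changeFraction, seed = seed, ...)
    .sceneCache[[key]] <- generateScenePair(cfg)
  }
  .sceneCache[[key]]
}

# five-class Gaussian feature fixture for model-level tests: class means on a
# simplex-like arrangement, unit-ish noise
gaussianClasses <- function(n = 300L, d = 8L, sep = 2.5, seed = 1L,
                            classes = vegClasses()) {
  set.seed(seed)
  k <- length(classes)
  centers <- matrix(stats::rnorm(k * d), k, d) * sep
  y <- sample(classes, n, replace = TRUE)
  X <- centers[match(y, classes), ] + matrix(stats::rnorm(n * d), n, d)
  colnames(X) <- paste0("f", seq_len(d))
  list(X = as.data.frame(X), y = y)
}

# TRUE when the full patch window of a polygon lies inside it (no mixing
# with neighboring units)
windowFullyInside <- function(scene, ring, size = 5L) {
  patch <- tryCatch(extractPatch(scene, ring, size), error = function(e) NULL)
  if (is.null(patch) || !patch$valid) return(FALSE)
  rc <- patch$centerRowcol
  tr <- sceneTransform(scene)
  half <- size %/% 2
  corners <- expand.grid(r = c(rc[1] - half, rc[1] + half),
                         c = c(rc[2] - half, rc[2] + half))
  all(apply(corners, 1, function(k) {
    xy <- c(tr[1] + (k[2] + 0.5) * tr[3], tr[2] - (k[1] + 0.5) * tr[3])
    pointInPolygon(xy, ring)
  }))
}

# brute-force GLCM + metrics oracle: explicit pair enumeration and double
# loops, independent of the vectorized implementation
oracleGlcm <- function(q, levels, distance = 1L,
                       angles = c(0, 45, 90, 135), symmetric = TRUE) {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  P <- matrix(0, levels, levels)
  for (ang in as.character(angles)) {
    dr <- offs[[ang]][1] * distance; dc <- offs[[ang]][2] * distance
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, cc] + 1, q[r2, c2] + 1] <- P[q[r, cc] + 1, q[r2, c2] + 1] + 1
        if (symmetric)
          P[q[r2, c2] + 1, q[r, cc] + 1] <- P[q[r2, c2] + 1, q[r, cc] + 1] + 1
      }
    }
  }
  P / sum(P)
}

oracleTextureMetrics <- function(P) {
  N <- nrow(P)
  MEAN <- 0; HOM <- 0; CON <- 0; DIS <- 0; ENT <- 0; ENE <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) {
    p <- P[i + 1, j + 1]
    MEAN <- MEAN + i * p
    HOM <- HOM + p / (1 + abs(i - j))
    CON <- CON + abs(i - j)^2 * p
    DIS <- DIS + abs(i - j) * p
    if (p > 0) ENT <- ENT - p * log2(p)
    ENE <- ENE + p^2
  }
  VAR <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1))
    VAR <- VAR + (i - MEAN)^2 * P[i + 1, j + 1]
  px <- rowSums(P); py <- colSums(P); lv <- 0:(N - 1)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px)); sy <- sqrt(sum((lv - my)^2 * py))
  COR <- 0
  if (sx * sy > 0) {
    for (i in 0:(N - 1)) for (j in 0:(N - 1))
      COR <- COR + (i - mx) * (j - my) * P[i + 1, j + 1]
    COR <- COR / (sx * sy)
  }
  c(MEAN = MEAN, VAR = VAR, HOM = HOM, CON = CON, DIS = DIS,
    ENT = ENT, ENE = ENE, COR = COR)
}

# per-cell hand computation of the accuracy metrics, independent of
# classificationMetrics()
oracleMetrics <- function(cm) {
  total <- sum(cm); k <- nrow(cm)
  prec <- rec <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]; fp <- sum(cm[, i]) - tp; fn <- sum(cm[i, ]) - tp
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  po <- sum(diag(cm)) / total
  pe <- 0
  for (i in seq_len(k)) pe <- pe + sum(cm[i, ]) * sum(cm[, i])
  pe <- pe / total^2
  list(OA = po, precision = mean(prec), recall = mean(rec), F1 = mean(f1),
       kappa = (po - pe) / (1 - pe), Pe = pe)
}

# printed county-wide transition table (earlier epoch in rows)
paperTransitionMatrix <- function(period = "2019_2020") {
  path <- system.file("extdata", paste0("transitions_", period, ".csv"),
                      package = "fscchange")
  tab <- utils::read.csv(path, check.names = FALSE)
  counts <- as.matrix(tab[, -1])
  rownames(counts) <- tab$from
  storage.mode(counts) <- "integer"
  new("TransitionMatrix", counts = counts, classOrder = rownames(counts),
      epochPair = strsplit(period, "_")[[1]])
}
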
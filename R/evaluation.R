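# Accuracy assessment: confusion matrices, overall accuracy / macro
# precision / recall / F1 / Cohen's kappa, change-detection accounting
# against reference changes, and Clark-Evans nearest-neighbor-index spatial
# clustering of change locations.

#' Confusion matrix of reference vs. predicted labels
#'
#' @param reference,predicted equal-length label vectors; rows of the result
#'   index the reference class, columns the predicted class.
#' @param classes class ordering; defaults to the canonical vegetation order
#'   restricted to observed labels, followed by any other labels sorted.
#' @return Integer K x K matrix with dimnames.
#' @export
confusionCounts <- function(reference, predicted, classes = NULL) {
  if (length(reference) == 0L) stop("empty input")
  if (length(reference) != length(predicted))
    stop("reference and predicted lengths differ")
  if (is.null(classes)) {
    seen <- unique(c(reference, predicted))
    classes <- c(intersect(vegClasses(), seen),
                 sort(setdiff(seen, vegClasses())))
  }
  counts <- table(factor(reference, levels = classes),
                  factor(predicted, levels = classes))
  matrix(as.integer(counts), length(classes),
         dimnames = list(reference = classes, predicted = classes))
}

#' Accuracy metrics from a confusion matrix
#'
#' OA = trace/total. Per-class one-vs-rest precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 their harmonic mean; the reported precision/recall/F1 are
#' unweighted macro averages (averaging = "weighted" weights by reference
#' class frequency). Kappa = (Po - Pe)/(1 - Pe) with Po = trace/total and
#' Pe = sum(row marginal x column marginal)/total^2. A class never predicted
#' (TP+FP = 0) gets precision 0 and is flagged; the macro average still
#' includes it.
#'
#' @param cm confusion matrix from [confusionCounts()].
#' @param averaging "macro" (default) or "weighted".
#' @return list(OA, precision, recall, F1, kappa, perClass, flags).
#' @export
classificationMetrics <- function(cm, averaging = c("macro", "weighted")) {
  averaging <- match.arg(averaging)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  if (is.null(rownames(cm)))
    dimnames(cm) <- list(paste0("class", seq_len(k)),
                         paste0("class", seq_len(k)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  flags <- character()
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  if (any(tp + fp == 0))
    flags <- c(flags, paste0("precision undefined (no predictions) for: ",
                             paste(rownames(cm)[tp + fp == 0], collapse = ", ")))
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- if (averaging == "macro") rep(1 / k, k) else rowSums(cm) / total
  po <- sum(tp) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  list(OA = po,
       precision = sum(w * precision),
       recall = sum(w * recall),
       F1 = sum(w * f1),
       kappa = kappa,
       perClass = data.frame(class = rownames(cm), TP = tp, FP = fp, FN = fn,
                             TN = total - tp - fp - fn,
                             precision = precision, recall = recall, F1 = f1,
                             row.names = NULL, stringsAsFactors = FALSE),
       Po = po, Pe = pe, flags = flags)
}

#' Change-detection accounting against reference changes
#'
#' @param referenceIds ids of reference (field-verified) changed units.
#' @param detectedIds ids of units the algorithm flags as changed.
#' @return list(detected, missed, rate): detected = |reference intersect
#'   detected|, missed = |reference setdiff detected|, rate =
#'   detected/|reference|; detected + missed = |reference| always.
#' @export
detectionRate <- function(referenceIds, detectedIds) {
  referenceIds <- unique(referenceIds)
  if (length(referenceIds) == 0L) stop("undefined rate: empty reference set")
  detected <- length(intersect(referenceIds, detectedIds))
  missed <- length(referenceIds) - detected
  list(detected = detected, missed = missed,
       rate = detected / length(referenceIds))
}

#' Clark-Evans nearest neighbor index
#'
#' NNI = observed mean nearest-neighbor distance / expected distance under
#' complete spatial randomness, with expected = 0.5 sqrt(area/n) and standard
#' error 0.26136 / sqrt(n^2/area); z = (obs - exp)/SE with a two-sided normal
#' p-value. No edge correction. NNI < 1 indicates clustering. All points
#' coincident gives NNI 0 with attribute `degenerate = TRUE`.
#'
#' @param points n x 2 matrix of planar coordinates (meters).
#' @param area study-area extent in m^2.
#' @return list(NNI, z, p, dObs, dExp) with attribute `degenerate` when the
#'   observed mean distance is 0.
#' @export
nearestNeighborIndex <- function(points, area) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  if (area <= 0) stop("area must be positive")
  d2 <- outer(points[, 1], points[, 1], "-")^2 +
    outer(points[, 2], points[, 2], "-")^2
  diag(d2) <- Inf
  dObs <- mean(sqrt(apply(d2, 1, min)))
  dExp <- 0.5 * sqrt(area / n)
  se <- 0.26136 / sqrt(n^2 / area)
  if (dObs == 0) {
    out <- list(NNI = 0, z = -dExp / se,
                p = 2 * stats::pnorm(-abs(-dExp / se)),
                dObs = 0, dExp = dExp)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (dObs - dExp) / se
  list(NNI = dObs / dExp, z = z, p = 2 * stats::pnorm(-abs(z)),
       dObs = dObs, dExp = dExp)
}
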
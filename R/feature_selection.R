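# Grouped feature selection: spectral (raw bands + vegetation indices) and
# texture features are ranked in two independent groups by the gain
# importance of a gradient-boosted tree classifier, then selected by the
# smallest prefix reaching a cumulative contribution threshold.

#' Rank features by gradient-boosting gain within groups
#'
#' Trains one multiclass gradient-boosted model per feature group and ranks
#' the group's features by total gain (summed loss reduction across all
#' splits using the feature). Features never used by a split receive gain 0
#' and rank last. Gains are normalized to sum 1 within each group.
#'
#' @param features data.frame or matrix of numeric features.
#' @param labels class labels (>= 2 distinct values).
#' @param groups named character vector mapping feature name to group (e.g.
#'   "spectral" or "texture"); defaults to one group named "all".
#' @param nrounds,maxDepth,eta boosting hyperparameters (defaults 100, 4,
#'   0.1).
#' @param seed RNG seed for the boosting; results are deterministic under a
#'   fixed seed and single-threaded training.
#' @return Named list of data.frames (one per group) with columns feature,
#'   gain, normalized, cumulative; each of class `ImportanceRanking`.
#' @export
rankByGain <- function(features, labels, groups = NULL,
                       nrounds = 100L, maxDepth = 4L, eta = 0.1, seed = 1L) {
  X <- as.matrix(features)
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  if (is.null(groups)) groups <- stats::setNames(rep("all", ncol(X)), colnames(X))
  y <- as.integer(factor(labels)) - 1L
  out <- list()
  for (g in unique(groups)) {
    cols <- names(groups)[groups == g]
    cols <- intersect(cols, colnames(X))
    if (!length(cols)) stop("group ", g, " has no features")
    set.seed(seed)
    dm <- xgboost::xgb.DMatrix(X[, cols, drop = FALSE], label = y)
    bst <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(unique(y)),
                    max_depth = maxDepth, eta = eta,
                    nthread = 1L, seed = seed),
      data = dm, nrounds = nrounds, verbose = 0)
    imp <- as.data.frame(xgboost::xgb.importance(model = bst))
    gain <- stats::setNames(rep(0, length(cols)), cols)
    if (nrow(imp)) {
      # xgb reports normalized gain; rescale is irrelevant for ranking and we
      # renormalize below anyway
      gain[imp$Feature] <- imp$Gain
    }
    ord <- order(-gain, match(names(gain), cols))
    gain <- gain[ord]
    total <- sum(gain)
    normalized <- if (total > 0) gain / total else rep(1 / length(gain), length(gain))
    rk <- data.frame(feature = names(gain), gain = unname(gain),
                     normalized = unname(normalized),
                     cumulative = cumsum(unname(normalized)),
                     stringsAsFactors = FALSE)
    class(rk) <- c("ImportanceRanking", "data.frame")
    attr(rk, "group") <- g
    out[[g]] <- rk
  }
  out
}

#' Select features by cumulative contribution
#'
#' Returns the smallest prefix of the ranking whose cumulative normalized
#' gain reaches the threshold.
#'
#' @param ranking an `ImportanceRanking` data.frame from [rankByGain()].
#' @param threshold cumulative contribution in (0, 1], default 0.85.
#' @return Character vector of selected feature names.
#' @export
selectByCumulative <- function(ranking, threshold = 0.85) {
  if (is.null(ranking) || nrow(ranking) == 0L) stop("empty ranking")
  stopifnot(threshold > 0, threshold <= 1)
  k <- which(ranking$cumulative >= threshold - 1e-12)[1]
  if (is.na(k)) k <- nrow(ranking)
  ranking$feature[seq_len(k)]
}
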
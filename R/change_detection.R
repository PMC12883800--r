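# Post-classification change detection: per-unit change records, transition
# matrices (rows = earlier epoch, columns = later epoch), retention and
# conversion rates, and export of the changed polygons.

#' Compare class labels between two epochs
#'
#' @param labelsE1,labelsE2 named character vectors (names = fsc ids) or
#'   data.frames with columns fsc_id and label.
#' @return data.frame of change records: fsc_id, from_class, to_class,
#'   changed (TRUE iff from != to).
#' @export
compareEpochs <- function(labelsE1, labelsE2) {
  asNamed <- function(x) {
    if (is.data.frame(x)) stats::setNames(as.character(x$label), x$fsc_id)
    else x
  }
  l1 <- asNamed(labelsE1); l2 <- asNamed(labelsE2)
  m1 <- setdiff(names(l2), names(l1))
  m2 <- setdiff(names(l1), names(l2))
  if (length(m1) || length(m2))
    stop("fsc id mismatch between epochs; missing in epoch 1: ",
         paste(utils::head(m1, 10), collapse = ", "),
         "; missing in epoch 2: ",
         paste(utils::head(m2, 10), collapse = ", "))
  ids <- names(l1)
  data.frame(fsc_id = ids, from_class = unname(l1),
             to_class = unname(l2[ids]),
             changed = unname(l1 != l2[ids]),
             stringsAsFactors = FALSE)
}

#' Transition matrix from change records
#'
#' @param records data.frame from [compareEpochs()]. Records with NA labels
#'   (units unclassified in either epoch) are excluded from the matrix and
#'   counted in attribute `n_excluded`.
#' @param classOrder class label ordering (default [vegClasses()]).
#' @param epochPair character length 2 naming the epochs.
#' @return A [TransitionMatrix-class].
#' @export
transitionMatrix <- function(records, classOrder = vegClasses(),
                             epochPair = c("e1", "e2")) {
  if (nrow(records) == 0L) stop("no change records")
  ok <- !is.na(records$from_class) & !is.na(records$to_class)
  rec <- records[ok, , drop = FALSE]
  bad <- setdiff(unique(c(rec$from_class, rec$to_class)), classOrder)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(rec$from_class, levels = classOrder),
                  factor(rec$to_class, levels = classOrder))
  counts <- matrix(as.integer(counts), length(classOrder),
                   dimnames = list(classOrder, classOrder))
  tm <- new("TransitionMatrix", counts = counts, classOrder = classOrder,
            epochPair = epochPair)
  attr(tm, "n_excluded") <- sum(!ok)
  tm
}

#' Retention rate of a class
#'
#' Percentage of the class's units (earlier epoch) that keep the class:
#' 100 * diagonal / row sum. Unrounded; round only at presentation.
#'
#' @param tm a [TransitionMatrix-class].
#' @param class class label.
#' @return Percentage in `[0, 100]`.
#' @export
retentionRate <- function(tm, class) {
  counts <- tm@counts
  if (!class %in% rownames(counts)) stop("unknown class: ", class)
  rs <- sum(counts[class, ])
  if (rs == 0) stop("undefined retention rate: empty row for ", class)
  100 * counts[class, class] / rs
}

#' Conversion rate between two classes
#'
#' Percentage of `fromClass` units (earlier epoch) that become `toClass`:
#' 100 * counts[from, to] / row sum(from).
#'
#' @param tm a [TransitionMatrix-class].
#' @param fromClass,toClass class labels.
#' @return Percentage in `[0, 100]`.
#' @export
conversionRate <- function(tm, fromClass, toClass) {
  counts <- tm@counts
  if (!fromClass %in% rownames(counts)) stop("unknown class: ", fromClass)
  if (!toClass %in% colnames(counts)) stop("unknown class: ", toClass)
  rs <- sum(counts[fromClass, ])
  if (rs == 0) stop("undefined conversion rate: empty row for ", fromClass)
  100 * counts[fromClass, toClass] / rs
}

#' Export changed sub-compartments as a GeoJSON layer
#'
#' @param records change records from [compareEpochs()].
#' @param fsc the [FSCSet-class] providing geometries.
#' @param path output `.geojson` path.
#' @return `path`, invisibly; the written FeatureCollection has one feature
#'   per changed record, with from/to attributes.
#' @export
exportChangeLayer <- function(records, fsc, path) {
  chg <- records[which(records$changed), , drop = FALSE]
  idx <- match(chg$fsc_id, fsc@fscId)
  if (anyNA(idx)) stop("changed ids missing from the FSC layer: ",
                       paste(chg$fsc_id[is.na(idx)], collapse = ", "))
  feats <- lapply(seq_len(nrow(chg)), function(k) {
    ring <- fsc@geometry[[idx[k]]]
    coords <- rbind(ring, ring[1L, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(coords, row(coords))))),
         properties = list(fsc_id = chg$fsc_id[k],
                           from_class = chg$from_class[k],
                           to_class = chg$to_class[k]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
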
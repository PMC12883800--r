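# Gray-level co-occurrence matrix texture features. Defaults: 32 gray
# levels, offset distance 1, the symmetric 4-angle set (0, 45, 90, 135
# degrees) accumulated into a single normalized matrix. The eight metrics
# follow the standard Haralick-style definitions; entropy is in bits.

#' Quantize a window to integer gray levels
#'
#' Uniform binning between the window minimum and maximum with right-closed
#' intervals, so a value exactly on an interior bin edge maps to the lower
#' level. A constant window maps entirely to level 0.
#'
#' @param window numeric matrix of reflectance.
#' @param levels number of gray levels N (>= 2).
#' @return Integer matrix with values in `0:(levels-1)`.
#' @export
quantizeWindow <- function(window, levels = 32L) {
  stopifnot(levels >= 2L, all(is.finite(window)))
  lo <- min(window); hi <- max(window)
  if (hi - lo <= 0) {
    q <- window; q[] <- 0L; storage.mode(q) <- "integer"
    return(q)
  }
  idx <- ceiling((window - lo) / (hi - lo) * levels) - 1L
  idx[idx < 0L] <- 0L
  idx[idx > levels - 1L] <- levels - 1L
  storage.mode(idx) <- "integer"
  idx
}

.ANGLE_OFFSETS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                       `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Gray-level co-occurrence matrix
#'
#' Accumulates co-occurrence counts over the requested angles at the given
#' pixel distance, symmetrizes (each pair counted in both directions) when
#' `symmetric = TRUE`, and normalizes to sum 1.
#'
#' @param q integer matrix of gray levels in `0:(levels-1)` (see
#'   [quantizeWindow()]).
#' @param levels number of gray levels N.
#' @param distance offset distance in pixels (default 1).
#' @param angles subset of c(0, 45, 90, 135), degrees.
#' @param symmetric count each pair in both directions (default TRUE).
#' @return N x N matrix of class `glcm` summing to 1, with attributes
#'   `levels`, `offsets`, `symmetric`.
#' @export
glcmMatrix <- function(q, levels = 32L, distance = 1L,
                       angles = c(0, 45, 90, 135), symmetric = TRUE) {
  stopifnot(levels >= 2L, nrow(q) >= 1L, ncol(q) >= 1L)
  if (max(nrow(q), ncol(q)) <= distance)
    stop("window smaller than the offset distance")
  P <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  nPairs <- 0L
  for (ang in as.character(angles)) {
    off <- .ANGLE_OFFSETS[[ang]]
    if (is.null(off)) stop("unsupported angle: ", ang)
    dr <- off[1] * distance; dc <- off[2] * distance
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(r1) < 1L || length(c1) < 1L) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ij <- cbind(as.vector(a) + 1L, as.vector(b) + 1L)
    tab <- table(factor(ij[, 1], levels = seq_len(levels)),
                 factor(ij[, 2], levels = seq_len(levels)))
    P <- P + unclass(tab)
    nPairs <- nPairs + nrow(ij)
  }
  if (nPairs == 0L) stop("no co-occurring pixel pairs for these offsets")
  if (symmetric) P <- P + t(P)
  P <- P / sum(P)
  structure(P, class = c("glcm", "matrix"),
            levels = levels, offsets = list(distance = distance, angles = angles),
            symmetric = symmetric)
}

#' Texture metrics of a normalized GLCM
#'
#' MEAN = sum i P(i,j); VAR = sum (i - MEAN)^2 P(i,j);
#' HOM = sum P(i,j)/(1+|i-j|); CON = sum |i-j|^2 P(i,j);
#' DIS = sum |i-j| P(i,j); ENT = -sum P log2 P (0 log 0 = 0);
#' ENE = sum P^2; COR = sum (i - mx)(j - my) P / (sx sy), with mx, my, sx, sy
#' the row/column marginal means and standard deviations. Gray levels i, j
#' are 0-based. When sx*sy = 0 the correlation is reported as 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param P normalized GLCM (matrix summing to 1).
#' @return Named numeric vector MEAN, VAR, HOM, CON, DIS, ENT, ENE, COR, with
#'   attribute `marginals` carrying mx, my, sx, sy.
#' @export
textureMetrics <- function(P) {
  N <- nrow(P)
  stopifnot(ncol(P) == N, abs(sum(P) - 1) < 1e-9)
  i <- matrix(rep(0:(N - 1L), N), N, N)        # row index
  j <- t(i)                                    # column index
  adiff <- abs(i - j)
  MEAN <- sum(i * P)
  VAR <- sum((i - MEAN)^2 * P)
  HOM <- sum(P / (1 + adiff))
  CON <- sum(adiff^2 * P)
  DIS <- sum(adiff * P)
  pos <- P > 0
  ENT <- -sum(P[pos] * log2(P[pos]))
  ENE <- sum(P^2)
  px <- rowSums(P); py <- colSums(P)
  lv <- 0:(N - 1L)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px)); sy <- sqrt(sum((lv - my)^2 * py))
  degenerate <- sx * sy <= 0
  COR <- if (degenerate) 0 else sum((i - mx) * (j - my) * P) / (sx * sy)
  out <- c(MEAN = MEAN, VAR = VAR, HOM = HOM, CON = CON,
           DIS = DIS, ENT = ENT, ENE = ENE, COR = COR)
  attr(out, "marginals") <- c(mx = mx, my = my, sx = sx, sy = sy)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}
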
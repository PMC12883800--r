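# Planar polygon utilities used by the scene generator, the vector reader and
# the patch extractor. Polygons are closed rings given as n x 2 matrices of
# map coordinates (first vertex NOT repeated at the end); vertex order may be
# clockwise or counter-clockwise.

#' Polygon area by the shoelace formula
#'
#' @param ring numeric matrix with columns x, y; vertices of a simple polygon,
#'   not closed (first vertex listed once).
#' @return Absolute area in squared map units.
#' @export
polygonArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Polygon geometric centroid
#'
#' Standard area-weighted centroid of a simple polygon. For a concave polygon
#' the centroid may fall outside the ring; see [interiorPoint()].
#'
#' @inheritParams polygonArea
#' @return Length-2 numeric (x, y).
#' @export
polygonCentroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-300) return(c(mean(x), mean(y)))  # degenerate: vertex mean
  cx <- sum((x + x[j]) * cross) / (6 * a)
  cy <- sum((y + y[j]) * cross) / (6 * a)
  c(cx, cy)
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param pt length-2 numeric (x, y).
#' @inheritParams polygonArea
#' @return TRUE if the point is strictly inside or on the boundary.
#' @export
pointInPolygon <- function(pt, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  px <- pt[1]; py <- pt[2]
  # boundary counts as inside: check distance to each segment
  dx <- x - x[j]; dy <- y - y[j]
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, pmin(1, pmax(0, ((px - x[j]) * dx + (py - y[j]) * dy) / len2)), 0)
  d2 <- (x[j] + t * dx - px)^2 + (y[j] + t * dy - py)^2
  if (min(d2) < 1e-18) return(TRUE)
  crossings <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(crossings) %% 2L == 1L
}

#' Guaranteed-interior representative point
#'
#' Returns the geometric centroid when it lies inside the ring; otherwise a
#' point on the horizontal line through the ring's vertical midpoint, at the
#' middle of the widest interior span (always inside for a simple polygon).
#'
#' @inheritParams polygonArea
#' @return Length-2 numeric (x, y) strictly inside the polygon.
#' @export
interiorPoint <- function(ring) {
  if (nrow(ring) < 3L) stop("empty or degenerate geometry")
  cen <- polygonCentroid(ring)
  if (pointInPolygon(cen, ring)) return(cen)
  ys <- sort(unique(ring[, 2]))
  ymid <- (min(ys) + max(ys)) / 2
  # avoid scanline through a vertex
  if (any(abs(ring[, 2] - ymid) < 1e-12)) {
    gaps <- ys[-1] - ys[-length(ys)]
    k <- which.max(gaps)
    ymid <- (ys[k] + ys[k + 1L]) / 2
  }
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  hit <- (y > ymid) != (y[j] > ymid)
  xs <- sort((x[j][hit] - x[hit]) * (ymid - y[hit]) / (y[j][hit] - y[hit]) + x[hit])
  spans <- matrix(xs, ncol = 2, byrow = TRUE)
  widths <- spans[, 2] - spans[, 1]
  k <- which.max(widths)
  c(mean(spans[k, ]), ymid)
}

# TRUE when segments p1-p2 and p3-p4 properly intersect (cross in their
# interiors). Shared endpoints do not count.
.segmentsCross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Test a ring for self-intersection
#'
#' Brute-force check of all non-adjacent edge pairs; adequate for the modest
#' vertex counts of sub-compartment polygons.
#'
#' @inheritParams polygonArea
#' @return TRUE if any two non-adjacent edges properly cross (a "bowtie").
#' @export
isSelfIntersecting <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(FALSE)
  v <- rbind(ring, ring[1L, , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    for (k in seq(i + 2L, n)) {
      if (i == 1L && k == n) next  # adjacent through the closure
      if (.segmentsCross(v[i, ], v[i + 1L, ], v[k, ], v[k + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

# Clip a convex ring with the half-plane of points closer to a than to b
# (Sutherland-Hodgman against the perpendicular bisector). Returns a matrix,
# possibly with 0 rows.
.clipHalfplane <- function(ring, a, b) {
  m <- (a + b) / 2
  d <- b - a
  val <- (ring[, 1] - m[1]) * d[1] + (ring[, 2] - m[2]) * d[2]  # <= 0 kept
  n <- nrow(ring)
  if (all(val <= 0)) return(ring)
  if (all(val > 0)) return(ring[0, , drop = FALSE])
  out <- matrix(0, n + 4L, 2L)
  cnt <- 0L
  for (i in seq_len(n)) {
    k <- if (i == n) 1L else i + 1L
    vi <- val[i]; vk <- val[k]
    if (vi <= 0) { cnt <- cnt + 1L; out[cnt, ] <- ring[i, ] }
    if ((vi <= 0) != (vk <= 0)) {
      t <- vi / (vi - vk)
      cnt <- cnt + 1L
      out[cnt, ] <- ring[i, ] + t * (ring[k, ] - ring[i, ])
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

#' Voronoi tessellation of a rectangle
#'
#' Computes the Voronoi cell of every seed point clipped to the bounding
#' rectangle, by iterative half-plane clipping against perpendicular
#' bisectors. Neighbors are visited in order of distance and clipping stops
#' once no remaining seed can cut the cell, so the cost stays near-linear per
#' cell for well-spread seeds.
#'
#' @param seeds n x 2 matrix of seed coordinates, all inside the rectangle.
#' @param bbox numeric length 4: (xmin, ymin, xmax, ymax).
#' @return List of n rings (matrices with columns x, y).
#' @export
voronoiCells <- function(seeds, bbox) {
  n <- nrow(seeds)
  rect <- rbind(c(bbox[1], bbox[2]), c(bbox[3], bbox[2]),
                c(bbox[3], bbox[4]), c(bbox[1], bbox[4]))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    p <- seeds[i, ]
    d2 <- (seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2
    ord <- order(d2)
    cell <- rect
    for (j in ord) {
      if (j == i) next
      dj <- sqrt(d2[j])
      if (dj == 0) next  # coincident seed: leave to the other cell
      rmax2 <- max((cell[, 1] - p[1])^2 + (cell[, 2] - p[2])^2)
      if ((dj / 2)^2 > rmax2) break  # bisector cannot reach the cell
      cell <- .clipHalfplane(cell, p, seeds[j, ])
      if (nrow(cell) == 0L) break
    }
    cells[[i]] <- cell
  }
  cells
}
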
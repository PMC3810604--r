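#' Polygon area by the shoelace formula
#'
#' Absolute (orientation-independent) area in squared pixel units. For
#' self-intersecting polygons this is the absolute signed area, which only
#' approximates the even-odd rasterized area; annotation polygons are
#' accepted as drawn.
#'
#' @param p a polygon ([polygon_coords()] or an n x 2 matrix, n >= 3).
#' @return non-negative numeric scalar.
#' @export
polygon_area <- function(p) {
  if (!is.matrix(p) || nrow(p) < 3) stop("polygon_area needs >= 3 vertices")
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Bounding-box center of a polygon
#'
#' The midpoint of the vertex bounding box,
#' `((xmin + xmax) / 2, (ymin + ymax) / 2)`, used as the "center" of every
#' object throughout the spatial statistics.
#'
#' @param p matrix of vertices (>= 1 row).
#' @return numeric length-2 vector `c(x, y)` in pixels.
#' @export
object_bbox_center <- function(p) {
  if (!is.matrix(p) || nrow(p) < 1) stop("need at least one vertex")
  c(x = (min(p[, 1]) + max(p[, 1])) / 2,
    y = (min(p[, 2]) + max(p[, 2])) / 2)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# Points exactly on an edge are resolved by the half-open crossing rule.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterize one polygon onto a grid of nx x ny cells covering
# [0, width] x [0, height]; returns a logical matrix (rows = y, cols = x)
# of cells whose center falls inside the polygon (even-odd rule).
polygon_raster_mask <- function(poly, width, height, nx, ny) {
  cx <- (seq_len(nx) - 0.5) * width / nx
  cy <- (seq_len(ny) - 0.5) * height / ny
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  ix <- which(cx >= xr[1] & cx <= xr[2])
  iy <- which(cy >= yr[1] & cy <= yr[2])
  if (!length(ix) || !length(iy)) return(mask)
  g <- expand.grid(x = cx[ix], y = cy[iy])
  inside <- points_in_polygon(g$x, g$y, poly)
  mask[iy, ix] <- matrix(inside, nrow = length(iy), byrow = TRUE)
  mask
}

#' Fraction of image pixels covered by at least one labeled polygon
#'
#' Measures annotation completeness: the fraction of pixel centers falling
#' inside the union of all object polygons (overlapping polygons counted
#' once). Pixel centers are taken on the native image grid at
#' `(i - 0.5, j - 0.5)`, membership by the even-odd rule.
#'
#' @param scene a [scene_annotation()] with known positive dimensions.
#' @return numeric in `[0, 1]`.
#' @export
label_coverage <- function(scene) {
  w <- as.integer(round(scene$width)); h <- as.integer(round(scene$height))
  if (w <= 0 || h <= 0) stop("zero-area image")
  if (!length(scene$objects)) return(0)
  covered <- matrix(FALSE, nrow = h, ncol = w)
  for (obj in scene$objects) {
    covered <- covered | polygon_raster_mask(obj$polygon, w, h, w, h)
  }
  sum(covered) / (w * h)
}
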
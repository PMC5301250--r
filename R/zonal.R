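#' Polygon helpers
#'
#' Polygons are plain two-column matrices of vertex coordinates (x, y),
#' open ring (the closing edge back to the first vertex is implicit).
#' \code{rect_poly} builds the axis-aligned rectangle used throughout the
#' synthetic scenes.
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return A 4 x 2 vertex matrix (counter-clockwise).
#' @export
rect_poly <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

check_polygon <- function(poly) {
  if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L)
    stop("polygon must be a matrix of >= 3 (x, y) vertices")
  if (!all(is.finite(poly))) stop("polygon has non-finite coordinates")
  n <- nrow(poly)
  # drop an explicitly closed ring
  if (n > 3L && all(poly[1L, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  storage.mode(poly) <- "double"
  # proper self-intersection check (edges are few: PA outlines, not coastlines)
  seg <- cbind(poly, poly[c(2:n, 1L), , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next   # closing edge shares vertex 1
      if (segments_cross(seg[i, ], seg[j, ])) stop("polygon self-intersects")
    }
  }
  if (abs(polygon_area(poly)) <= 0) stop("polygon has zero area")
  poly
}

segments_cross <- function(a, b) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Shoelace area of a polygon
#' @param poly two-column vertex matrix.
#' @return Signed area in squared map units (positive if counter-clockwise).
#' @export
polygon_area <- function(poly) {
  x <- as.numeric(poly[, 1]); y <- as.numeric(poly[, 2])
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised crossing-number test. The half-open convention falls out of
#' the strict inequalities: for an axis-aligned rectangle a point on the
#' left or bottom edge is inside, on the right or top edge outside, so a
#' partition of the plane into rectangles assigns every point exactly once.
#'
#' @param px,py point coordinates (equal-length vectors).
#' @param poly two-column vertex matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- (yi > py) != (yj > py)
    xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
    hit <- crosses & (px < xint)      # FALSE & NA == FALSE where edge is flat
    inside <- xor(inside, hit & !is.na(hit))
    j <- i
  }
  inside
}

# row/col index ranges of grid cells whose centre could fall in a bbox
zone_window <- function(g, poly) {
  ext <- grid_extent(g)
  bx <- range(poly[, 1]); by <- range(poly[, 2])
  if (bx[1] >= ext["xmax"] || bx[2] <= ext["xmin"] ||
      by[1] >= ext["ymax"] || by[2] <= ext["ymin"]) return(NULL)
  cols <- seq_len(ncol(g$values))
  rows <- seq_len(nrow(g$values))
  cx <- grid_x_centers(g); cy <- grid_y_centers(g)
  cols <- cols[cx > bx[1] - g$px & cx < bx[2] + g$px]
  rows <- rows[cy > by[1] - g$px & cy < by[2] + g$px]
  if (!length(cols) || !length(rows)) return(NULL)
  list(rows = rows, cols = cols)
}

# linear cell indices of g whose centre lies inside poly
zone_cells <- function(g, poly) {
  w <- zone_window(g, poly)
  if (is.null(w)) return(integer(0))
  cx <- grid_x_centers(g)[w$cols]
  cy <- grid_y_centers(g)[w$rows]
  pts <- expand.grid(row = w$rows, col = w$cols, KEEP.OUT.ATTRS = FALSE)
  inside <- point_in_polygon(rep(cx, each = length(w$rows)),
                             rep(cy, times = length(w$cols)), poly)
  idx <- (pts$col[inside] - 1L) * nrow(g$values) + pts$row[inside]
  idx
}

#' Zonal statistics of a raster over a polygon
#'
#' A pixel belongs to the zone iff its centre lies inside the polygon
#' (see \code{\link{point_in_polygon}} for the deterministic boundary
#' rule). Statistics are computed over zone pixels excluding no-data; a
#' polygon disjoint from the grid gives a zero-count result, not an error.
#'
#' @param g a \code{pa_grid}.
#' @param poly two-column vertex matrix (validated).
#' @param predicate optional function of cell values returning a logical
#'   vector, e.g. \code{function(v) v %in% 1:8} for forest classes; its
#'   matches are counted in \code{pred_count}.
#' @return A list of class \code{zonal_result}: \code{count} (valid zone
#'   pixels), \code{pred_count}, \code{mean}, \code{sum}, \code{area}
#'   (count x pixel area; map units squared). \code{mean} is \code{NA}
#'   when the zone holds no valid pixel, never 0.
#' @export
zonal_stats <- function(g, poly, predicate = NULL) {
  stopifnot(inherits(g, "pa_grid"))
  poly <- check_polygon(poly)
  idx <- zone_cells(g, poly)
  v <- g$values[idx]
  keep <- !is_nodata(g, v)
  v <- v[keep]
  n <- length(v)
  pc <- if (is.null(predicate)) NA_integer_ else sum(predicate(v))
  structure(list(count = n,
                 pred_count = pc,
                 mean = if (n > 0) mean(v) else NA_real_,
                 sum = if (n > 0) sum(v) else 0,
                 area = n * g$px^2),
            class = "zonal_result")
}

#' @export
print.zonal_result <- function(x, ...) {
  cat(sprintf("<zonal_result> count %d, mean %s, sum %g, area %g\n",
              x$count, format(x$mean), x$sum, x$area))
  invisible(x)
}
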
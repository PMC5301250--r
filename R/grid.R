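#' Planar raster grid
#'
#' A minimal in-memory raster: a numeric matrix anchored to a planar
#' equal-area frame by its upper-left corner and a square pixel size.
#' Row 1 of the matrix is the northernmost row. Three kinds are
#' distinguished: \code{"categorical"} (integer class codes, e.g. land
#' cover), \code{"continuous"} (e.g. biomass in Mg ha^-1) and
#' \code{"fraction"} (values constrained to [0, 1], e.g. proportion of a
#' pixel deforested).
#'
#' @param values numeric matrix; row 1 is the top (maximum y) row.
#' @param origin numeric length-2, x and y of the upper-left corner.
#' @param px pixel edge length (> 0); pixels are square.
#' @param kind one of \code{"categorical"}, \code{"continuous"},
#'   \code{"fraction"}.
#' @param nodata value marking missing cells (compared with \code{==});
#'   \code{NA} cells are always treated as missing.
#' @return An object of class \code{pa_grid}.
#' @examples
#' g <- pa_grid(matrix(1:12, 3, 4), origin = c(0, 3000), px = 1000,
#'              kind = "categorical")
#' dim(g$values)
#' @export
pa_grid <- function(values, origin = c(0, nrow(values) * px), px = 1,
                    kind = c("continuous", "categorical", "fraction"),
                    nodata = NA_real_) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one cell")
  if (!is.numeric(px) || length(px) != 1L || !is.finite(px) || px <= 0)
    stop("pixel size must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("'origin' must be two finite coordinates (upper-left corner)")
  g <- structure(list(values = values, origin = as.numeric(origin),
                      px = as.numeric(px), kind = kind, nodata = nodata),
                 class = "pa_grid")
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  v <- valid_values(g)
  if (g$kind == "categorical" && any(v != round(v)))
    stop("categorical grid holds non-integer values")
  if (g$kind == "fraction" && length(v) && (min(v) < 0 || max(v) > 1))
    stop("fraction grid holds values outside [0, 1]")
  invisible(g)
}

#' @export
print.pa_grid <- function(x, ...) {
  v <- valid_values(x)
  cat(sprintf("<pa_grid> %d x %d px @ %g (%s)\n",
              nrow(x$values), ncol(x$values), x$px, x$kind))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]\n",
              x$origin[1], x$origin[1] + ncol(x$values) * x$px,
              x$origin[2] - nrow(x$values) * x$px, x$origin[2]))
  if (length(v))
    cat(sprintf("  values: min %g, max %g (%d valid cells)\n",
                min(v), max(v), length(v)))
  invisible(x)
}

#' @export
plot.pa_grid <- function(x, main = NULL, ...) {
  m <- x$values
  m[is_nodata(x, m)] <- NA
  # image() wants x ascending and the matrix transposed
  graphics::image(x = grid_x_centers(x), y = rev(grid_y_centers(x)),
                  z = t(m[nrow(m):1, , drop = FALSE]),
                  asp = 1, xlab = "x", ylab = "y",
                  main = main %||% x$kind, useRaster = TRUE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_nodata <- function(g, v = g$values) {
  if (is.na(g$nodata)) is.na(v) else (is.na(v) | v == g$nodata)
}

valid_values <- function(g) {
  v <- g$values
  v[!is_nodata(g, v)]
}

grid_x_centers <- function(g) g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$px

grid_y_centers <- function(g) g$origin[2] - (seq_len(nrow(g$values)) - 0.5) * g$px

grid_extent <- function(g) {
  c(xmin = g$origin[1], xmax = g$origin[1] + ncol(g$values) * g$px,
    ymin = g$origin[2] - nrow(g$values) * g$px, ymax = g$origin[2])
}

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text raster interchange (the classic Arc/Info ASCII grid): a
#' six-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows of values, northernmost row first.
#' The grid kind is not part of the format and must be supplied on read.
#'
#' @param g a \code{pa_grid}.
#' @param path file path, conventionally with extension \code{.asc}.
#' @param kind,nodata grid metadata to attach on read.
#' @return \code{write_ascii_grid} returns \code{path} invisibly;
#'   \code{read_ascii_grid} returns a \code{pa_grid}.
#' @export
write_ascii_grid <- function(g, path) {
  stopifnot(inherits(g, "pa_grid"))
  nodata <- if (is.na(g$nodata)) -9999 else g$nodata
  m <- g$values
  m[is_nodata(g, m)] <- nodata
  ext <- grid_extent(g)
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", ext["xmin"]),
           sprintf("yllcorner %.10g", ext["ymin"]),
           sprintf("cellsize %.10g", g$px),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(m, 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, kind = "continuous", nodata = NULL) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d x %d",
                 length(body), nr, nc))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  nd <- nodata %||% unname(vals["nodata_value"])
  if (is.na(nd)) nd <- NA_real_
  pa_grid(m, origin = c(vals[["xllcorner"]],
                        vals[["yllcorner"]] + nr * vals[["cellsize"]]),
          px = vals[["cellsize"]], kind = kind, nodata = nd)
}
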
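#' Nearest-neighbour resampling
#'
#' Regrids a raster to a new pixel size over the same origin: every output
#' cell takes the input value at the output cell's centre, so the value set
#' never changes (class codes and biomass densities are preserved, merely
#' re-gridded). Output cells whose centre falls outside the input extent
#' are set to no-data.
#'
#' @param g a \code{pa_grid}.
#' @param target_px output pixel size (> 0).
#' @return A \code{pa_grid} of the same kind at the new resolution.
#' @examples
#' g <- pa_grid(matrix(1:4, 2, 2), px = 1000, kind = "categorical")
#' resample_nearest(g, 250)$px
#' @export
resample_nearest <- function(g, target_px) {
  stopifnot(inherits(g, "pa_grid"))
  if (!is.numeric(target_px) || length(target_px) != 1L ||
      !is.finite(target_px) || target_px <= 0)
    stop("target pixel size must be a single positive number")
  nr_in <- nrow(g$values); nc_in <- ncol(g$values)
  w <- nc_in * g$px; h <- nr_in * g$px
  nc_out <- max(1L, ceiling(w / target_px - 1e-9))
  nr_out <- max(1L, ceiling(h / target_px - 1e-9))
  # input row/col containing each output cell centre
  cx <- (seq_len(nc_out) - 0.5) * target_px
  cy <- (seq_len(nr_out) - 0.5) * target_px   # measured down from the top
  col_in <- floor(cx / g$px) + 1L
  row_in <- floor(cy / g$px) + 1L
  ok_c <- col_in >= 1L & col_in <= nc_in
  ok_r <- row_in >= 1L & row_in <= nr_in
  out <- matrix(if (is.na(g$nodata)) NA_real_ else g$nodata, nr_out, nc_out)
  out[ok_r, ok_c] <- g$values[row_in[ok_r], col_in[ok_c], drop = FALSE]
  pa_grid(out, origin = g$origin, px = target_px, kind = g$kind,
          nodata = g$nodata)
}

#' Area-averaging aggregation of a binary raster to fractions
#'
#' Collapses a fine binary raster (e.g. 30 m forest-loss cells) to a
#' coarser grid whose cells hold the arithmetic mean of their
#' \code{factor} x \code{factor} block, i.e. the proportion of the coarse
#' pixel that is 1. If the fine dimensions are not divisible by
#' \code{factor} the grid is padded with zeros on the right/bottom and the
#' result carries attribute \code{padded = TRUE}.
#'
#' @param g a binary (0/1, no missing cells) \code{pa_grid}.
#' @param factor integer block edge (>= 1).
#' @return A \code{pa_grid} of kind \code{"fraction"} with pixel size
#'   \code{g$px * factor}.
#' @examples
#' fine <- pa_grid(matrix(c(1, 1, 0, 0), 2, 2), px = 30, kind = "categorical")
#' aggregate_fraction(fine, 2)$values
#' @export
aggregate_fraction <- function(g, factor) {
  stopifnot(inherits(g, "pa_grid"))
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != round(factor))
    stop("'factor' must be a single integer >= 1")
  factor <- as.integer(factor)
  m <- g$values
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("input is not binary: value %s at cell %d",
                 format(m[bad[1]]), bad[1]))
  nr <- nrow(m); nc <- ncol(m)
  padded <- (nr %% factor != 0L) || (nc %% factor != 0L)
  if (padded) {
    nr2 <- ceiling(nr / factor) * factor
    nc2 <- ceiling(nc / factor) * factor
    m2 <- matrix(0, nr2, nc2)
    m2[seq_len(nr), seq_len(nc)] <- m
    m <- m2; nr <- nr2; nc <- nc2
  }
  rg <- rep(seq_len(nr %/% factor), each = factor)
  cg <- rep(seq_len(nc %/% factor), each = factor)
  s <- rowsum(m, rg, reorder = FALSE)
  s <- t(rowsum(t(s), cg, reorder = FALSE))
  dimnames(s) <- NULL
  out <- pa_grid(s / factor^2, origin = g$origin, px = g$px * factor,
                 kind = "fraction", nodata = NA_real_)
  attr(out, "padded") <- padded
  out
}
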
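#' Grid specification for raster layers
#'
#' Defines the shared geometry of all per-ROI raster layers: a regular grid in
#' projected metres with square cells. The companion coarse grid (biomass at
#' 500 m-analog resolution, fire and land-cover stacks) is obtained by grouping
#' `coarse_factor` x `coarse_factor` fine cells into one block, so the fine
#' grid must nest exactly into the coarse one.
#'
#' @param n_rows,n_cols Grid dimensions (fine resolution), positive integers.
#' @param cell_size Cell edge length in metres.
#' @param origin Numeric length-2, projected (x, y) of the top-left corner.
#' @param coarse_factor Integer ratio of coarse to fine cell size (>= 1).
#'   `n_rows` and `n_cols` must be exact multiples.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(64, 64, 30, coarse_factor = 16)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, origin = c(0, 0),
                      coarse_factor = 1L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  coarse_factor <- as.integer(coarse_factor)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (coarse_factor < 1L) stop("coarse_factor must be >= 1")
  if (n_rows %% coarse_factor != 0L || n_cols %% coarse_factor != 0L)
    stop("fine grid dimensions must be exact multiples of coarse_factor")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 origin = as.numeric(origin), coarse_factor = coarse_factor),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (coarse_factor %d)\n",
              x$n_rows, x$n_cols, x$cell_size, x$coarse_factor))
  invisible(x)
}

#' Area of one grid cell in km^2
#'
#' @param spec A [grid_spec()].
#' @param coarse If `TRUE`, area of one coarse block instead of one fine cell.
#' @return Cell area in km^2.
#' @export
cell_area_km2 <- function(spec, coarse = FALSE) {
  s <- spec$cell_size * if (coarse) spec$coarse_factor else 1L
  (s / 1000)^2
}

#' Derive the nested coarse grid of a fine grid
#'
#' @param spec A fine [grid_spec()].
#' @return A `grid_spec` for the coarse grid (coarse_factor 1).
#' @export
coarse_spec <- function(spec) {
  grid_spec(spec$n_rows %/% spec$coarse_factor,
            spec$n_cols %/% spec$coarse_factor,
            spec$cell_size * spec$coarse_factor,
            spec$origin, 1L)
}

#' Raster layer on a grid
#'
#' A thin container pairing a numeric matrix with its [grid_spec()] and a
#' units tag. `NA` entries are nodata.
#'
#' @param values Numeric matrix, `n_rows x n_cols` of `spec`.
#' @param spec The [grid_spec()] the values live on.
#' @param units Character units tag (e.g. `"Mg/ha"`, `"people/km2"`).
#' @return An object of class `ece_raster`.
#' @export
raster_layer <- function(values, spec, units = "") {
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_rows, spec$n_cols)))
    stop("values dimensions do not match grid spec")
  structure(list(values = values, spec = spec, units = units),
            class = "ece_raster")
}

#' @export
print.ece_raster <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<ece_raster> %d x %d [%s] range %.4g..%.4g (%d nodata)\n",
              x$spec$n_rows, x$spec$n_cols, x$units, rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

raster_values <- function(x) if (inherits(x, "ece_raster")) x$values else x

#' Check that one grid nests exactly into another
#'
#' Grid `fine` nests into `coarse` when they share an origin and the coarse
#' cell size is an integer multiple of the fine cell size covering the same
#' extent.
#'
#' @param fine,coarse Two [grid_spec()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
grids_nested <- function(fine, coarse) {
  r <- coarse$cell_size / fine$cell_size
  isTRUE(all.equal(fine$origin, coarse$origin)) &&
    abs(r - round(r)) < 1e-9 && round(r) >= 1 &&
    fine$n_rows == coarse$n_rows * round(r) &&
    fine$n_cols == coarse$n_cols * round(r)
}

#' Block index of each fine cell within the coarse grid
#'
#' @param spec Fine [grid_spec()].
#' @param factor Integer block edge in fine cells; defaults to
#'   `spec$coarse_factor`.
#' @return Integer matrix of 1-based coarse block ids (column-major over the
#'   coarse grid), same shape as the fine grid.
#' @export
block_index <- function(spec, factor = spec$coarse_factor) {
  factor <- as.integer(factor)
  br <- (seq_len(spec$n_rows) - 1L) %/% factor      # 0-based coarse row
  bc <- (seq_len(spec$n_cols) - 1L) %/% factor
  ncr <- ceiling(spec$n_rows / factor)
  outer(br, bc, function(i, j) i + j * ncr + 1L)
}

#' Aggregate a fine raster to its coarse grid by block means
#'
#' @param x An `ece_raster` on a fine grid with `coarse_factor > 1`, or a
#'   matrix (then `factor` is required).
#' @param factor Block edge in fine cells.
#' @param na.rm Drop nodata cells from the block mean.
#' @return An `ece_raster` on the coarse grid (matrix input returns a matrix).
#' @export
block_average <- function(x, factor = NULL, na.rm = TRUE) {
  is_layer <- inherits(x, "ece_raster")
  v <- raster_values(x)
  if (is.null(factor)) {
    if (!is_layer) stop("factor required for matrix input")
    factor <- x$spec$coarse_factor
  }
  factor <- as.integer(factor)
  if (nrow(v) %% factor != 0L || ncol(v) %% factor != 0L)
    stop("matrix dimensions must be multiples of factor")
  nr <- nrow(v) %/% factor; nc <- ncol(v) %/% factor
  ri <- (seq_len(nrow(v)) - 1L) %/% factor            # 0-based block row/col
  ci <- (seq_len(ncol(v)) - 1L) %/% factor
  gid <- ri[row(v)] + ci[col(v)] * nr + 1L            # column-major block id
  vv <- as.vector(v)
  keep <- if (na.rm) !is.na(vv) else rep(TRUE, length(vv))
  sums <- rowsum(vv[keep], gid[keep])
  cnts <- rowsum(rep(1, sum(keep)), gid[keep])
  m <- matrix(NA_real_, nr, nc)
  m[as.integer(rownames(sums))] <- sums / cnts
  if (!is_layer) return(m)
  raster_layer(m, coarse_spec(x$spec), units = x$units)
}

#' Expand a coarse raster to a fine grid by containing-block lookup
#'
#' Each fine cell receives the value of the coarse block that contains it
#' (nearest-block lookup, no interpolation) -- appropriate for probabilities
#' and categorical layers which are not interpolatable.
#'
#' @param coarse An `ece_raster` on the coarse grid, or a matrix.
#' @param fine_spec Target fine [grid_spec()]; must nest into the coarse grid.
#' @return An `ece_raster` on `fine_spec` (matrix in, matrix out).
#' @export
block_lookup <- function(coarse, fine_spec) {
  v <- raster_values(coarse)
  if (inherits(coarse, "ece_raster") &&
      !grids_nested(fine_spec, coarse$spec))
    stop("fine grid does not nest into the coarse grid")
  f1 <- fine_spec$n_rows / nrow(v); f2 <- fine_spec$n_cols / ncol(v)
  if (f1 != round(f1) || f1 != f2)
    stop("fine grid does not nest into the coarse grid")
  f <- as.integer(round(f1))
  out <- v[(seq_len(fine_spec$n_rows) - 1L) %/% f + 1L,
           (seq_len(fine_spec$n_cols) - 1L) %/% f + 1L, drop = FALSE]
  if (!inherits(coarse, "ece_raster")) return(out)
  raster_layer(out, fine_spec, units = coarse$units)
}
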
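#' Belowground biomass from aboveground biomass (allometric)
#'
#' Tropical-forest allometric relation `BGB = 0.489 * AGB^0.89`, applied on a
#' per-area density basis (Mg/ha in, Mg/ha out).
#'
#' @param agb Aboveground biomass density, Mg/ha. Non-negative.
#' @return Belowground biomass density, Mg/ha.
#' @examples
#' bgb_allometric(1)    # 0.489
#' @export
bgb_allometric <- function(agb) {
  if (any(agb < 0, na.rm = TRUE)) stop("agb must be non-negative")
  0.489 * agb^0.89
}

#' Convert aboveground biomass density to total carbon density
#'
#' Total biomass is AGB plus allometric BGB ([bgb_allometric()]); carbon is
#' taken as 50% of total biomass. Optionally converts the areal basis from
#' Mg/ha to Mg/km^2 (factor 100).
#'
#' @param agb Aboveground biomass density, Mg/ha. Non-negative; `NA` passes
#'   through.
#' @param per_km2 If `TRUE`, return MgC/km^2 instead of MgC/ha.
#' @return Carbon density.
#' @examples
#' agb_to_carbon(1)             # 0.5 * (1 + 0.489) = 0.7445 MgC/ha
#' agb_to_carbon(1, TRUE)       # 74.45 MgC/km^2
#' @export
agb_to_carbon <- function(agb, per_km2 = FALSE) {
  cc <- 0.5 * (agb + bgb_allometric(agb))
  if (per_km2) cc * 100 else cc
}

#' Invert the AGB to carbon conversion numerically
#'
#' [agb_to_carbon()] is strictly increasing in AGB, so its inverse is well
#' defined; it has no closed form and is solved by Newton iteration (exact to
#' ~1e-12 relative). Used when exporting synthetic coarse biomass in the
#' dataset's native AGB units.
#'
#' @param carbon Carbon density (MgC/ha, or MgC/km^2 with `per_km2 = TRUE`).
#' @param per_km2 Interpret `carbon` as MgC/km^2.
#' @return Aboveground biomass density, Mg/ha.
#' @export
carbon_to_agb <- function(carbon, per_km2 = FALSE) {
  cc <- if (per_km2) carbon / 100 else carbon
  if (any(cc < 0, na.rm = TRUE)) stop("carbon must be non-negative")
  a <- 2 * cc / 1.489                       # exact when exponent were 1
  for (i in 1:60) {
    fa <- 0.5 * (a + 0.489 * a^0.89) - cc
    da <- 0.5 * (1 + 0.489 * 0.89 * a^(-0.11))
    step <- ifelse(is.na(fa) | a == 0, 0, fa / da)
    a <- pmax(a - step, 0)
    if (all(abs(step) <= 1e-13 * (a + 1), na.rm = TRUE)) break
  }
  a
}

#' Logistic biomass growth, closed form
#'
#' Solution of `d rho/dt = alpha * rho * (V - rho)` after `dt` years:
#' `rho(dt) = A rho0 V / ((A - 1) rho0 + V)` with `A = exp(V alpha dt)`.
#' Fixed points 0 and `V` are preserved exactly; `rho0 > V` decays toward `V`.
#'
#' @param rho0 Initial carbon density (>= 0), any consistent unit.
#' @param alpha Growth rate, 1/(yr * density-unit). May be negative.
#' @param V Carrying capacity, same unit as `rho0` (> 0).
#' @param dt Elapsed time, years (>= 0).
#' @return Density after `dt` years, same unit as `rho0`.
#' @examples
#' simulate_logistic_growth(50, log(3) / 100 / 8, 100, 8)   # 75
#' @export
simulate_logistic_growth <- function(rho0, alpha, V, dt) {
  if (any(V <= 0)) stop("V must be > 0")
  if (any(rho0 < 0, na.rm = TRUE)) stop("rho0 must be >= 0")
  if (any(dt < 0)) stop("dt must be >= 0")
  A <- exp(V * alpha * dt)
  A * rho0 * V / ((A - 1) * rho0 + V)
}

#' Calibrate per-block logistic growth factors from two biomass epochs
#'
#' Given the fine-grid carbon-density map at year 2000 and the coarse-grid
#' map at year 2008 (8-yr lag between the two source datasets), estimates for
#' every coarse block the 8-yr growth factor `A` under the assumption that all
#' fine cells of a block share one `A` and one carrying capacity `V`.
#'
#' Writing `rho_M` for the block mean of year-2000 fine densities and
#' `rho_500` for the block's coarse value, the first-order estimate is
#' `A = rho_500 / rho_M`; substituting it back into the block-mean matching
#' condition once gives the second-order estimate
#' `A = N rho_500 / sum_i 1 / ((A1 - 1)/V + 1/rho_i)`, summed over cells with
#' `rho_i > 0` (zero-density cells are logistic fixed points and carry no
#' growth information). Iterating further yields a continued fraction with
#' negligible gain, so the recursion stops at second order.
#'
#' @param rho0_fine `ece_raster` (or matrix) of year-2000 carbon density on
#'   the fine grid (MgC/km^2).
#' @param rho_coarse `ece_raster` (or matrix) of year-2008 carbon density on
#'   the nested coarse grid.
#' @param V Carrying capacity. Default `NULL` applies the cautious rule
#'   V = max over blocks of `rho_M`; supply a value when it is known (e.g.
#'   validation against forward-simulated scenes).
#' @param factor Block edge in fine cells; defaults to the fine grid's
#'   `coarse_factor`.
#' @return A `carbon_density_model` list: `rho0_fine`, `rho_coarse` matrices,
#'   per-block matrices `A1`, `A2`, `rho_M`, logical `undefined` (all-zero or
#'   all-nodata blocks), scalar `V`, `dt_star = 8`, and `factor`.
#' @export
calibrate_growth <- function(rho0_fine, rho_coarse, V = NULL, factor = NULL) {
  if (is.null(factor)) {
    if (!inherits(rho0_fine, "ece_raster"))
      stop("factor required for matrix input")
    factor <- rho0_fine$spec$coarse_factor
  }
  fine <- raster_values(rho0_fine)
  coarse <- raster_values(rho_coarse)
  if (inherits(rho0_fine, "ece_raster") && inherits(rho_coarse, "ece_raster") &&
      !grids_nested(rho0_fine$spec, rho_coarse$spec))
    stop("fine grid does not nest into coarse grid")
  factor <- as.integer(factor)
  if (nrow(fine) != nrow(coarse) * factor || ncol(fine) != ncol(coarse) * factor)
    stop("fine grid does not nest into coarse grid")

  rho_M <- block_average(fine, factor)
  if (is.null(V)) V <- max(rho_M, na.rm = TRUE)
  if (!is.finite(V) || V <= 0) stop("carrying capacity V must be positive")

  A1 <- coarse / rho_M
  undefined <- is.na(rho_M) | rho_M == 0 | is.na(coarse)
  A1[undefined] <- NA_real_

  # second order: blockwise harmonic-type sum over positive cells
  nrb <- nrow(coarse); ncb <- ncol(coarse)
  A2 <- matrix(NA_real_, nrb, ncb)
  bid <- matrix(0L, nrow(fine), ncol(fine))
  bid[] <- ((row(fine) - 1L) %/% factor) + ((col(fine) - 1L) %/% factor) * nrb + 1L
  for (b in which(!undefined)) {
    ri <- fine[bid == b]
    ri <- ri[!is.na(ri)]
    pos <- ri[ri > 0]
    if (length(pos) == 0L) { undefined[b] <- TRUE; next }
    n <- length(ri)
    denom <- sum(1 / ((A1[b] - 1) / V + 1 / pos))
    A2[b] <- n * coarse[b] / denom
  }
  structure(list(rho0_fine = fine, rho_coarse = coarse, A1 = A1, A2 = A2,
                 rho_M = rho_M, undefined = undefined, V = V, dt_star = 8,
                 factor = factor),
            class = "carbon_density_model")
}

#' Build a carbon-density model from known growth factors
#'
#' Bypasses calibration: use when the per-block 8-yr factor `A` is known
#' (forward simulations, sensitivity analysis). [calibrate_growth()] is the
#' data-driven path.
#'
#' @param rho0_fine Fine-grid year-2000 carbon-density matrix.
#' @param A Per-block 8-yr growth-factor matrix (or scalar, recycled).
#' @param V Carrying capacity (> 0).
#' @param factor Block edge in fine cells.
#' @return A `carbon_density_model` (both orders set to `A`).
#' @export
carbon_density_model <- function(rho0_fine, A, V, factor) {
  rho0_fine <- raster_values(rho0_fine)
  factor <- as.integer(factor)
  nbr <- nrow(rho0_fine) %/% factor; nbc <- ncol(rho0_fine) %/% factor
  Am <- matrix(A, nbr, nbc)
  if (V <= 0) stop("carrying capacity V must be positive")
  structure(list(rho0_fine = rho0_fine, rho_coarse = NULL, A1 = Am, A2 = Am,
                 rho_M = block_average(rho0_fine, factor),
                 undefined = is.na(Am), V = V, dt_star = 8, factor = factor),
            class = "carbon_density_model")
}

#' @export
print.carbon_density_model <- function(x, ...) {
  cat(sprintf(
    "<carbon_density_model> %d x %d blocks (factor %d), V = %.4g, dt* = %d yr\n",
    nrow(x$rho_M), ncol(x$rho_M), x$factor, x$V, x$dt_star))
  cat(sprintf("  A (2nd order): %.4g..%.4g, %d undefined block(s)\n",
              min(x$A2, na.rm = TRUE), max(x$A2, na.rm = TRUE),
              sum(x$undefined)))
  invisible(x)
}

block_of_pixel <- function(model, pixel) {
  f <- model$factor
  cbind((pixel[, 1] - 1L) %/% f + 1L, (pixel[, 2] - 1L) %/% f + 1L)
}

as_pixel_matrix <- function(pixel) {
  if (is.null(dim(pixel))) pixel <- matrix(pixel, ncol = 2)
  pixel
}

#' Method M1: constant year-2000 carbon density
#'
#' The density of a cell is taken from the fine-resolution year-2000 map and
#' assumed constant over the whole analysis period.
#'
#' @param model A `carbon_density_model` from [calibrate_growth()].
#' @param pixel Integer matrix (or length-2 vector) of (row, col) fine-grid
#'   indices; `NULL` returns the full map.
#' @return Carbon density value(s), MgC/km^2.
#' @export
density_m1 <- function(model, pixel = NULL) {
  if (is.null(pixel)) return(model$rho0_fine)
  pixel <- as_pixel_matrix(pixel)
  v <- model$rho0_fine[pixel]
  if (any(is.na(v))) stop("nodata pixel requested")
  v
}

#' Method M2: carbon density updated to the loss year by logistic growth
#'
#' Applies the calibrated per-block growth factor to advance the year-2000
#' density of each cell to its loss year:
#' `rho(t) = A rho0 V / ((A^(dt/8) - 1) rho0 + V)` where `A` raised to
#' `dt/8` rescales the calibrated 8-yr factor to the elapsed time
#' `dt = loss_year - 2000`. Equals `rho0` when `A = 1` or `dt = 0`; output is
#' floored at 0 (apparent-decline blocks, `A < 1`, are allowed).
#'
#' @param model A `carbon_density_model`.
#' @param loss_year Calendar year(s) of loss (>= 2000), recycled against
#'   `pixel`.
#' @param pixel (row, col) fine-grid indices as in [density_m1()]; `NULL`
#'   updates the full map (then `loss_year` is a scalar or full matrix).
#' @param order `"second"` (default) or `"first"`: which calibrated factor to
#'   use.
#' @return Updated carbon density, MgC/km^2.
#' @export
density_m2 <- function(model, loss_year, pixel = NULL, order = c("second", "first")) {
  order <- match.arg(order)
  Ab <- if (order == "second") model$A2 else model$A1
  if (is.null(pixel)) {
    rho0 <- model$rho0_fine
    A <- block_lookup(Ab, grid_spec(nrow(rho0), ncol(rho0), 1))
  } else {
    pixel <- as_pixel_matrix(pixel)
    rho0 <- model$rho0_fine[pixel]
    A <- Ab[block_of_pixel(model, pixel)]
  }
  if (any(is.na(A) & !is.na(rho0) & rho0 != 0))
    stop("undefined growth factor for requested pixel(s)")
  dt <- loss_year - 2000
  if (any(dt < 0)) stop("loss_year must be >= 2000")
  # time-rescaled growth factor; used consistently in numerator and
  # denominator so that dt = 0 and A = 1 both reduce to rho0
  Adt <- A^(dt / model$dt_star)
  out <- Adt * rho0 * model$V / ((Adt - 1) * rho0 + model$V)
  out[!is.na(rho0) & rho0 == 0] <- 0
  pmax(out, 0)
}

#' Method M3: ROI spatial mean of fine-grid carbon density
#'
#' Ergodic-like substitution of a cell's (unobserved) time-mean density by the
#' spatial average over the whole ROI, on the fine-resolution map.
#'
#' @param rho_fine `ece_raster` or matrix of carbon density.
#' @param roi Logical mask matrix (same shape) selecting ROI cells; `NULL`
#'   uses all cells.
#' @return Scalar mean density.
#' @export
density_m3 <- function(rho_fine, roi = NULL) {
  v <- raster_values(rho_fine)
  if (!is.null(roi)) v <- v[roi]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("ROI contains no valid pixel")
  mean(v)
}

#' Method M4: ROI spatial mean of coarse-grid carbon density
#'
#' As [density_m3()] but on the coarse-resolution (year 2007-2008) map.
#'
#' @param rho_coarse `ece_raster` or matrix of coarse carbon density.
#' @param roi Logical mask on the coarse grid; `NULL` uses all cells.
#' @return Scalar mean density.
#' @export
density_m4 <- function(rho_coarse, roi = NULL) density_m3(rho_coarse, roi)
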
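#' Uncertainty-propagation configuration
#'
#' Enumerates the configurations used for error propagation: density method,
#' coefficient of variation of the density error (M1/M2 only), the
#' autocorrelation length scale (ALS) defining perfectly-correlated blocks,
#' and how the per-block bound is computed.
#'
#' M3 and M4 derive their density from a ROI-scale spatial average, so they
#' force `als = "roi_scale"` and take the ROI spatial SD as the density
#' error; a supplied `cv` is ignored with a warning.
#'
#' @param method `"M1"`, `"M2"`, `"M3"` or `"M4"`.
#' @param cv Coefficient of variation in `{0.5, 0.75, 1, 1.25}` (M1/M2).
#' @param als `"block_500m"` (square blocks) or `"roi_scale"` (one block).
#' @param block_mode `"sum_sd"` (block SD = sum of pixel SDs, the
#'   perfect-correlation bound; default) or `"supremum"`
#'   (block variance = (N_block * max pixel SD)^2, an upper bound of
#'   `sum_sd`).
#' @return An `uncertainty_config` object.
#' @export
uncertainty_config <- function(method = c("M1", "M2", "M3", "M4"), cv = 1,
                               als = c("block_500m", "roi_scale"),
                               block_mode = c("sum_sd", "supremum")) {
  method <- match.arg(method)
  als <- match.arg(als)
  block_mode <- match.arg(block_mode)
  if (method %in% c("M3", "M4")) {
    if (!missing(cv)) warning("cv is ignored for methods M3/M4")
    cv <- NA_real_
    als <- "roi_scale"
  }
  structure(list(method = method, cv = cv, als = als, block_mode = block_mode),
            class = "uncertainty_config")
}

#' All Table-style uncertainty configurations
#'
#' The full grid: M1/M2 x {block_500m, roi_scale} x Cv in
#' {0.5, 0.75, 1, 1.25} (16 configurations) plus M3 and M4 at ROI scale
#' (2 more), 18 in total.
#'
#' @param block_mode Passed to every configuration.
#' @return List of 18 [uncertainty_config()] objects.
#' @export
uncertainty_configs <- function(block_mode = "sum_sd") {
  cfgs <- list()
  for (m in c("M1", "M2"))
    for (a in c("block_500m", "roi_scale"))
      for (cv in c(0.5, 0.75, 1, 1.25))
        cfgs[[length(cfgs) + 1L]] <- uncertainty_config(m, cv, a, block_mode)
  for (m in c("M3", "M4"))
    cfgs[[length(cfgs) + 1L]] <- uncertainty_config(m, als = "roi_scale",
                                                    block_mode = block_mode)
  cfgs
}

#' Variance of the Bernoulli loss indicator
#'
#' @param p RDFL probability (vectorized, in \[0, 1\]).
#' @return `p * (1 - p)`.
#' @export
bernoulli_variance <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0,1]")
  p * (1 - p)
}

#' Per-pixel eCE error variance (Goodman product formula)
#'
#' The pixel export is the product of a Bernoulli loss indicator (mean `p`)
#' and an uncertain density (mean `rho`, SD `sigma_rho`), scaled by the pixel
#' area `A`. Goodman's variance of a product of independent variables gives
#' `sigma^2 = A^2 * p * (sigma_rho^2 + (1 - p) * rho^2)`.
#'
#' @param A Pixel area (km^2); include any annualization factor in `A`.
#' @param p RDFL probability in \[0, 1\].
#' @param rho Density mean (MgC/km^2).
#' @param sigma_rho Density SD (MgC/km^2).
#' @return Variance of the pixel export, (MgC)^2 per (yr)^2 if `A` is an
#'   annual rate.
#' @examples
#' pixel_ece_variance(1, 0.5, 10, 2)   # 27
#' @export
pixel_ece_variance <- function(A, p, rho, sigma_rho) {
  if (any(c(A, rho, sigma_rho) < 0, na.rm = TRUE)) stop("inputs must be >= 0")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0,1]")
  A^2 * p * (sigma_rho^2 + (1 - p) * rho^2)
}

#' Per-pixel density SD under a configuration
#'
#' Methods M1/M2: `sigma_rho = Cv * rho` elementwise. Methods M3/M4: one
#' constant, the spatial SD of all densities measured inside the ROI,
#' broadcast to every pixel.
#'
#' @param config An [uncertainty_config()].
#' @param rho Density matrix (M1/M2) or any object whose shape the result
#'   should match.
#' @param roi_sample Vector of ROI densities (M3/M4).
#' @return Matrix (or vector) of per-pixel density SDs.
#' @export
sigma_rho <- function(config, rho = NULL, roi_sample = NULL) {
  if (config$method %in% c("M1", "M2")) {
    if (is.null(rho)) stop("rho required for M1/M2")
    config$cv * raster_values(rho)
  } else {
    if (is.null(roi_sample)) stop("roi_sample required for M3/M4")
    s <- stats::sd(roi_sample)
    if (is.null(rho)) s
    else array(s, dim = dim(raster_values(rho)) %||% length(rho))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-pixel SDs into per-block variances
#'
#' Pixels within an autocorrelation block are treated as perfectly
#' correlated: mode `"sum_sd"` sums the pixel SDs and squares
#' (`(sum sd)^2`); mode `"supremum"` bounds it from above by
#' `(N_block * max sd)^2`.
#'
#' @param sd_map Matrix of per-pixel SDs (`NA` = outside ROI).
#' @param blocks Integer matrix of block ids (same shape), e.g.
#'   [block_index()]; or a single integer block edge in pixels.
#' @param mode `"sum_sd"` or `"supremum"`.
#' @return Named numeric vector of per-block variances.
#' @export
block_aggregate <- function(sd_map, blocks, mode = c("sum_sd", "supremum")) {
  mode <- match.arg(mode)
  sd_map <- raster_values(sd_map)
  if (length(blocks) == 1L)
    blocks <- block_index(grid_spec(nrow(sd_map), ncol(sd_map), 1),
                          factor = blocks)
  keep <- !is.na(sd_map)
  if (!any(keep)) stop("empty block set: no valid pixels")
  b <- blocks[keep]; s <- sd_map[keep]
  v <- if (mode == "sum_sd") tapply(s, b, sum)^2
       else (tapply(s, b, max) * tapply(s, b, length))^2
  stats::setNames(as.vector(v), dimnames(v)[[1]])
}

#' Sum block variances into an aggregated uncertainty
#'
#' Blocks are assumed uncorrelated, so variances add:
#' `sigma^2 = sum_i sigma_i^2`.
#'
#' @param block_variances Numeric vector of per-block variances.
#' @param ece Optional total export (MgC/yr) for a percentage report.
#' @return An `uncertainty_result` list: `block_variances`, `variance`,
#'   `sigma` (same unit as the pixel exports), `sigma_tgc` (TgC/yr), and
#'   `pct` (% of `ece`, `NA` if not given).
#' @export
continental_variance <- function(block_variances, ece = NULL) {
  if (length(block_variances) < 1L) stop("at least one block required")
  v <- sum(block_variances)
  s <- sqrt(v)
  structure(list(block_variances = block_variances, variance = v, sigma = s,
                 sigma_tgc = mgc_to_tgc(s),
                 pct = if (is.null(ece)) NA_real_ else 100 * s / ece),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("<uncertainty_result> sigma = %.6g (%.4g TgC/yr) over %d block(s)",
              x$sigma, x$sigma_tgc, length(x$block_variances)))
  if (!is.na(x$pct)) cat(sprintf(", %.2f%% of eCE", x$pct))
  cat("\n"); invisible(x)
}

#' ROI-level uncertainty of the annual carbon export
#'
#' Convenience wrapper: computes the per-pixel export-rate SD from Goodman's
#' formula (with the annualized pixel area `A_cell / T`), groups pixels into
#' autocorrelation blocks per the configuration, and sums block variances.
#'
#' @param p Probability matrix (combined RDFL probability).
#' @param rho Density matrix (MgC/km^2).
#' @param sd_rho Matrix of per-pixel density SDs (see [sigma_rho()]).
#' @param spec The fine [grid_spec()].
#' @param config An [uncertainty_config()].
#' @param T_years Observation period (years).
#' @param roi Optional logical ROI mask.
#' @param block_m Block edge in metres for `als = "block_500m"`
#'   (default 500).
#' @return An `uncertainty_result` (sigma in MgC/yr).
#' @export
roi_uncertainty <- function(p, rho, sd_rho, spec, config, T_years = 20,
                            roi = NULL, block_m = 500) {
  A <- cell_area_km2(spec) / T_years
  var_map <- pixel_ece_variance(A, raster_values(p), raster_values(rho),
                                raster_values(sd_rho))
  sd_map <- sqrt(var_map)
  if (!is.null(roi)) sd_map[!roi] <- NA_real_
  if (config$als == "roi_scale") {
    blocks <- matrix(1L, spec$n_rows, spec$n_cols)
  } else {
    edge <- max(1L, as.integer(round(block_m / spec$cell_size)))
    blocks <- block_index(spec, factor = edge)
  }
  bv <- block_aggregate(sd_map, blocks, config$block_mode)
  continental_variance(bv)
}
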
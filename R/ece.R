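#' Per-ROI eco-morphodynamic carbon export
#'
#' Sums the per-pixel product of the annual river-driven loss-area rate
#' `L` (km^2/yr) and the carbon density `rho` (MgC/km^2) over the ROI:
#' `eCE = sum_k L_k * rho_k` in MgC/yr. A scalar `rho` (methods M3/M4) is
#' broadcast to all pixels.
#'
#' @param L Matrix of per-pixel RDFL rates (km^2/yr), e.g. `rdfl_area()$L`.
#' @param rho Matrix of per-pixel carbon density (MgC/km^2), or a scalar.
#' @param roi Optional logical ROI mask.
#' @return eCE in MgC/yr.
#' @export
roi_ece <- function(L, rho, roi = NULL) {
  L <- raster_values(L); rho <- raster_values(rho)
  if (length(rho) > 1 && !all(dim(L) == dim(rho)))
    stop("L and rho must share the grid (or rho must be scalar)")
  x <- L * rho
  if (!is.null(roi)) x[!roi] <- 0
  sum(x, na.rm = TRUE)
}

#' Area-normalized carbon export
#'
#' @param ece eCE in MgC/yr.
#' @param a_roi ROI area in km^2 (> 0).
#' @return eCE_A in MgC/km^2/yr.
#' @export
area_normalize <- function(ece, a_roi) {
  if (any(a_roi <= 0)) stop("A_ROI must be > 0")
  ece / a_roi
}

#' Convert MgC/yr to TgC/yr
#' @param x Value(s) in MgC/yr.
#' @return Value(s) in TgC/yr.
#' @export
mgc_to_tgc <- function(x) x * 1e-6

#' Aggregate per-ROI export records into group totals with shares
#'
#' @param records Data frame with one row per ROI; must contain the grouping
#'   column and the value columns.
#' @param by Name of the grouping column (e.g. `"basin_code"`,
#'   `"continent"`).
#' @param value Name(s) of the column(s) to total (default all `eCE_M*`
#'   columns present plus `A_RDFL` if present).
#' @return Data frame with one row per group plus a `TOTAL` row; for the
#'   first value column a `share_pct` column gives each group's percentage of
#'   the grand total (shares sum to 100 within rounding).
#' @export
aggregate_ece <- function(records, by, value = NULL) {
  if (!by %in% names(records)) stop("unknown group key: ", by)
  if (nrow(records) == 0L) stop("no records to aggregate")
  if (is.null(value)) {
    value <- intersect(c(paste0("eCE_M", 1:4), "A_RDFL"), names(records))
    if (length(value) == 0L) stop("no value columns found")
  }
  g <- records[[by]]
  out <- do.call(rbind, lapply(split(records[value], g), colSums))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    check.names = FALSE)
  names(out)[1] <- by
  tot <- colSums(out[value])
  share <- if (tot[value[1]] > 0) 100 * out[[value[1]]] / tot[value[1]]
           else rep(NA_real_, nrow(out))
  out$share_pct <- share
  total_row <- data.frame(grp = "TOTAL", as.list(tot),
                          share_pct = if (all(is.na(share))) NA_real_ else 100,
                          check.names = FALSE)
  names(total_row)[1] <- by
  rbind(out, total_row)
}

#' Run the full export pipeline on one scene / ROI
#'
#' Executes the stage order of the estimation framework: probabilistic RDFL
#' filtering, loss-area computation, growth-model calibration, the four
#' density methods, per-method eCE and area-normalized eCE, signature
#' classification, and (optionally) ROI-scale uncertainty.
#'
#' @param scene An `ece_scene` from [simulate_scene()] or [import_scene()].
#' @param window A [causal_window()].
#' @param roi Optional logical mask on the fine grid; default whole scene.
#' @param uncertainty_cfg Optional [uncertainty_config()]; default the
#'   ROI-scale, Cv = 1 configuration for method M2.
#' @return List with `probability` (`probability_maps`), `L`/`a_rdfl`,
#'   `model` (`carbon_density_model`), `ece` (named MgC/yr, M1-M4), `ece_A`
#'   (MgC/km^2/yr), `a_roi` (km^2), `signature` (`signature_class`), and
#'   `uncertainty` (list with `sigma` MgC/yr and `pct`).
#' @export
run_pipeline <- function(scene, window = causal_window(), roi = NULL,
                         uncertainty_cfg = uncertainty_config("M2", als = "roi_scale")) {
  spec <- scene$spec
  pm <- combine_probabilities(scene$loss_year, scene$pop_density,
                              scene$fire_years, scene$landcover, window)
  ra <- rdfl_area(pm, spec, scene$T_years, roi)

  rho0 <- agb_to_carbon(raster_values(scene$biomass_fine_2000), per_km2 = TRUE)
  rhoc <- agb_to_carbon(raster_values(scene$biomass_coarse_2008), per_km2 = TRUE)
  model <- calibrate_growth(rho0, rhoc, factor = spec$coarse_factor)

  ly <- raster_values(scene$loss_year)
  rho2 <- rho0
  lost <- which(!is.na(ly) & ly > 0)
  if (length(lost)) {
    px <- cbind(((lost - 1) %% nrow(ly)) + 1, ((lost - 1) %/% nrow(ly)) + 1)
    rho2[lost] <- density_m2(model, ly[lost], px)
  }

  roi_fine <- if (is.null(roi)) matrix(TRUE, spec$n_rows, spec$n_cols) else roi
  a_roi <- sum(roi_fine) * cell_area_km2(spec)
  rho3 <- density_m3(rho0, roi_fine)
  roi_coarse <- block_average(roi_fine * 1, spec$coarse_factor) > 0
  rho4 <- density_m4(rhoc, roi_coarse)

  ece <- c(M1 = roi_ece(ra$L, rho0, roi_fine),
           M2 = roi_ece(ra$L, rho2, roi_fine),
           M3 = roi_ece(ra$L, rho3, roi_fine),
           M4 = roi_ece(ra$L, rho4, roi_fine))
  ece_A <- area_normalize(ece, a_roi)

  # classify on the fine map (MgC/ha scale matches the default bin width);
  # the coarse map has too few cells on small scenes for stable histograms
  sig_sample <- rho0[roi_fine] / 100
  sig <- classify_signature(distribution_stats(sig_sample))

  rho_for_unc <- switch(uncertainty_cfg$method,
      M1 = rho0, M2 = rho2, M3 = matrix(rho3, spec$n_rows, spec$n_cols),
      M4 = block_lookup(rhoc, spec))
  sd_map <- sigma_rho(uncertainty_cfg, rho = rho_for_unc,
    roi_sample = if (uncertainty_cfg$method == "M4") rhoc[roi_coarse]
                 else rho0[roi_fine])
  unc <- roi_uncertainty(pm$p_combined, rho_for_unc, sd_map, spec,
                         uncertainty_cfg, T_years = scene$T_years,
                         roi = roi_fine)

  list(probability = pm, L = ra$L, a_rdfl = ra$a_rdfl, model = model,
       ece = ece, ece_A = ece_A, a_roi = a_roi, signature = sig,
       uncertainty = list(sigma = unc$sigma,
                          pct = 100 * unc$sigma / max(ece[[uncertainty_cfg$method]],
                                                      .Machine$double.eps)))
}
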
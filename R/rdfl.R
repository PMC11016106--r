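#' Causal temporal window for non-river-driven events
#'
#' The attribution function `f(dt)` is a step: a forest loss and a
#' non-river-driven event (wildfire, anthropic land-cover change) occurring
#' within `half_width` years of each other are treated as causally connected
#' (`f = inside_value`, by default certainty), and unconnected outside.
#'
#' @param half_width Window half-width in years (default 5).
#' @param inside_value Probability assigned inside the window (fixed 1 by
#'   convention; configurable for sensitivity analysis).
#' @param outside_value Probability outside the window (default 0).
#' @return A `causal_window` object.
#' @export
causal_window <- function(half_width = 5, inside_value = 1, outside_value = 0) {
  if (half_width < 0) stop("half_width must be >= 0")
  if (any(c(inside_value, outside_value) < 0 | c(inside_value, outside_value) > 1))
    stop("window values must be probabilities in [0,1]")
  structure(list(half_width = half_width, inside_value = inside_value,
                 outside_value = outside_value), class = "causal_window")
}

#' Causal attribution function f(dt)
#'
#' @param dt Signed year difference (loss year minus event year); vectorized.
#' @param window A [causal_window()].
#' @return Probability that the event caused the loss.
#' @examples
#' causal_attribution(0)   # 1
#' causal_attribution(7)   # 0
#' @export
causal_attribution <- function(dt, window = causal_window()) {
  ifelse(abs(dt) <= window$half_width, window$inside_value,
         window$outside_value)
}

#' Probability that a forest loss is not urbanization-driven
#'
#' Decreases with population density PD (people/km^2):
#' `1 - 0.333 * log10(PD + 1)` below 1000 people/km^2 and 0 at or above;
#' clamped to \[0, 1\]. The base-10 logarithm makes the expression continuous
#' (approximately 0) at the cutoff.
#'
#' @param pd Population density, people/km^2 (vectorized, >= 0; `NA` passes).
#' @return Probability in \[0, 1\].
#' @examples
#' urban_probability(0)      # 1
#' urban_probability(9)      # 0.667
#' urban_probability(1500)   # 0
#' @export
urban_probability <- function(pd) {
  if (any(pd < 0, na.rm = TRUE)) stop("population density must be >= 0")
  p <- ifelse(pd >= 1000, 0, 1 - 0.333 * log10(pd + 1))
  pmin(pmax(p, 0), 1)
}

#' Probability that a forest loss is not wildfire-driven
#'
#' Product over all observed fire events of `1 - f(dt)` where `dt` is the
#' year gap between the loss and the fire; 1 when no fires were observed.
#'
#' @param loss_year Year of the forest loss.
#' @param fire_years Integer vector of fire years at the pixel (possibly
#'   empty). Monthly fire records are expected collapsed to years.
#' @param window A [causal_window()].
#' @return Probability in \[0, 1\].
#' @export
wildfire_probability <- function(loss_year, fire_years,
                                 window = causal_window()) {
  if (length(fire_years) == 0L) return(1)
  p <- prod(1 - causal_attribution(loss_year - fire_years, window))
  min(max(p, 0), 1)
}

#' Default IGBP to macro-class mapping
#'
#' Groups the 17 IGBP land-cover classes into four macro-classes:
#' NHV (natural, high vegetation density: forests, shrublands, grasslands,
#' permanent wetlands), NLV (natural, low vegetation density: savannas),
#' AN (anthropic: croplands, mosaics, urban), UV (water / snow / barren).
#'
#' @return Named character vector mapping IGBP class id (1-17, names) to
#'   macro-class code.
#' @export
macroclass_mapping <- function() {
  c(`1` = "NHV",  # evergreen needleleaf forest
    `2` = "NHV",  # evergreen broadleaf forest
    `3` = "NHV",  # deciduous needleleaf forest
    `4` = "NHV",  # deciduous broadleaf forest
    `5` = "NHV",  # mixed forest
    `6` = "NHV",  # closed shrublands
    `7` = "NHV",  # open shrublands
    `8` = "NLV",  # woody savannas
    `9` = "NLV",  # savannas
    `10` = "NHV", # grasslands
    `11` = "NHV", # permanent wetlands
    `12` = "AN",  # croplands
    `13` = "AN",  # urban and built-up
    `14` = "AN",  # cropland/natural vegetation mosaic
    `15` = "UV",  # permanent snow and ice
    `16` = "UV",  # barren
    `17` = "UV")  # water bodies
}

#' Read a macro-class mapping from a text file
#'
#' One class per line, `<igbp_id> <macro_class>` separated by whitespace;
#' lines starting with `#` are comments. The mapping must be total over the
#' ids it lists and use only codes NHV/NLV/AN/UV.
#'
#' @param path File path.
#' @return Named character vector as [macroclass_mapping()].
#' @export
read_macroclass_mapping <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "\\s+")
  ids <- vapply(parts, `[`, "", 1)
  cls <- vapply(parts, `[`, "", 2)
  if (anyDuplicated(ids)) stop("duplicate IGBP class id in mapping")
  if (!all(cls %in% c("NHV", "NLV", "AN", "UV")))
    stop("unknown macro-class code in mapping")
  stats::setNames(cls, ids)
}

.anthropic_pairs <- c("NHV>NLV", "NHV>AN", "NLV>AN")

#' Detect anthropic land-cover transitions in a macro-class history
#'
#' Year-to-year changes NHV to NLV, NHV to AN, and NLV to AN are attributed
#' to human activity; every other change (including reverse transitions) is
#' attributed to river morphodynamic processes and excluded.
#'
#' @param history Character vector of yearly macro-class codes
#'   (NHV/NLV/AN/UV) for consecutive years.
#' @param years Integer vector of the years covered (default 2001 onward).
#' @return Data frame with columns `year` (year of the new state), `from`,
#'   `to`; zero rows when no anthropic transition occurred.
#' @export
anthropic_transitions <- function(history,
                                  years = seq(2001, length.out = length(history))) {
  history <- as.character(history)
  if (!all(history %in% c("NHV", "NLV", "AN", "UV")))
    stop("unknown macro-class code in history")
  if (length(history) != length(years)) stop("history/years length mismatch")
  if (length(history) < 2L)
    return(data.frame(year = integer(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  from <- history[-length(history)]; to <- history[-1]
  key <- paste0(from, ">", to)
  sel <- key %in% .anthropic_pairs
  data.frame(year = years[-1][sel], from = from[sel], to = to[sel],
             stringsAsFactors = FALSE)
}

#' Probability that a forest loss is not due to anthropic land-cover change
#'
#' Same product form as [wildfire_probability()], over the years of detected
#' anthropic macro-class transitions; 1 when none were detected.
#'
#' @param loss_year Year of the forest loss.
#' @param transition_years Integer vector of anthropic-transition years
#'   (e.g. the `year` column of [anthropic_transitions()]).
#' @param window A [causal_window()].
#' @return Probability in \[0, 1\].
#' @export
landcover_probability <- function(loss_year, transition_years,
                                  window = causal_window()) {
  wildfire_probability(loss_year, transition_years, window)
}

#' Combine the three non-river filters into per-pixel RDFL probability
#'
#' Evaluates, for every pixel with an observed forest loss, the probabilities
#' that the loss was not urbanization-driven, not wildfire-driven, and not
#' anthropic land-cover change, and multiplies them (independent events):
#' `P = P_u * P_wf * P_lc`. Pixels without loss get `P = 0` by convention.
#'
#' @param loss_year `ece_raster` or matrix of loss years (0 = no loss).
#' @param pop_density `ece_raster`/matrix of population density; may live on
#'   a coarser nested grid (containing-block lookup, no interpolation).
#' @param fire_years 3-D logical/0-1 array `[rows, cols, years]` of annual
#'   burned flags with `dimnames[[3]]` (or attribute `years`) giving the
#'   years; may be on a coarser nested grid.
#' @param landcover 3-D character/integer array of yearly macro-class codes
#'   (codes NHV/NLV/AN/UV or integers 1-4 in that order) with years as the
#'   third dimension; may be on a coarser nested grid.
#' @param window A [causal_window()].
#' @return A `probability_maps` list of matrices `p_urban`, `p_wildfire`,
#'   `p_landcover`, `p_combined`, all in \[0, 1\], plus the `loss_year`
#'   matrix used.
#' @export
combine_probabilities <- function(loss_year, pop_density, fire_years,
                                  landcover, window = causal_window()) {
  ly <- raster_values(loss_year)
  nr <- nrow(ly); nc <- ncol(ly)
  tgt <- grid_spec(nr, nc, 1)

  pd <- raster_values(pop_density)
  if (!all(dim(pd) == c(nr, nc))) pd <- block_lookup(pd, tgt)

  fy_years <- fire_stack_years(fire_years)
  fires <- expand_stack(fire_years, nr, nc)
  lc_years <- stack_years(landcover, default_start = 2001)
  lc <- expand_stack(landcover, nr, nc)
  lc <- normalize_macroclass(lc)

  p_u <- urban_probability(pd)
  p_wf <- matrix(1, nr, nc)
  p_lc <- matrix(1, nr, nc)
  loss_idx <- which(!is.na(ly) & ly > 0)
  for (k in loss_idx) {
    i <- ((k - 1) %% nr) + 1; j <- ((k - 1) %/% nr) + 1
    fy <- fy_years[fires[i, j, ] > 0]
    p_wf[k] <- wildfire_probability(ly[k], fy, window)
    tr <- anthropic_transitions(lc[i, j, ], lc_years)
    p_lc[k] <- landcover_probability(ly[k], tr$year, window)
  }
  clamp01 <- function(m) pmin(pmax(m, 0), 1)
  p_u <- clamp01(p_u); p_wf <- clamp01(p_wf); p_lc <- clamp01(p_lc)
  p <- clamp01(p_u * p_wf * p_lc)
  p[is.na(ly) | ly == 0] <- 0
  structure(list(p_urban = p_u, p_wildfire = p_wf, p_landcover = p_lc,
                 p_combined = p, loss_year = ly),
            class = "probability_maps")
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("<probability_maps> %d x %d; %d loss pixel(s), mean P = %.3f\n",
              nrow(x$p_combined), ncol(x$p_combined),
              sum(x$loss_year > 0, na.rm = TRUE),
              mean(x$p_combined[x$loss_year > 0])))
  invisible(x)
}

fire_stack_years <- function(stack) stack_years(stack, default_start = 2000)

stack_years <- function(stack, default_start) {
  ys <- attr(stack, "years")
  if (is.null(ys) && length(dim(stack)) == 3L && !is.null(dimnames(stack)[[3]]))
    ys <- as.integer(dimnames(stack)[[3]])
  if (is.null(ys)) ys <- seq(default_start, length.out = dim(stack)[3])
  as.integer(ys)
}

# Expand a possibly-coarse annual stack to the fine grid, slice by slice.
expand_stack <- function(stack, nr, nc) {
  d <- dim(stack)
  if (length(d) != 3L) stop("annual stack must be a 3-D array")
  if (d[1] == nr && d[2] == nc) return(stack)
  out <- array(stack[0][1], dim = c(nr, nc, d[3]))
  for (t in seq_len(d[3]))
    out[, , t] <- block_lookup(stack[, , t, drop = TRUE],
                               grid_spec(nr, nc, 1))
  attr(out, "years") <- stack_years(stack, default_start = 2000)
  out
}

normalize_macroclass <- function(lc) {
  if (is.character(lc)) return(lc)
  codes <- c("NHV", "NLV", "AN", "UV")
  out <- array(codes[lc], dim = dim(lc))
  attributes(out)$years <- attr(lc, "years")
  out
}

#' Annual river-driven forest-loss area
#'
#' Converts the RDFL probability map into an expected loss-area rate:
#' `L = A_cell * P / T` per pixel (km^2/yr) where `T` is the length of the
#' observation period, and sums it into the ROI total `A_RDFL`.
#'
#' @param p A `probability_maps` object (or a probability matrix).
#' @param spec The fine [grid_spec()] (pixel areas).
#' @param T_years Observation period length in years (default 20, the
#'   2000-2019 window).
#' @param roi Optional logical ROI mask.
#' @return List with `L` (matrix, km^2/yr) and `a_rdfl` (scalar, km^2/yr).
#' @export
rdfl_area <- function(p, spec, T_years = 20, roi = NULL) {
  if (T_years <= 0) stop("T_years must be > 0")
  pm <- if (inherits(p, "probability_maps")) p$p_combined else raster_values(p)
  L <- cell_area_km2(spec) * pm / T_years
  if (!is.null(roi)) L[!roi] <- 0
  list(L = L, a_rdfl = sum(L, na.rm = TRUE))
}
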
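#' Scene-generation parameters
#'
#' Bundles the tunable knobs of [simulate_scene()] with the defaults used
#' throughout validation. Fractions are per-pixel probabilities that a pixel
#' experienced a loss of the given cause during 2001-2019; their sum must not
#' exceed 1.
#'
#' @param frac_river,frac_urban,frac_wildfire,frac_landcover Expected
#'   fractions of fine pixels lost to each cause.
#' @param agb_mean,agb_sd Mean and SD (Mg/ha) of the smoothed aboveground
#'   biomass field for year 2000.
#' @param agb_smooth Half-width (cells) of the box smoother applied (three
#'   passes) to the white-noise AGB field; larger values give smoother
#'   floodplain mosaics.
#' @param growth_A_range Range of the per-block true 8-yr growth factor
#'   `A = exp(8 V alpha)`; drawn uniformly per coarse block. `c(1, 1)`
#'   disables growth (alpha = 0).
#' @param V_factor Carrying capacity as a multiple of the maximum initial
#'   carbon density in the scene.
#' @param coarse_noise_sd SD of multiplicative noise (relative) applied to
#'   the block-averaged 2008 coarse carbon field; 0 keeps the calibration
#'   target exact.
#' @param n_stray_fires Number of fire events placed at loss-free pixels
#'   (they exercise the wildfire filter without confounding any loss).
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(frac_river = 0.05, frac_urban = 0.01,
                         frac_wildfire = 0.01, frac_landcover = 0.01,
                         agb_mean = 180, agb_sd = 60, agb_smooth = 2,
                         growth_A_range = c(1.02, 1.30), V_factor = 1.3,
                         coarse_noise_sd = 0, n_stray_fires = 5) {
  fr <- c(frac_river, frac_urban, frac_wildfire, frac_landcover)
  if (any(fr < 0)) stop("cause fractions must be non-negative")
  if (sum(fr) > 1) stop("cause fractions must sum to <= 1")
  if (any(growth_A_range <= 0)) stop("growth factors must be positive")
  structure(list(frac_river = frac_river, frac_urban = frac_urban,
                 frac_wildfire = frac_wildfire, frac_landcover = frac_landcover,
                 agb_mean = agb_mean, agb_sd = agb_sd, agb_smooth = agb_smooth,
                 growth_A_range = growth_A_range, V_factor = V_factor,
                 coarse_noise_sd = coarse_noise_sd,
                 n_stray_fires = n_stray_fires),
            class = "scene_params")
}

# three-pass box blur with reflecting edges; keeps the field smooth at the
# coarse-block scale so block means vary gently
box_blur <- function(m, half_width, passes = 3) {
  if (half_width < 1) return(m)
  k <- 2 * half_width + 1
  smooth1d <- function(x) {
    n <- length(x)
    xe <- c(rev(x[seq_len(half_width)]), x, rev(x[n - seq_len(half_width) + 1]))
    as.numeric(stats::filter(xe, rep(1 / k, k), sides = 2))[half_width + seq_len(n)]
  }
  for (p in seq_len(passes)) {
    m <- apply(m, 2, smooth1d)
    m <- t(apply(m, 1, smooth1d))
  }
  m
}

#' Simulate a synthetic floodplain scene with known ground truth
#'
#' Generates all per-ROI input layers the export pipeline consumes -- a
#' year-2000 fine AGB map, a year-2008 coarse AGB map obtained by
#' forward-simulating logistic growth and block-averaging, a loss-year map,
#' population density, annual fire flags, and yearly land-cover macro-class
#' history -- together with a per-pixel ground-truth cause label and the true
#' eco-morphodynamic carbon export.
#'
#' Cause exclusivity is built in: river-caused losses have zero population
#' density, no fire within the causal window, and no anthropic land-cover
#' transition, so the probabilistic filter assigns them `P = 1` exactly;
#' urban / wildfire / land-cover losses are collocated with their stated
#' confounder inside the window, so they receive `P = 0`.
#'
#' The true export is
#' `truth_eCE = sum over river-caused pixels of A_cell * rho(loss year) / T`
#' (MgC/yr), with `rho` the forward-simulated carbon density at the loss year
#' and `T = 20` yr the 2000-2019 observation window.
#'
#' @param spec A [grid_spec()]; dimensions must be multiples of
#'   `coarse_factor`.
#' @param params A [scene_params()].
#' @param seed Integer seed; the same seed and parameters give a bit-identical
#'   scene. All randomness is drawn inside an isolated RNG scope.
#' @return An `ece_scene` list: `spec`, raster layers `biomass_fine_2000`
#'   (AGB, Mg/ha), `biomass_coarse_2008` (AGB, Mg/ha, coarse grid),
#'   `loss_year` (0 or 2001-2019), `pop_density` (people/km^2), arrays
#'   `fire_years` (rows x cols x 2000-2019, 0/1) and `landcover`
#'   (rows x cols x 2001-2019, macro-class codes), `truth_cause` (matrix of
#'   "none"/"river"/"urban"/"wildfire"/"landcover"), scalar `truth_ece`
#'   (MgC/yr), `growth` (list: per-block `alpha`, `A8`, scalar `V` in
#'   MgC/km^2), `rho_fine_2000` and `rho_at_loss` (carbon density matrices,
#'   MgC/km^2), and `T_years = 20`.
#' @export
simulate_scene <- function(spec, params = scene_params(), seed) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(inherits(spec, "grid_spec"))
  withr::with_seed(as.integer(seed), simulate_scene_impl(spec, params))
}

simulate_scene_impl <- function(spec, params) {
  nr <- spec$n_rows; nc <- spec$n_cols
  f <- spec$coarse_factor
  years_fire <- 2000:2019
  years_lc <- 2001:2019
  T_years <- 20

  # --- biomass field (AGB, Mg/ha), smoothed noise, strictly positive
  raw <- matrix(stats::rnorm(nr * nc), nr, nc)
  sm <- box_blur(raw, params$agb_smooth)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  agb0 <- pmax(params$agb_mean + params$agb_sd * sm, 1)
  rho0 <- agb_to_carbon(agb0, per_km2 = TRUE)

  # --- growth parameters: per-coarse-block alpha from a target 8-yr factor
  V <- params$V_factor * max(rho0)
  nbr <- nr %/% f; nbc <- nc %/% f
  A8 <- matrix(stats::runif(nbr * nbc, params$growth_A_range[1],
                            params$growth_A_range[2]), nbr, nbc)
  alpha_blk <- log(A8) / (V * 8)
  alpha_fine <- block_lookup(alpha_blk, grid_spec(nr, nc, 1))

  # --- loss placement
  n <- nr * nc
  fr <- c(river = params$frac_river, urban = params$frac_urban,
          wildfire = params$frac_wildfire, landcover = params$frac_landcover)
  n_cause <- round(fr * n)
  cause <- matrix("none", nr, nc)
  loss_year <- matrix(0L, nr, nc)
  if (sum(n_cause) > 0) {
    picked <- sample.int(n, sum(n_cause))
    lab <- rep(names(n_cause), n_cause)
    cause[picked] <- lab
    loss_year[picked] <- sample(2001:2019, sum(n_cause), replace = TRUE)
  }

  # --- confounder layers honoring cause exclusivity
  pop <- matrix(0, nr, nc)
  pop[cause == "urban"] <- stats::runif(sum(cause == "urban"), 1000, 5000)

  fires <- array(0L, dim = c(nr, nc, length(years_fire)),
                 dimnames = list(NULL, NULL, years_fire))
  wf_idx <- which(cause == "wildfire")
  if (length(wf_idx)) {
    # fire in the loss year itself: dt = 0, causal connection guaranteed
    t_idx <- match(loss_year[wf_idx], years_fire)
    fires[cbind(((wf_idx - 1) %% nr) + 1, ((wf_idx - 1) %/% nr) + 1, t_idx)] <- 1L
  }
  if (params$n_stray_fires > 0) {
    free <- which(cause == "none")
    stray <- free[sample.int(length(free), min(params$n_stray_fires, length(free)))]
    t_idx <- sample.int(length(years_fire), length(stray), replace = TRUE)
    fires[cbind(((stray - 1) %% nr) + 1, ((stray - 1) %/% nr) + 1, t_idx)] <- 1L
  }

  lc <- array("NHV", dim = c(nr, nc, length(years_lc)),
              dimnames = list(NULL, NULL, years_lc))
  lc_idx <- which(cause == "landcover")
  for (k in lc_idx) {
    i <- ((k - 1) %% nr) + 1; j <- ((k - 1) %/% nr) + 1
    # NHV -> AN in the loss year (or 2002, so the prior NHV year is visible
    # in the 2001-2019 history; dt = -1 is still inside the causal window)
    tr_year <- max(loss_year[k], 2002L)
    from_t <- match(tr_year, years_lc)
    lc[i, j, from_t:length(years_lc)] <- "AN"
  }

  # --- forward growth: density at 2008 (for the coarse map) and at loss year
  rho2008 <- simulate_logistic_growth(rho0, alpha_fine, V, 8)
  rho_loss <- rho0
  lost <- which(loss_year > 0)
  if (length(lost))
    rho_loss[lost] <- simulate_logistic_growth(rho0[lost], alpha_fine[lost],
                                               V, loss_year[lost] - 2000)

  rho_coarse <- block_average(rho2008, f)
  if (params$coarse_noise_sd > 0)
    rho_coarse <- pmax(rho_coarse *
      (1 + stats::rnorm(length(rho_coarse), 0, params$coarse_noise_sd)), 0)
  agb_coarse <- carbon_to_agb(rho_coarse, per_km2 = TRUE)

  # --- ground truth export (river pixels only, density at loss year)
  a_cell <- cell_area_km2(spec)
  riv <- which(cause == "river")
  truth_ece <- sum(a_cell * rho_loss[riv]) / T_years

  structure(list(
    spec = spec,
    biomass_fine_2000 = raster_layer(agb0, spec, "Mg/ha"),
    biomass_coarse_2008 = raster_layer(agb_coarse, coarse_spec(spec), "Mg/ha"),
    loss_year = raster_layer(loss_year, spec, "year"),
    pop_density = raster_layer(pop, spec, "people/km2"),
    fire_years = fires,
    landcover = lc,
    truth_cause = cause,
    truth_ece = truth_ece,
    growth = list(alpha = alpha_blk, A8 = A8, V = V),
    rho_fine_2000 = rho0,
    rho_at_loss = rho_loss,
    T_years = T_years), class = "ece_scene")
}

#' @export
print.ece_scene <- function(x, ...) {
  cat(sprintf("<ece_scene> %d x %d (coarse factor %d); %d loss pixel(s); truth eCE = %.4g MgC/yr\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$coarse_factor,
              sum(x$truth_cause != "none"), x$truth_ece))
  print(table(x$truth_cause[x$truth_cause != "none"]))
  invisible(x)
}

#' Sample a carbon-density distribution of a prescribed signature shape
#'
#' Fixture generator for the signature classifier: NS (negatively skewed,
#' population skewness <= -1), PS (positively skewed, >= +1), MM (two-normal
#' mixture with component means >= 4 pooled SD apart), BS (symmetric
#' unimodal). All values are non-negative, on the Mg/ha scale.
#'
#' @param shape One of `"NS"`, `"PS"`, `"MM"`, `"BS"`.
#' @param n Sample size (>= 100).
#' @param seed Integer seed (reproducible draws).
#' @return Numeric vector of length `n`.
#' @export
sample_signature_distribution <- function(shape = c("NS", "PS", "MM", "BS"),
                                          n, seed) {
  shape <- match.arg(shape)
  if (n < 100) stop("n must be >= 100")
  if (missing(seed)) stop("seed must be given")
  withr::with_seed(as.integer(seed), switch(shape,
    PS = 20 + stats::rgamma(n, shape = 1.2, scale = 40),
    NS = pmax(0, 300 - stats::rgamma(n, shape = 1.2, scale = 40)),
    MM = {
      z <- stats::rbinom(n, 1, 0.5)
      pmax(0, stats::rnorm(n, ifelse(z == 1, 60, 220), 20))
    },
    BS = pmax(0, stats::rnorm(n, 150, 30))))
}
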
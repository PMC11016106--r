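#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text interchange raster: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' top row first. Values are written with 17 significant digits so a
#' write/read round trip is bit-identical; the units tag is preserved in a
#' `# units:` comment line that standard readers ignore.
#'
#' @param layer An `ece_raster`.
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "ece_raster"))
  sp <- layer$spec
  v <- layer$values
  nodata <- -9999
  if (any(v == nodata, na.rm = TRUE)) nodata <- min(v, na.rm = TRUE) - 1e6
  hdr <- c(sprintf("ncols %d", sp$n_cols),
           sprintf("nrows %d", sp$n_rows),
           sprintf("xllcorner %.17g", sp$origin[1]),
           sprintf("yllcorner %.17g", sp$origin[2] - sp$n_rows * sp$cell_size),
           sprintf("cellsize %.17g", sp$cell_size),
           sprintf("NODATA_value %.17g", nodata),
           sprintf("# units: %s", layer$units),
           sprintf("# coarse_factor: %d", sp$coarse_factor))
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path Path to a `.asc` file written by [write_raster()] (or any
#'   conforming ASCII grid).
#' @return An `ece_raster`; the units tag and coarse factor are recovered
#'   from comment lines when present.
#' @export
read_raster <- function(path) {
  ln <- readLines(path)
  kv <- function(key) {
    m <- grep(paste0("^", key, "\\b"), ln, ignore.case = TRUE, value = TRUE)
    if (length(m) == 0L) return(NA)
    strsplit(trimws(m[1]), "\\s+")[[1]][2]
  }
  nc <- as.integer(kv("ncols")); nr <- as.integer(kv("nrows"))
  cs <- as.numeric(kv("cellsize"))
  xll <- as.numeric(kv("xllcorner")); yll <- as.numeric(kv("yllcorner"))
  nodata <- as.numeric(kv("NODATA_value"))
  units <- sub("^# units:\\s*", "", grep("^# units:", ln, value = TRUE))
  cf <- suppressWarnings(as.integer(
    sub("^# coarse_factor:\\s*", "", grep("^# coarse_factor:", ln, value = TRUE))))
  data_ln <- ln[!grepl("^(ncols|nrows|xllcorner|yllcorner|cellsize|NODATA_value|#)",
                       ln, ignore.case = TRUE)]
  v <- do.call(rbind, lapply(data_ln, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  if (!all(dim(v) == c(nr, nc))) stop("ASCII grid data does not match header")
  if (!is.na(nodata)) v[v == nodata] <- NA_real_
  spec <- grid_spec(nr, nc, cs, origin = c(xll, yll + nr * cs),
                    coarse_factor = if (length(cf) && !is.na(cf)) cf else 1L)
  raster_layer(v, spec, units = if (length(units)) units[1] else "")
}

#' Export a scene as a directory of ASCII rasters plus a JSON sidecar
#'
#' One `.asc` per single-band layer; the annual fire and land-cover stacks
#' are written as one `.asc` per year (`fire_<year>.asc`,
#' `landcover_<year>.asc`, land-cover coded 1=NHV, 2=NLV, 3=AN, 4=UV). The
#' truth metadata (cause labels, true eCE, growth parameters) go to
#' `scene.json`.
#'
#' @param scene An `ece_scene`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- scene$spec
  write_raster(scene$biomass_fine_2000, file.path(dir, "biomass_fine_2000.asc"))
  write_raster(scene$biomass_coarse_2008, file.path(dir, "biomass_coarse_2008.asc"))
  write_raster(scene$loss_year, file.path(dir, "loss_year.asc"))
  write_raster(scene$pop_density, file.path(dir, "pop_density.asc"))
  fy <- stack_years(scene$fire_years, 2000)
  for (t in seq_along(fy))
    write_raster(raster_layer(scene$fire_years[, , t] + 0, sp, "burned"),
                 file.path(dir, sprintf("fire_%d.asc", fy[t])))
  lcy <- stack_years(scene$landcover, 2001)
  codes <- c(NHV = 1, NLV = 2, AN = 3, UV = 4)
  for (t in seq_along(lcy)) {
    m <- matrix(codes[scene$landcover[, , t]], sp$n_rows, sp$n_cols)
    write_raster(raster_layer(m, sp, "macroclass"),
                 file.path(dir, sprintf("landcover_%d.asc", lcy[t])))
  }
  meta <- list(truth_cause = as.vector(scene$truth_cause),
               truth_ece = scene$truth_ece,
               growth = list(alpha = as.vector(scene$growth$alpha),
                             A8 = as.vector(scene$growth$A8),
                             V = scene$growth$V,
                             blocks = dim(scene$growth$A8)),
               T_years = scene$T_years,
               n_rows = sp$n_rows, n_cols = sp$n_cols,
               fire_years = fy, landcover_years = lcy)
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Import a scene directory written by [export_scene()]
#'
#' @param dir Scene directory.
#' @return An `ece_scene` equivalent to the exported one (truth layers
#'   restored from the JSON sidecar).
#' @export
import_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"), simplifyVector = TRUE)
  fine <- read_raster(file.path(dir, "biomass_fine_2000.asc"))
  coarse <- read_raster(file.path(dir, "biomass_coarse_2008.asc"))
  sp <- fine$spec
  if (!grids_nested(sp, coarse$spec)) stop("coarse grid does not nest fine grid")
  nr <- sp$n_rows; nc <- sp$n_cols
  fy <- as.integer(meta$fire_years)
  fires <- array(0L, c(nr, nc, length(fy)), dimnames = list(NULL, NULL, fy))
  for (t in seq_along(fy))
    fires[, , t] <- read_raster(file.path(dir, sprintf("fire_%d.asc", fy[t])))$values
  lcy <- as.integer(meta$landcover_years)
  codes <- c("NHV", "NLV", "AN", "UV")
  lc <- array("NHV", c(nr, nc, length(lcy)), dimnames = list(NULL, NULL, lcy))
  for (t in seq_along(lcy)) {
    m <- read_raster(file.path(dir, sprintf("landcover_%d.asc", lcy[t])))$values
    lc[, , t] <- codes[m]
  }
  rho0 <- agb_to_carbon(fine$values, per_km2 = TRUE)
  structure(list(
    spec = sp,
    biomass_fine_2000 = fine,
    biomass_coarse_2008 = coarse,
    loss_year = read_raster(file.path(dir, "loss_year.asc")),
    pop_density = read_raster(file.path(dir, "pop_density.asc")),
    fire_years = fires,
    landcover = lc,
    truth_cause = matrix(meta$truth_cause, nr, nc),
    truth_ece = meta$truth_ece,
    growth = list(alpha = matrix(meta$growth$alpha, meta$growth$blocks[1],
                                 meta$growth$blocks[2]),
                  A8 = matrix(meta$growth$A8, meta$growth$blocks[1],
                              meta$growth$blocks[2]),
                  V = meta$growth$V),
    rho_fine_2000 = rho0,
    rho_at_loss = NULL,
    T_years = meta$T_years), class = "ece_scene")
}

.roi_fields <- c("A_ROI", "A_RDFL", "Basin code", "Basin or region Name",
                 "Carbon signature code", "Carbon signature description",
                 "code", "eCE_M1", "eCE_M2", "eCE_M3", "eCE_M4",
                 "eCE_AM1", "eCE_AM2", "eCE_AM3", "eCE_AM4",
                 "FFR", "geo", "Name", "roi code", "State", "unicode", "URL")

#' Assemble one 22-field ROI attribute row
#'
#' Field set and semantics follow the published geodatabase schema: areas in
#' km^2 (A_RDFL in km^2/yr), eCE per method in TgC/yr, area-normalized eCE
#' in MgC/km^2/yr, the signature code/description pair, the river (`code`)
#' and ROI (`roi code`) identifiers with `unicode` their concatenation, and
#' the ROI polygon as a GeoJSON geometry string (WGS84, EPSG:4326).
#'
#' @param a_roi ROI area, km^2.
#' @param a_rdfl River-driven forest-loss area, km^2/yr.
#' @param basin_code Integer basin/region code.
#' @param basin_name Basin/region name.
#' @param signature A `signature_class` (or integer code 1-4).
#' @param river_code River identification code (text).
#' @param ece MgC/yr named vector `c(M1=, M2=, M3=, M4=)`; converted to
#'   TgC/yr in the row.
#' @param ece_A MgC/km^2/yr named vector (M1-M4).
#' @param ffr Free-flowing flag, 0 or 1.
#' @param geometry GeoJSON geometry string or list (Polygon, lon/lat).
#' @param name River name.
#' @param roi_code ROI identifier within the river.
#' @param state State name.
#' @param url Link to the carbon-density histogram figure.
#' @return One-row data frame with exactly the 22 schema fields.
#' @export
roi_record <- function(a_roi, a_rdfl, basin_code, basin_name, signature,
                       river_code, ece, ece_A, ffr, geometry, name,
                       roi_code, state = "", url = "") {
  if (!inherits(signature, "signature_class"))
    signature <- signature_class(signature)
  if (is.list(geometry) && !is.character(geometry))
    geometry <- as.character(jsonlite::toJSON(geometry, auto_unbox = TRUE,
                                              digits = NA))
  stopifnot(all(c("M1", "M2", "M3", "M4") %in% names(ece)),
            all(c("M1", "M2", "M3", "M4") %in% names(ece_A)))
  df <- data.frame(
    A_ROI = a_roi, A_RDFL = a_rdfl,
    `Basin code` = as.integer(basin_code), `Basin or region Name` = basin_name,
    `Carbon signature code` = signature$code,
    `Carbon signature description` = signature$label,
    code = river_code,
    eCE_M1 = mgc_to_tgc(ece[["M1"]]), eCE_M2 = mgc_to_tgc(ece[["M2"]]),
    eCE_M3 = mgc_to_tgc(ece[["M3"]]), eCE_M4 = mgc_to_tgc(ece[["M4"]]),
    eCE_AM1 = ece_A[["M1"]], eCE_AM2 = ece_A[["M2"]],
    eCE_AM3 = ece_A[["M3"]], eCE_AM4 = ece_A[["M4"]],
    FFR = as.integer(ffr), geo = geometry, Name = name,
    `roi code` = roi_code, State = state,
    unicode = paste0(river_code, roi_code), URL = url,
    check.names = FALSE, stringsAsFactors = FALSE)
  df[.roi_fields]
}

#' Validate a ROI attribute table against the 22-field schema
#'
#' Checks field names and order, signature code/description consistency,
#' `unicode` = `code` + `roi code`, parseable GeoJSON in `geo`, and the
#' eCE_A * A_ROI = eCE consistency (TgC vs MgC bookkeeping) per method.
#'
#' @param df A data frame of ROI rows (e.g. from [roi_record()]).
#' @param tol Relative tolerance for the eCE consistency check.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_roi_table <- function(df, tol = 1e-8) {
  if (!identical(names(df), .roi_fields))
    stop("attribute table does not match the 22-field schema")
  for (i in seq_len(nrow(df))) {
    sig <- signature_class(df$`Carbon signature code`[i])
    if (sig$label != df$`Carbon signature description`[i])
      stop("signature code/description mismatch in row ", i)
    if (df$unicode[i] != paste0(df$code[i], df$`roi code`[i]))
      stop("unicode is not code + roi code in row ", i)
    g <- jsonlite::fromJSON(df$geo[i])
    if (is.null(g$type)) stop("geo field is not GeoJSON in row ", i)
    for (m in 1:4) {
      lhs <- df[[paste0("eCE_AM", m)]][i] * df$A_ROI[i]      # MgC/yr
      rhs <- df[[paste0("eCE_M", m)]][i] * 1e6               # MgC/yr
      if (abs(lhs - rhs) > tol * max(abs(rhs), 1e-12))
        stop("eCE_A * A_ROI != eCE for M", m, " in row ", i)
    }
  }
  invisible(TRUE)
}

#' Read ROI polygons with metadata from a GeoJSON file
#'
#' Expects a FeatureCollection of Polygon features in geographic coordinates
#' (WGS84 / EPSG:4326); feature properties are returned as metadata.
#'
#' @param path GeoJSON file path.
#' @return List of ROIs, each a list with `geometry` (list with `type`,
#'   `coordinates` as an n x 2 matrix of the outer ring) and `properties`
#'   (named list).
#' @export
read_rois <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection")
  lapply(g$features, function(f) {
    geom <- f$geometry
    if (is.null(geom$type) || geom$type != "Polygon")
      stop("only Polygon geometries are supported")
    ring <- do.call(rbind, lapply(geom$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    list(geometry = list(type = "Polygon", coordinates = ring),
         properties = f$properties)
  })
}

#' Rasterize a polygon onto a grid by cell-center containment
#'
#' A cell belongs to the ROI when its center lies inside the polygon
#' (half-open cell coverage; the cell's whole area is assigned to it).
#' Polygon coordinates must be in the grid's projected units.
#'
#' @param ring n x 2 matrix of polygon outer-ring vertices (x, y).
#' @param spec A [grid_spec()].
#' @return Logical mask matrix.
#' @export
rasterize_roi <- function(ring, spec) {
  cs <- spec$cell_size
  xc <- spec$origin[1] + (seq_len(spec$n_cols) - 0.5) * cs
  yc <- spec$origin[2] - (seq_len(spec$n_rows) - 0.5) * cs
  gx <- matrix(rep(xc, each = spec$n_rows), spec$n_rows, spec$n_cols)
  gy <- matrix(rep(yc, times = spec$n_cols), spec$n_rows, spec$n_cols)
  inside <- pracma::inpolygon(as.vector(gx), as.vector(gy),
                              ring[, 1], ring[, 2], boundary = TRUE)
  matrix(inside, spec$n_rows, spec$n_cols)
}

polygon_centroid <- function(ring) {
  # area-weighted centroid of a simple polygon (shoelace); ring need not be
  # closed
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (x[1] != x[n] || y[1] != y[n]) { x <- c(x, x[1]); y <- c(y, y[1]) }
  cr <- x[-length(x)] * y[-1] - x[-1] * y[-length(y)]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(ring[, 1]), mean(ring[, 2])))
  c(sum((x[-length(x)] + x[-1]) * cr) / (6 * a),
    sum((y[-length(y)] + y[-1]) * cr) / (6 * a))
}

#' Write the ROI results as CSV plus GeoJSON polygon and centroid layers
#'
#' Produces three files under `dir`: `results.csv` (the 22-field attribute
#' table, eCE columns formatted to 6 significant digits), `rois.geojson`
#' (Polygon features carrying the same attributes), and
#' `centroids.geojson` (one Point per ROI, same attributes).
#'
#' @param df ROI attribute table ([roi_record()] rows); validated first.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_results <- function(df, dir) {
  validate_roi_table(df)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  out <- df
  for (nm in grep("^eCE", names(out), value = TRUE))
    out[[nm]] <- signif(out[[nm]], 6)
  utils::write.csv(out, csv, row.names = FALSE)

  feature <- function(i, geom) {
    props <- as.list(df[i, setdiff(names(df), "geo")])
    list(type = "Feature", properties = props, geometry = geom)
  }
  polys <- lapply(seq_len(nrow(df)), function(i)
    feature(i, jsonlite::fromJSON(df$geo[i], simplifyVector = FALSE)))
  cents <- lapply(seq_len(nrow(df)), function(i) {
    g <- jsonlite::fromJSON(df$geo[i], simplifyVector = TRUE)
    ring <- if (is.list(g$coordinates)) g$coordinates[[1]] else
      g$coordinates[1, , ]
    ctr <- polygon_centroid(as.matrix(ring))
    feature(i, list(type = "Point", coordinates = ctr))
  })
  gj <- function(features) jsonlite::toJSON(
    list(type = "FeatureCollection", features = features),
    auto_unbox = TRUE, digits = NA)
  pj <- file.path(dir, "rois.geojson")
  cj <- file.path(dir, "centroids.geojson")
  writeLines(gj(polys), pj)
  writeLines(gj(cents), cj)
  invisible(c(csv = csv, polygons = pj, centroids = cj))
}
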
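#' Construct a climate grid
#'
#' A `climate_grid` is one georeferenced raster variable on a regular
#' longitude/latitude grid, stored row-major north-to-south (row 1 is the
#' northernmost row).  Missing cells are held as `NA`; the nodata sentinel is
#' only used when writing to disk.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param origin_lon,origin_lat degrees of the *top-left corner* (west edge of
#'   column 1, north edge of row 1).
#' @param cell_size cell edge in decimal degrees (default 2.5 arc-minutes).
#' @param variable variable name, e.g. `"bio4"`.
#' @param nodata_value sentinel used on disk; any cell equal to it is
#'   converted to `NA` on construction.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(values, origin_lon, origin_lat,
                         cell_size = 2.5 / 60, variable = "var",
                         nodata_value = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number of degrees")
  values[!is.na(values) & values == nodata_value] <- NA_real_
  if (any(!is.finite(values) & !is.na(values)))
    stop("grid values must be finite or nodata")
  lat_s <- origin_lat - nrow(values) * cell_size
  if (origin_lat > 90 + 1e-9 || lat_s < -90 - 1e-9)
    stop("grid extends beyond a pole")
  structure(list(
    variable     = variable,
    values       = values,
    origin_lon   = origin_lon,
    origin_lat   = origin_lat,
    cell_size    = cell_size,
    nodata_value = nodata_value
  ), class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid '%s': %d x %d cells, %.6f deg, origin (%.4f, %.4f)>\n",
              x$variable, nrow(x$values), ncol(x$values),
              x$cell_size, x$origin_lon, x$origin_lat))
  v <- x$values[!is.na(x$values)]
  cat(sprintf("  %d valid cells; range [%.4g, %.4g]\n",
              length(v), if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Read a raster grid from disk
#'
#' Reads an ESRI ASCII grid (`.asc`).  The six-line header
#' (`NCOLS`/`NROWS`/`XLLCORNER`/`YLLCORNER`/`CELLSIZE`/`NODATA_value`) is
#' honoured exactly; `XLLCENTER`/`YLLCENTER` registration is converted to the
#' corner convention.  GeoTIFF input is not supported: only regular
#' longitude/latitude ASCII grids are read, and an informative error is raised
#' for `format = "geotiff"`.
#'
#' @param path path to the file.
#' @param format `"esri_ascii"` (default) or `"geotiff"` (unsupported).
#' @param variable variable name to attach; defaults to the file stem.
#' @return a [climate_grid()].
#' @export
read_grid <- function(path, format = c("esri_ascii", "geotiff"),
                      variable = NULL) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("GeoTIFF reading is not supported; convert to ESRI ASCII grid")
  if (!file.exists(path)) stop("cannot read grid: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("not an ESRI ASCII grid (too short): ", path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("inconsistent ESRI ASCII header in ", path,
         " (missing ", paste(setdiff(need, names(hdr)), collapse = ", "), ")")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - cs / 2
  else stop("inconsistent ESRI ASCII header: no XLLCORNER/XLLCENTER")
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - cs / 2
  else stop("inconsistent ESRI ASCII header: no YLLCORNER/YLLCENTER")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ESRI ASCII body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (is.null(variable))
    variable <- sub("\\.[^.]*$", "", basename(path))
  climate_grid(m, origin_lon = xll, origin_lat = yll + nr * cs,
               cell_size = cs, variable = variable, nodata_value = nodata)
}

#' Write a climate grid as an ESRI ASCII file
#'
#' Values are written at full double precision (`%.17g`) so that
#' `read_grid(write_grid(g))` round-trips bit-exactly.
#'
#' @param grid a [climate_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  hdr <- c(
    sprintf("NCOLS %d", nc),
    sprintf("NROWS %d", nr),
    sprintf("XLLCORNER %.17g", grid$origin_lon),
    sprintf("YLLCORNER %.17g", grid$origin_lat - nr * grid$cell_size),
    sprintf("CELLSIZE %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata_value)
  )
  v <- grid$values
  v[is.na(v)] <- grid$nodata_value
  body <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Align climate grids into a layer stack
#'
#' A `layer_stack` is a named, co-registered set of climate grids for one
#' scenario plus a validity mask: a cell is valid iff *no* layer is nodata
#' there.  All downstream analysis is restricted to the valid mask.
#'
#' @param grids list of [climate_grid()] objects sharing one geometry.
#' @param scenario_id label for the scenario, e.g. `"present"`.
#' @return an object of class `layer_stack`.
#' @export
align_stack <- function(grids, scenario_id = "present") {
  if (length(grids) < 1) stop("need at least one grid")
  if (inherits(grids, "climate_grid")) grids <- list(grids)
  ref <- grids[[1]]
  for (g in grids) {
    if (!inherits(g, "climate_grid")) stop("all elements must be climate_grid")
    if (!same_geometry(ref, g))
      stop("alignment error: layer '", g$variable,
           "' does not share the stack geometry")
  }
  nms <- vapply(grids, function(g) g$variable, character(1))
  if (anyDuplicated(nms)) stop("duplicate layer names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  names(grids) <- nms
  valid <- Reduce(`&`, lapply(grids, function(g) !is.na(g$values)))
  structure(list(
    scenario_id = scenario_id,
    layers      = grids,
    valid_mask  = valid
  ), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<layer_stack '%s': %d layers, %d x %d cells, %d valid>\n",
              x$scenario_id, length(x$layers), nrow(g$values), ncol(g$values),
              sum(x$valid_mask)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

stack_values <- function(stack, cells = NULL, variables = NULL) {
  # matrix of raw layer values: one row per cell, one column per variable
  if (is.null(variables)) variables <- names(stack$layers)
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing))
    stop("projection error: scenario '", stack$scenario_id,
         "' is missing variable(s): ", paste(missing, collapse = ", "))
  if (is.null(cells)) {
    idx <- which(stack$valid_mask)
  } else {
    idx <- (cells[, 2] - 1L) * nrow(stack$valid_mask) + cells[, 1]
  }
  out <- vapply(variables, function(v) stack$layers[[v]]$values[idx],
                numeric(length(idx)))
  if (!is.matrix(out)) out <- matrix(out, ncol = length(variables),
                                     dimnames = list(NULL, variables))
  out
}

#' Per-cell geodesic areas
#'
#' Cell areas on a spherical Earth from the closed-form latitude-band formula
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`.  Areas are constant
#' within a row and decrease monotonically from the equator toward either
#' pole.
#'
#' @param grid a [climate_grid()] or [align_stack()] output (geometry source).
#' @param earth_radius_km spherical Earth radius, default 6371 km.
#' @return matrix of cell areas in km2 matching the grid dimensions.
#' @export
cell_areas <- function(grid, earth_radius_km = 6371) {
  if (inherits(grid, "layer_stack")) grid <- grid$layers[[1]]
  stopifnot(inherits(grid, "climate_grid"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  top <- grid$origin_lat - (seq_len(nr) - 1) * cs
  bot <- top - cs
  if (any(top > 90 + 1e-9) || any(bot < -90 - 1e-9))
    stop("geometry error: cell band straddles a pole")
  top <- pmin(top, 90); bot <- pmax(bot, -90)
  dlam <- cs * pi / 180
  band <- earth_radius_km^2 * dlam *
    (sin(top * pi / 180) - sin(bot * pi / 180))
  matrix(rep(band, nc), nrow = nr, ncol = nc)
}
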
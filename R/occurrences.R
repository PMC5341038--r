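#' Snap longitude/latitude points to grid cells
#'
#' Cell registration: row 1 is the northernmost row; a cell owns the
#' half-open interval `[edge, edge + cell_size)` in longitude and the interval
#' just south of its top edge in latitude, so a point exactly on a shared
#' edge belongs to the cell south/east of it.
#'
#' @param lon,lat numeric vectors of decimal degrees.
#' @param grid a [climate_grid()] or [align_stack()] output.
#' @return integer matrix with columns `row`, `col`; points outside the grid
#'   get `NA`.
#' @export
snap_to_cell <- function(lon, lat, grid) {
  if (inherits(grid, "layer_stack")) grid <- grid$layers[[1]]
  cs <- grid$cell_size
  col <- floor((lon - grid$origin_lon) / cs) + 1L
  row <- floor((grid$origin_lat - lat) / cs) + 1L
  # a point on the very top edge belongs to row 1 (there is no cell north)
  row[!is.na(lat) & lat == grid$origin_lat] <- 1L
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  bad <- is.na(row) | is.na(col) | row < 1L | row > nr | col < 1L | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

cell_center <- function(cells, grid) {
  if (inherits(grid, "layer_stack")) grid <- grid$layers[[1]]
  cs <- grid$cell_size
  cbind(lon = grid$origin_lon + (cells[, 2] - 0.5) * cs,
        lat = grid$origin_lat - (cells[, 1] - 0.5) * cs)
}

#' Load occurrence records and deduplicate per pixel
#'
#' Reads an occurrence table (CSV with header `species,lon,lat`, or a data
#' frame with `lon`/`lat` columns), snaps each record to its containing grid
#' cell, drops records outside the grid or on invalid (nodata) cells, and
#' collapses duplicates within a cell to the first record in file order —
#' the pixel-deduplication step standard for herbarium/GBIF compilations at
#' 2.5 arc-min resolution.
#'
#' @param x CSV path or data frame.
#' @param stack a [align_stack()] output (or a single [climate_grid()], in
#'   which case all non-nodata cells are treated as valid).
#' @return an `occurrence_set`: data frame with columns `species`, `lon`,
#'   `lat`, `row`, `col` (one row per occupied cell) plus attributes
#'   `n_raw`, `n_dropped_outside`, `n_dropped_invalid`, `n_duplicates`.
#' @export
load_occurrences <- function(x, stack) {
  if (is.character(x)) {
    df <- utils::read.csv(x, stringsAsFactors = FALSE)
  } else df <- as.data.frame(x)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("schema error: occurrence table needs 'lon' and 'lat' columns")
  if (!"species" %in% names(df)) df$species <- "species"
  if (inherits(stack, "climate_grid"))
    stack <- align_stack(list(stack), scenario_id = "present")
  n_raw <- nrow(df)
  cells <- snap_to_cell(df$lon, df$lat, stack)
  outside <- is.na(cells[, 1])
  valid <- rep(FALSE, n_raw)
  inb <- which(!outside)
  valid[inb] <- stack$valid_mask[cbind(cells[inb, 1], cells[inb, 2])]
  keep <- !outside & valid
  n_out <- sum(outside); n_inv <- sum(!outside & !valid)
  df <- df[keep, , drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  key <- paste(cells[, 1], cells[, 2])
  first <- !duplicated(key)
  n_dup <- sum(!first)
  out <- data.frame(species = df$species[first],
                    lon = df$lon[first], lat = df$lat[first],
                    row = cells[first, 1], col = cells[first, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(out) == 0)
    stop("empty-input error: no occurrence records survive snapping/dedup")
  if (n_out + n_inv > 0)
    message(sprintf("load_occurrences: dropped %d outside-grid and %d invalid-cell record(s)",
                    n_out, n_inv))
  structure(out, class = c("occurrence_set", "data.frame"),
            n_raw = n_raw, n_dropped_outside = n_out,
            n_dropped_invalid = n_inv, n_duplicates = n_dup)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set: %d records in distinct pixels (%s raw, %s duplicate(s) removed)>\n",
              nrow(x), attr(x, "n_raw") %||% "?", attr(x, "n_duplicates") %||% "?"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

occ_cells <- function(occ) cbind(row = occ$row, col = occ$col)
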
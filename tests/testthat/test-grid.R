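test_that("ESRI ASCII header semantics and round-trip are exact", {
  tmp <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 100", "YLLCORNER 30",
               "CELLSIZE 0.5", "NODATA_value -9999",
               "1 2", "-9999 4"), tmp)
  g <- read_grid(tmp)
  expect_equal(sum(is.na(g$values)), 1)
  expect_true(is.na(g$values[2, 1]))
  expect_equal(g$origin_lon, 100)
  expect_equal(g$origin_lat, 31)   # yllcorner 30 + 2 rows * 0.5
  expect_equal(g$values[1, 2], 2)

  # round-trip preserves values bit-exactly, including the nodata hole
  set.seed(3)
  g2 <- climate_grid(matrix(rnorm(30), 5, 6), origin_lon = -1.25,
                     origin_lat = 12.75, cell_size = 2.5 / 60,
                     variable = "bio7")
  g2$values[4, 2] <- NA
  tmp2 <- withr::local_tempfile(fileext = ".asc")
  write_grid(g2, tmp2)
  g3 <- read_grid(tmp2, variable = "bio7")
  expect_identical(g3$values, g2$values)
  expect_identical(g3$origin_lat, g2$origin_lat)

  expect_error(read_grid(tmp, format = "geotiff"), "not supported")
  expect_error(read_grid(file.path(tempdir(), "absent.asc")), "no such file")
  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "XLLCORNER 0", "YLLCORNER 0", "CELLSIZE 1",
               "NODATA_value -9999", "1 2", "3 4"), bad)
  expect_error(read_grid(bad), "header")
})

test_that("stack alignment requires identical geometry and conjoins validity", {
  g1 <- tiny_grid()
  g2 <- tiny_grid(); g2$variable <- "bio2"; g2$values[1, 1] <- NA
  s <- align_stack(list(g1, g2))
  expect_length(s$layers, 2)
  expect_false(s$valid_mask[1, 1])   # nodata in one layer only
  expect_false(s$valid_mask[2, 3])   # nodata in both
  expect_equal(sum(s$valid_mask), 14)

  g3 <- tiny_grid(); g3$variable <- "bio3"; g3$cell_size <- 0.25
  expect_error(align_stack(list(g1, g3)), "bio3")
})

test_that("stack validity mask matches per-layer data under random nodata", {
  set.seed(42)
  for (rep in 1:5) {
    grids <- lapply(1:3, function(i) {
      m <- matrix(rnorm(100), 10, 10)
      m[sample(100, 15)] <- NA
      climate_grid(m, 0, 10, 0.1, variable = paste0("v", i))
    })
    s <- align_stack(grids)
    manual <- !is.na(grids[[1]]$values) & !is.na(grids[[2]]$values) &
      !is.na(grids[[3]]$values)
    expect_identical(s$valid_mask, manual)
  }
})

test_that("cell areas follow the spherical band formula", {
  R <- 6371
  cs <- 2.5 / 60
  # one 2.5 arc-min cell with bottom edge on the equator: closed form
  g <- climate_grid(matrix(0, 1, 1), origin_lon = 0, origin_lat = cs,
                    cell_size = cs)
  a <- cell_areas(g)
  expect_equal(a[1, 1], R^2 * (cs * pi / 180) * sin(cs * pi / 180),
               tolerance = 1e-12)
  expect_equal(a[1, 1], 21.47, tolerance = 1e-3)

  # north/south symmetry of equal bands
  gn <- climate_grid(matrix(0, 1, 1), 0, 10 + cs, cs)
  gs <- climate_grid(matrix(0, 1, 1), 0, -10, cs)
  expect_equal(cell_areas(gn)[1, 1], cell_areas(gs)[1, 1], tolerance = 1e-12)

  # full-sphere conservation at 90-degree cells
  sphere <- climate_grid(matrix(0, 2, 4), origin_lon = -180, origin_lat = 90,
                         cell_size = 90)
  expect_equal(sum(cell_areas(sphere)), 4 * pi * R^2, tolerance = 1e-9)

  # row monotonicity away from the equator and per-band conservation
  g <- climate_grid(matrix(0, 40, 7), origin_lon = 0, origin_lat = 50,
                    cell_size = 0.25)
  a <- cell_areas(g)
  expect_true(all(diff(a[, 1]) > 0))  # rows approach the equator going south
  band_total <- sum(a[13, ])
  phi_t <- (50 - 12 * 0.25) * pi / 180
  phi_b <- (50 - 13 * 0.25) * pi / 180
  expect_equal(band_total,
               6371^2 * (7 * 0.25 * pi / 180) * (sin(phi_t) - sin(phi_b)),
               tolerance = 1e-9)

  # a grid whose bands would straddle a pole is rejected at construction
  expect_error(climate_grid(matrix(0, 2, 2), 0, 100, 10), "pole")
})

test_that("point snapping follows the south/east edge-ownership rule", {
  g <- tiny_grid()  # origin (10, 50), cell 0.5
  # interior point
  expect_equal(snap_to_cell(10.1, 49.9, g), cbind(row = 1L, col = 1L))
  # on a shared vertical edge -> cell east of it
  expect_equal(snap_to_cell(10.5, 49.9, g)[1, "col"], c(col = 2L))
  # on a shared horizontal edge -> cell south of it
  expect_equal(snap_to_cell(10.1, 49.5, g)[1, "row"], c(row = 2L))
  # top edge of the grid belongs to row 1
  expect_equal(snap_to_cell(10.1, 50, g)[1, "row"], c(row = 1L))
  # outside
  expect_true(all(is.na(snap_to_cell(9.9, 49, g))))
  expect_true(all(is.na(snap_to_cell(10.1, 47.9, g))))
})

test_that("occurrence loading dedups per pixel and drops invalid records", {
  g <- tiny_grid()
  df <- data.frame(species = "sp",
                   lon = c(10.10, 10.101, 11.1, 11.9, 5.0),
                   lat = c(49.90, 49.901, 49.2, 49.9, 49.9))
  # records 1+2 share a cell; record 3 lands on the nodata cell (row2,col3);
  # record 4 in-grid valid; record 5 outside
  expect_message(occ <- load_occurrences(df, g), "dropped 1 outside.*1 invalid")
  expect_equal(nrow(occ), 2)
  expect_equal(attr(occ, "n_duplicates"), 1)
  expect_equal(occ$lon[1], 10.10)   # first record in file order kept

  # idempotence: re-loading its own output changes nothing
  occ2 <- load_occurrences(occ[, c("species", "lon", "lat")], g)
  expect_equal(occ2$row, occ$row)
  expect_equal(occ2$col, occ$col)

  expect_error(load_occurrences(data.frame(x = 1, y = 2), g), "schema")
  expect_error(load_occurrences(data.frame(lon = 5, lat = 5), g),
               "empty-input")
})

test_that("a 300-record sample over a constrained range yields 203 pixels", {
  # emulates the field/herbarium compilation: raw records with many
  # within-pixel duplicates collapse to the published count of one record
  # per 2.5 arc-min pixel
  g <- climate_grid(matrix(0, 30, 30), origin_lon = 100, origin_lat = 30,
                    cell_size = 2.5 / 60)
  set.seed(9)
  cells <- cbind(sample(30, 203, replace = TRUE), sample(30, 203, TRUE))
  cells <- cells[!duplicated(cells), , drop = FALSE]
  while (nrow(cells) < 203) {
    extra <- cbind(sample(30, 203, TRUE), sample(30, 203, TRUE))
    cells <- rbind(cells, extra)[!duplicated(rbind(cells, extra)), , drop = FALSE]
    cells <- cells[seq_len(min(203, nrow(cells))), , drop = FALSE]
  }
  ctr <- maxsdm:::cell_center(cells, g)
  dup <- sample(203, 97, replace = TRUE)  # 97 duplicate records -> 300 raw
  df <- data.frame(species = "sp",
                   lon = c(ctr[, 1], ctr[dup, 1]),
                   lat = c(ctr[, 2], ctr[dup, 2]))
  occ <- load_occurrences(df, g)
  expect_equal(nrow(occ), 203)
})
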
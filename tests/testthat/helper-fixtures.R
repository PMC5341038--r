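# Shared small fixtures, built once per test run.

# a small synthetic study system: 60x60 grid, 5 variables (niche on v1, v2,
# collinear pair v4/v5), modest occurrence sample -- fast enough for unit tests
small_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- synthetic_world(n_vars = 5, n_rows = 60, n_cols = 60,
                                          n_raw = 150, seed = 101)
    w
  }
})

small_background <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- sample_background(small_world()$stack, 800, seed = 7)
    b
  }
})

# a deterministic 4x4 single-variable grid with one nodata hole
tiny_grid <- function() {
  m <- matrix(as.numeric(1:16), 4, 4)
  m[2, 3] <- NA
  climate_grid(m, origin_lon = 10, origin_lat = 50, cell_size = 0.5,
               variable = "bio1")
}

jaccard <- function(a, b) {
  A <- !is.na(a) & a
  B <- !is.na(b) & b
  sum(A & B) / sum(A | B)
}
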
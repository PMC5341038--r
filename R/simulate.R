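#' Generate a spatially smooth, correlated climate landscape
#'
#' Builds `n_vars` spatially autocorrelated surfaces with a prescribed
#' pairwise correlation structure: independent smooth base fields are drawn
#' from a random low-frequency cosine basis, centred, orthonormalized (QR),
#' and mixed through the Cholesky factor of the target correlation matrix, so
#' the sample correlations over cells match the targets exactly while each
#' surface stays smooth.  Layers are named `v1 ... v<n_vars>` and each has
#' zero mean and unit variance over cells.
#'
#' @param n_vars number of variables.
#' @param n_rows,n_cols grid size (default 150 x 150).
#' @param correlation target correlation matrix (`n_vars` square, positive
#'   definite).  Default: identity except one strongly collinear pair
#'   (`r = 0.95` between the last two variables) and two mild correlations,
#'   to exercise the grouping and VIF machinery.
#' @param smoothness highest spatial frequency (cycles per domain) of the
#'   cosine basis; smaller = smoother (default 6).
#' @param n_modes number of random cosine modes per base field.
#' @param seed integer seed; same seed, same landscape, bit for bit.
#' @param origin_lon,origin_lat,cell_size georeferencing of the grid
#'   (defaults place it over the subtropical mountains of south-central
#'   China at 2.5 arc-min).
#' @return a [align_stack()] stack with scenario id `"present"`.
#' @export
generate_landscape <- function(n_vars = 8, n_rows = 150, n_cols = 150,
                               correlation = NULL, smoothness = 6,
                               n_modes = 60, seed = 1,
                               origin_lon = 100, origin_lat = 33,
                               cell_size = 2.5 / 60) {
  if (is.null(correlation)) correlation <- default_correlation(n_vars)
  correlation <- as.matrix(correlation)
  stopifnot(nrow(correlation) == n_vars, ncol(correlation) == n_vars)
  U <- tryCatch(chol(correlation),
                error = function(e) stop("parameter error: correlation targets not positive definite"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xs <- (seq_len(n_cols) - 0.5) / n_cols
  ys <- (seq_len(n_rows) - 0.5) / n_rows
  Xc <- matrix(rep(xs, each = n_rows), n_rows, n_cols)
  Yc <- matrix(rep(ys, n_cols), n_rows, n_cols)
  ncell <- n_rows * n_cols
  M <- matrix(0, ncell, n_vars)
  for (v in seq_len(n_vars)) {
    fx <- stats::runif(n_modes, 0, smoothness)
    fy <- stats::runif(n_modes, 0, smoothness)
    ph <- stats::runif(n_modes, 0, 2 * pi)
    amp <- stats::rnorm(n_modes) / sqrt(1 + fx^2 + fy^2)
    f <- matrix(0, n_rows, n_cols)
    for (k in seq_len(n_modes))
      f <- f + amp[k] * cos(2 * pi * (fx[k] * Xc + fy[k] * Yc) + ph[k])
    M[, v] <- as.vector(f)
  }
  M <- scale(M, center = TRUE, scale = FALSE)
  qrd <- qr(M)
  Q <- qr.Q(qrd)
  # fix QR sign ambiguity for determinism
  sgn <- sign(diag(qr.R(qrd))); sgn[sgn == 0] <- 1
  Q <- sweep(Q, 2, sgn, `*`)
  Z <- Q * sqrt(ncell - 1)          # unit sample variance, zero correlation
  V <- Z %*% U                      # sample correlation = target, exactly
  grids <- lapply(seq_len(n_vars), function(v)
    climate_grid(matrix(V[, v], n_rows, n_cols),
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size, variable = paste0("v", v)))
  align_stack(grids, scenario_id = "present")
}

default_correlation <- function(n_vars) {
  # one strongly collinear pair (last two variables) plus mild correlations
  # kept disjoint from the pair so the matrix stays positive definite
  C <- diag(n_vars)
  if (n_vars >= 2) {
    i <- n_vars - 1; j <- n_vars
    C[i, j] <- C[j, i] <- 0.95
  }
  if (n_vars >= 5) C[1, 3] <- C[3, 1] <- 0.5
  if (n_vars >= 6) C[2, 4] <- C[4, 2] <- 0.4
  C
}

#' Gaussian niche specification and true suitability
#'
#' The virtual species responds to each driving variable through a Gaussian
#' response `exp(-(x - mu)^2 / (2 sigma^2))`; joint suitability is the
#' product over driving variables (peak 1 at the joint optimum), independent
#' of all other variables.
#'
#' @param mu,sigma named numeric vectors (names = driving variables).
#' @return a `niche_spec` list.
#' @export
niche_spec <- function(mu = c(v1 = 0, v2 = 0), sigma = c(v1 = 0.25, v2 = 0.25)) {
  stopifnot(identical(sort(names(mu)), sort(names(sigma))), all(sigma > 0))
  structure(list(mu = mu, sigma = sigma[names(mu)]), class = "niche_spec")
}

#' True suitability of a niche over a stack
#'
#' @param niche a [niche_spec()].
#' @param stack a [align_stack()] stack containing the driving variables.
#' @return suitability matrix in `(0, 1]` (`NA` on invalid cells).
#' @export
true_suitability <- function(niche, stack) {
  vars <- names(niche$mu)
  vals <- stack_values(stack, NULL, vars)
  s <- rep(1, nrow(vals))
  for (v in vars)
    s <- s * exp(-(vals[, v] - niche$mu[[v]])^2 / (2 * niche$sigma[[v]]^2))
  out <- matrix(NA_real_, nrow(stack$valid_mask), ncol(stack$valid_mask))
  out[stack$valid_mask] <- s
  out
}

#' Sample occurrence records from a true suitability surface
#'
#' Cells are drawn with probability proportional to suitability, *with*
#' replacement (duplicate records within a pixel are intended: they exercise
#' the pixel-deduplication step).  Records are placed at cell centres and
#' returned as the standard `species,lon,lat` table.
#'
#' @param suitability matrix from [true_suitability()].
#' @param stack the stack defining the grid geometry.
#' @param n_raw number of raw records to draw (default 250).
#' @param seed integer seed.
#' @param species species label for the CSV column.
#' @return data frame `species`, `lon`, `lat` (one row per raw record).
#' @export
sample_occurrences <- function(suitability, stack, n_raw = 250, seed = 1,
                               species = "virtual") {
  w <- suitability[stack$valid_mask]
  if (all(w <= 0 | is.na(w)))
    stop("sampling error: all-zero suitability surface")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  valid_idx <- which(stack$valid_mask)
  take <- sample(valid_idx, n_raw, replace = TRUE, prob = w)
  nr <- nrow(stack$valid_mask)
  cells <- cbind(row = ((take - 1L) %% nr) + 1L,
                 col = ((take - 1L) %/% nr) + 1L)
  ctr <- cell_center(cells, stack)
  data.frame(species = species, lon = ctr[, "lon"], lat = ctr[, "lat"],
             stringsAsFactors = FALSE)
}

#' Shift a climate stack to emulate a scenario
#'
#' Adds a named per-variable delta to the layers (e.g. a warming shift on
#' the temperature-like variable); geometry and validity are preserved.
#'
#' @param stack a [align_stack()] stack.
#' @param deltas named numeric vector of additive shifts.
#' @param scenario_id id for the shifted stack.
#' @return a new [align_stack()] stack.
#' @export
shift_scenario <- function(stack, deltas, scenario_id = "scenario") {
  unknown <- setdiff(names(deltas), names(stack$layers))
  if (length(unknown))
    stop("parameter error: unknown variable(s) in deltas: ",
         paste(unknown, collapse = ", "))
  grids <- lapply(stack$layers, function(g) {
    d <- deltas[g$variable]
    if (!is.na(d) && !is.null(d) && g$variable %in% names(deltas))
      g$values <- g$values + unname(d)
    g
  })
  align_stack(grids, scenario_id = scenario_id)
}

#' Random contiguous protected-area mask
#'
#' Grows random contiguous patches over the valid cells until the requested
#' fraction of the valid area is covered (exact to one cell).
#'
#' @param stack a [align_stack()] stack (geometry + validity source).
#' @param coverage_fraction target fraction of valid cells in `[0, 1]`.
#' @param seed integer seed.
#' @return logical matrix (TRUE = protected; FALSE elsewhere).
#' @export
make_protected_mask <- function(stack, coverage_fraction = 0.25, seed = 1) {
  stopifnot(coverage_fraction >= 0, coverage_fraction <= 1)
  vm <- stack$valid_mask
  nr <- nrow(vm); nc <- ncol(vm)
  mask <- matrix(FALSE, nr, nc)
  target <- round(coverage_fraction * sum(vm))
  if (target == 0) return(mask)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_in <- 0L
  while (n_in < target) {
    # seed a new patch at a random unprotected valid cell
    open <- which(vm & !mask)
    if (!length(open)) break
    frontier <- open[sample.int(length(open), 1)]
    patch_target <- min(target - n_in, sample(50:400, 1))
    grown <- 0L
    while (grown < patch_target && length(frontier)) {
      cell <- frontier[sample.int(length(frontier), 1)]
      frontier <- setdiff(frontier, cell)
      if (mask[cell]) next
      mask[cell] <- TRUE
      n_in <- n_in + 1L; grown <- grown + 1L
      r <- ((cell - 1L) %% nr) + 1L; cc <- ((cell - 1L) %/% nr) + 1L
      nb <- c(if (r > 1) cell - 1L, if (r < nr) cell + 1L,
              if (cc > 1) cell - nr, if (cc < nc) cell + nr)
      nb <- nb[vm[nb] & !mask[nb]]
      frontier <- c(frontier, nb)
    }
  }
  mask
}

#' Build a complete synthetic study system
#'
#' Bundles everything one model-validation run needs: a present-day
#' landscape with a known Gaussian niche on `v1` and `v2` (plus nuisance
#' variables including one strongly collinear pair), scenario stacks with
#' per-variable climate shifts, true suitability surfaces per scenario, a
#' raw occurrence sample (with duplicates), and a protected-area mask.
#' Default scenario shifts emulate a mildly different mid-Holocene, a cooler
#' glacial maximum, and a +1.5 SD warming future on the temperature-like
#' driver `v1`.
#'
#' @param n_vars,n_rows,n_cols,correlation,smoothness landscape parameters
#'   (see [generate_landscape()]).
#' @param niche a [niche_spec()]; default Gaussian niche on `v1`, `v2` with
#'   `mu = 0`, `sigma = 0.5` (in landscape SD units).
#' @param scenarios named list of delta vectors for [shift_scenario()].
#' @param n_raw raw occurrence draws (default 250).
#' @param protected_fraction protected-area coverage (default 0.25).
#' @param seed master seed; all component seeds derive from it.
#' @return a `synthetic_world`: list with `stack`, `scenarios` (list of
#'   stacks), `niche`, `truth` (true-suitability matrices per scenario,
#'   incl. `present`), `occurrences_raw` (CSV-shaped data frame),
#'   `occurrences` (deduplicated `occurrence_set`), `protected_mask`,
#'   `seed`.
#' @export
synthetic_world <- function(n_vars = 8, n_rows = 150, n_cols = 150,
                            correlation = NULL, smoothness = 6,
                            niche = niche_spec(),
                            scenarios = list(
                              holocene = c(v1 = -0.4),
                              lgm = c(v1 = -0.9, v2 = 0.2),
                              warming2070 = c(v1 = 1.5)),
                            n_raw = 250, protected_fraction = 0.25,
                            seed = 1) {
  stack <- generate_landscape(n_vars, n_rows, n_cols, correlation,
                              smoothness, seed = seed)
  scen_stacks <- lapply(names(scenarios), function(id)
    shift_scenario(stack, scenarios[[id]], scenario_id = id))
  names(scen_stacks) <- names(scenarios)
  truth <- c(list(present = true_suitability(niche, stack)),
             lapply(scen_stacks, function(s) true_suitability(niche, s)))
  occ_raw <- sample_occurrences(truth$present, stack, n_raw = n_raw,
                                seed = seed + 1L)
  occ <- load_occurrences(occ_raw, stack)
  mask <- make_protected_mask(stack, protected_fraction, seed = seed + 2L)
  structure(list(stack = stack, scenarios = scen_stacks, niche = niche,
                 truth = truth, occurrences_raw = occ_raw,
                 occurrences = occ, protected_mask = mask, seed = seed),
            class = "synthetic_world")
}

#' Write a synthetic world to disk
#'
#' Writes each scenario's layers as ESRI ASCII grids, the raw occurrence
#' records as the standard `species,lon,lat` CSV, the protected mask as a
#' 0/1 grid, and the niche parameters and seed as `truth.json`, so a run
#' can be scored for recovery later.
#'
#' @param world a [synthetic_world()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stacks <- c(list(present = world$stack), world$scenarios)
  for (id in names(stacks))
    for (g in stacks[[id]]$layers)
      write_grid(g, file.path(dir, paste0(id, "_", g$variable, ".asc")))
  utils::write.csv(world$occurrences_raw,
                   file.path(dir, "occurrences.csv"), row.names = FALSE)
  gref <- world$stack$layers[[1]]
  write_grid(climate_grid(world$protected_mask + 0, gref$origin_lon,
                          gref$origin_lat, gref$cell_size,
                          variable = "protected_mask"),
             file.path(dir, "protected_mask.asc"))
  truth <- sprintf(
    '{"driving_variables": [%s], "mu": [%s], "sigma": [%s], "seed": %d}',
    paste(sprintf('"%s"', names(world$niche$mu)), collapse = ", "),
    paste(sprintf("%.17g", world$niche$mu), collapse = ", "),
    paste(sprintf("%.17g", world$niche$sigma), collapse = ", "),
    world$seed)
  writeLines(truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world: %d x %d grid, %d variables, %d occurrence pixels, %d scenario(s), seed %d>\n",
              nrow(x$stack$valid_mask), ncol(x$stack$valid_mask),
              length(x$stack$layers), nrow(x$occurrences),
              length(x$scenarios), x$seed))
  invisible(x)
}
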
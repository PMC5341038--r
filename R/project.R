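#' Project a fitted model onto a climate scenario
#'
#' Features are computed with the *training* (min, max) bounds; with
#' `clamp = TRUE` scaled features are truncated to `[0, 1]` where the
#' scenario climate leaves the training range.  Projecting onto the training
#' stack reproduces the training map exactly.
#'
#' @param model a [maxent_fit()] model.
#' @param scenario a [align_stack()] stack containing the model's variables.
#' @param clamp clamp features to the training range (default `TRUE`).
#' @param type output scale (default `"logistic"`).
#' @return suitability matrix with attribute `clamped_fraction` (share of
#'   valid cells where any feature was clamped).
#' @export
project <- function(model, scenario, clamp = TRUE, type = "logistic") {
  predict(model, stack = scenario, type = type, clamp = clamp)
}

#' Project a cross-validated ensemble onto a scenario
#'
#' Each of the k fold models is projected, binarized at its own MSS
#' threshold, and the consensus machinery (agreement counts, >= 95%
#' refinement of the averaged map) is applied on the scenario — the same
#' uncertainty treatment as on the training climate.
#'
#' @param cv a [cross_validate()] result.
#' @param scenario target [align_stack()] stack.
#' @param clamp clamp features to the training range.
#' @param min_agreement consensus fraction (default 0.95).
#' @return a `scenario_projection`: list with `scenario_id`, `standard_map`,
#'   `agreement`, `refined` ([refine()] output), `binary_map` (refined map
#'   cut at the ensemble threshold), `threshold`, `clamped_fraction`.
#' @export
project_cv <- function(cv, scenario, clamp = TRUE, min_agreement = 0.95) {
  k <- cv$k
  maps <- vector("list", k)
  bins <- vector("list", k)
  clamped <- numeric(k)
  for (f in seq_len(k)) {
    m <- project(cv$models[[f]], scenario, clamp = clamp)
    clamped[f] <- attr(m, "clamped_fraction")
    maps[[f]] <- m
    bins[[f]] <- binarize(m, cv$fold_stats$mss_threshold[f])
  }
  standard <- Reduce(`+`, maps) / k
  agr <- agreement(bins)
  ref <- refine(standard, agr, min_agreement)
  structure(list(scenario_id = scenario$scenario_id,
                 standard_map = standard, agreement = agr, refined = ref,
                 binary_map = !is.na(ref$values) & ref$values >= cv$threshold,
                 threshold = cv$threshold,
                 clamped_fraction = mean(clamped)),
            class = "scenario_projection")
}

#' @export
print.scenario_projection <- function(x, ...) {
  cat(sprintf("<scenario_projection '%s': %d suitable pixels at tau = %.4f (%.1f%% cells clamped)>\n",
              x$scenario_id, sum(x$binary_map, na.rm = TRUE), x$threshold,
              100 * x$clamped_fraction))
  invisible(x)
}

#' Suitability-band area accounting
#'
#' Total suitable area (`value >= tau`), split into a low band
#' `[tau, 0.5)` and a high band `[0.5, 1]` (the high edge owns 0.5), in km2.
#'
#' @param map continuous suitability matrix (e.g. a refined map; `NA` =
#'   unsuitable/invalid).
#' @param tau suitability threshold; must be below the 0.5 band split.
#' @param areas km2 cell-area matrix from [cell_areas()].
#' @return data frame with `total_km2`, `low_km2`, `high_km2`,
#'   `high_fraction` (high/total).
#' @export
band_areas <- function(map, tau, areas) {
  if (tau >= 0.5)
    stop("band-definition error: threshold ", tau, " is not below 0.5")
  if (!all(dim(map) == dim(areas))) stop("geometry mismatch")
  ok <- !is.na(map)
  tot <- sum(areas[ok & map >= tau])
  high <- sum(areas[ok & map >= 0.5])
  low <- sum(areas[ok & map >= tau & map < 0.5])
  data.frame(total_km2 = tot, low_km2 = low, high_km2 = high,
             high_fraction = if (tot > 0) high / tot else NA_real_)
}

#' Between-scenario overlap, gain and loss accounting
#'
#' Intersects two binary suitability maps and reports the km2 overlap, the
#' overlap as a percentage of each map's area, the absolute and signed
#' relative difference of A with respect to the reference B, and the gained
#' (`A` only) and lost (`B` only) areas.
#'
#' @param map_A binary matrix for the scenario of interest.
#' @param map_B binary matrix for the reference (e.g. present).
#' @param areas km2 cell-area matrix.
#' @return one-row data frame: `area_A_km2`, `area_B_km2`, `overlap_km2`,
#'   `pct_of_A`, `pct_of_B`, `diff_km2` (absolute), `diff_pct` (signed,
#'   relative to B), `gained_km2`, `lost_km2`.
#' @export
overlap_analysis <- function(map_A, map_B, areas) {
  if (!all(dim(map_A) == dim(map_B)) || !all(dim(map_A) == dim(areas)))
    stop("geometry mismatch")
  a <- !is.na(map_A) & map_A
  b <- !is.na(map_B) & map_B
  area_a <- sum(areas[a]); area_b <- sum(areas[b])
  ov <- sum(areas[a & b])
  data.frame(area_A_km2 = area_a, area_B_km2 = area_b, overlap_km2 = ov,
             pct_of_A = if (area_a > 0) 100 * ov / area_a else NA_real_,
             pct_of_B = if (area_b > 0) 100 * ov / area_b else NA_real_,
             diff_km2 = abs(area_b - area_a),
             diff_pct = if (area_b > 0) 100 * (area_a - area_b) / area_b else NA_real_,
             gained_km2 = area_a - ov, lost_km2 = area_b - ov)
}

#' Range-accounting report with period averages
#'
#' Takes per-scenario km2 accounting (total and band areas, overlap with a
#' reference scenario) and emits the standard range-change table: one row per
#' scenario with every derived percentage, plus an arithmetic-mean row per
#' period.  Percentage columns of the average rows are reported in both
#' conventions — the mean of the per-scenario percentages (`*_pct`,
#' mean-of-ratios) and the percentage recomputed from the period-mean areas
#' (`*_pct_rom`, ratio-of-means) — because the two differ and published
#' tables mix them.
#'
#' @param df data frame with columns `model`, `period`, `total_km2`,
#'   `low_km2`, `high_km2`, `overlap_km2` (overlap with the reference; `NA`
#'   for the reference row itself).
#' @param present name of the reference scenario in `model` (default
#'   `"present"`, matched case-insensitively).
#' @return data frame with per-scenario rows followed by one `average <period>`
#'   row per non-reference period (`is_average` flags them); columns include
#'   `high_fraction_pct`, `diff_km2`, `diff_pct`, `overlap_pct_of_model`,
#'   `overlap_pct_of_present`, and `_rom` variants on average rows.
#' @export
scenario_table <- function(df, present = "present") {
  ip <- which(tolower(df$model) == tolower(present))
  if (length(ip) != 1) stop("need exactly one reference row named '",
                            present, "'")
  pres_total <- df$total_km2[ip]
  out <- df
  out$high_fraction_pct <- 100 * out$high_km2 / out$total_km2
  out$diff_km2 <- abs(pres_total - out$total_km2)
  out$diff_pct <- 100 * (out$total_km2 - pres_total) / pres_total
  out$overlap_pct_of_model <- 100 * out$overlap_km2 / out$total_km2
  out$overlap_pct_of_present <- 100 * out$overlap_km2 / pres_total
  out$diff_km2[ip] <- out$diff_pct[ip] <- NA_real_
  out$is_average <- FALSE
  avg_rows <- lapply(setdiff(unique(out$period[-ip]), NA), function(per) {
    g <- out[-ip, ][out$period[-ip] == per, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    avg <- g[1, , drop = FALSE]
    avg$model <- paste("average", per)
    num <- c("total_km2", "low_km2", "high_km2", "overlap_km2",
             "high_fraction_pct", "diff_km2", "diff_pct",
             "overlap_pct_of_model", "overlap_pct_of_present")
    for (cn in num) avg[[cn]] <- mean(g[[cn]])
    # ratio-of-means variants recomputed from the period-mean areas
    avg$high_fraction_pct_rom <- 100 * avg$high_km2 / avg$total_km2
    avg$diff_pct_rom <- 100 * (avg$total_km2 - pres_total) / pres_total
    avg$overlap_pct_of_model_rom <- 100 * avg$overlap_km2 / avg$total_km2
    avg$overlap_pct_of_present_rom <- 100 * avg$overlap_km2 / pres_total
    avg$is_average <- TRUE
    avg
  })
  out$high_fraction_pct_rom <- NA_real_
  out$diff_pct_rom <- NA_real_
  out$overlap_pct_of_model_rom <- NA_real_
  out$overlap_pct_of_present_rom <- NA_real_
  res <- rbind(out, do.call(rbind, avg_rows))
  rownames(res) <- NULL
  res
}

#' Protected-area coverage of a suitable range
#'
#' Partitions the suitable area of a binary map into the parts inside and
#' outside a protected-area mask.
#'
#' @param binary_map binary suitability matrix.
#' @param protected_mask logical matrix (TRUE = protected).
#' @param areas km2 cell-area matrix.
#' @return one-row data frame: `inside_km2`, `outside_km2`, `total_km2`,
#'   `pct_outside`.
#' @export
protection_overlap <- function(binary_map, protected_mask, areas) {
  if (!all(dim(binary_map) == dim(protected_mask)) ||
      !all(dim(binary_map) == dim(areas)))
    stop("geometry mismatch")
  s <- !is.na(binary_map) & binary_map
  inside <- sum(areas[s & protected_mask])
  outside <- sum(areas[s & !protected_mask])
  tot <- inside + outside
  data.frame(inside_km2 = inside, outside_km2 = outside, total_km2 = tot,
             pct_outside = if (tot > 0) 100 * outside / tot else NA_real_)
}
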
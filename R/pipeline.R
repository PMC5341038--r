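#' Pipeline configuration
#'
#' Bundles and validates every tunable of the analysis chain.  Defaults are
#' the study conventions: correlation grouping at `|r| >= 0.85`, VIF
#' exclusion above 10, at most 2 variables per collinearity group, 10000
#' background points, 20-fold cross-validation, 95% consensus refinement,
#' and a 0.5 low/high band split.
#'
#' @param r_threshold correlation-grouping threshold.
#' @param vif_max VIF exclusion threshold.
#' @param max_per_group max variables per collinearity group in a candidate.
#' @param min_subset minimum candidate subset size.
#' @param background_n background sample size.
#' @param k_folds number of cross-validation folds.
#' @param min_agreement consensus fraction for refinement.
#' @param band_split low/high suitability band boundary.
#' @param beta_multiplier L1 regularization multiplier.
#' @param clamp clamp projected features to the training range.
#' @param include_presence add presence cells to the background.
#' @param seed master seed for background sampling and fold assignment.
#' @return a validated `sdm_config` list.
#' @export
sdm_config <- function(r_threshold = 0.85, vif_max = 10, max_per_group = 2,
                       min_subset = 2, background_n = 10000, k_folds = 20,
                       min_agreement = 0.95, band_split = 0.5,
                       beta_multiplier = 1.0, clamp = TRUE,
                       include_presence = TRUE, seed = 1) {
  if (r_threshold <= 0 || r_threshold > 1)
    stop("validation error: r_threshold must be in (0, 1]")
  if (vif_max < 1) stop("validation error: vif_max must be >= 1")
  if (k_folds < 2) stop("validation error: k_folds must be >= 2")
  if (min_agreement < 0 || min_agreement > 1)
    stop("validation error: min_agreement must be in [0, 1]")
  if (band_split <= 0 || band_split >= 1)
    stop("validation error: band_split must be in (0, 1)")
  if (background_n < 10) stop("validation error: background_n too small")
  if (beta_multiplier < 0) stop("validation error: beta_multiplier < 0")
  structure(list(r_threshold = r_threshold, vif_max = vif_max,
                 max_per_group = max_per_group, min_subset = min_subset,
                 background_n = background_n, k_folds = k_folds,
                 min_agreement = min_agreement, band_split = band_split,
                 beta_multiplier = beta_multiplier, clamp = clamp,
                 include_presence = include_presence,
                 seed = as.integer(seed)),
            class = "sdm_config")
}

#' Run the full modelling pipeline
#'
#' Chains every stage on one training stack: background sampling, exhaustive
#' AICc variable selection, a full-data fit, k-fold cross-validation of the
#' winning subset, consensus refinement, projection of the ensemble onto
#' each scenario, and km2 range accounting (band areas, overlap/gain/loss
#' vs the present, protected-area coverage).  Identical inputs and config
#' give identical outputs.
#'
#' @param stack training (present) [align_stack()] stack.
#' @param occurrences an `occurrence_set`, or a CSV path / data frame
#'   (then deduplicated against `stack`).
#' @param scenarios named list of scenario [align_stack()] stacks.
#' @param protected_mask optional logical matrix (TRUE = protected).
#' @param config an [sdm_config()].
#' @param variables optional fixed variable subset; skips selection.
#' @param out_dir optional directory; when given, the selection report, CV
#'   report and range table are written as CSV and each refined map as an
#'   ESRI ASCII grid.
#' @return an `sdm_pipeline` list: `config`, `selection`, `fit` (full-data
#'   model), `cv`, `projections` (per scenario incl. `present`), `table`
#'   (range-accounting report from [scenario_table()]), `protection`
#'   (per-scenario coverage or `NULL`), `provenance`.
#' @export
run_pipeline <- function(stack, occurrences, scenarios = list(),
                         protected_mask = NULL, config = sdm_config(),
                         variables = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "sdm_config"))
  if (!inherits(occurrences, "occurrence_set"))
    occurrences <- load_occurrences(occurrences, stack)
  background <- sample_background(stack, config$background_n, config$seed)
  selection <- NULL
  if (is.null(variables)) {
    selection <- select_variables(occurrences, background, stack,
                                  r_threshold = config$r_threshold,
                                  vif_max = config$vif_max,
                                  max_per_group = config$max_per_group,
                                  min_size = config$min_subset,
                                  beta_multiplier = config$beta_multiplier)
    variables <- selection$winner
  }
  fit <- maxent_fit(occurrences, background, stack, variables = variables,
                    beta_multiplier = config$beta_multiplier,
                    include_presence = config$include_presence)
  cv <- cross_validate(occurrences, background, stack, variables = variables,
                       k = config$k_folds, seed = config$seed,
                       beta_multiplier = config$beta_multiplier,
                       include_presence = config$include_presence)
  areas <- cell_areas(stack)
  all_stacks <- c(list(present = stack), scenarios)
  projections <- lapply(all_stacks, function(s)
    project_cv(cv, s, clamp = config$clamp,
               min_agreement = config$min_agreement))
  names(projections) <- names(all_stacks)
  rows <- lapply(names(projections), function(id) {
    pr <- projections[[id]]
    ba <- band_areas(pr$refined$values, cv$threshold, areas)
    ov <- if (id == "present") NA_real_ else
      overlap_analysis(pr$binary_map, projections$present$binary_map,
                       areas)$overlap_km2
    data.frame(model = id, period = if (id == "present") "present" else id,
               total_km2 = ba$total_km2, low_km2 = ba$low_km2,
               high_km2 = ba$high_km2, overlap_km2 = ov,
               stringsAsFactors = FALSE)
  })
  tab <- scenario_table(do.call(rbind, rows), present = "present")
  protection <- NULL
  if (!is.null(protected_mask)) {
    protection <- do.call(rbind, lapply(names(projections), function(id)
      cbind(model = id,
            protection_overlap(projections[[id]]$binary_map,
                               protected_mask, areas))))
  }
  provenance <- list(package_version = as.character(utils::packageVersion("maxsdm")),
                     seed = config$seed,
                     config_hash = config_hash(config),
                     n_occurrences = nrow(occurrences),
                     variables = variables)
  res <- structure(list(config = config, selection = selection, fit = fit,
                        cv = cv, projections = projections, table = tab,
                        protection = protection, provenance = provenance),
                   class = "sdm_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, stack, out_dir)
  res
}

config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 17), collapse = ","), ""), collapse = ";")
  # small deterministic rolling hash (no extra deps)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_pipeline <- function(res, stack, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# maxsdm %s | seed %d | config %s | variables %s",
                 res$provenance$package_version, res$provenance$seed,
                 res$provenance$config_hash,
                 paste(res$provenance$variables, collapse = "+"))
  wcsv <- function(df, file) {
    con <- file.path(out_dir, file)
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(df, con, append = TRUE, sep = ",",
                                        row.names = FALSE, quote = FALSE))
  }
  if (!is.null(res$selection)) wcsv(res$selection$ranked, "selection_report.csv")
  wcsv(summary(res$cv), "cv_report.csv")
  wcsv(res$table, "range_table.csv")
  if (!is.null(res$protection)) wcsv(res$protection, "protection_report.csv")
  g <- stack$layers[[1]]
  for (id in names(res$projections)) {
    m <- res$projections[[id]]$refined$values
    write_grid(climate_grid(m, g$origin_lon, g$origin_lat, g$cell_size,
                            variable = paste0("refined_", id)),
               file.path(out_dir, paste0("refined_", id, ".asc")))
  }
  invisible(out_dir)
}

#' @export
print.sdm_pipeline <- function(x, ...) {
  cat("<sdm_pipeline>\n")
  cat("  variables:", paste(x$provenance$variables, collapse = ", "), "\n")
  cat(sprintf("  CV AUC = %.3f +/- %.3f, threshold = %.4f\n",
              x$cv$auc_mean, x$cv$auc_sd, x$cv$threshold))
  cat(sprintf("  scenarios: %s\n", paste(names(x$projections), collapse = ", ")))
  invisible(x)
}
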
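#' Virtual-species recovery experiment
#'
#' The package's end-to-end validation harness.  For each seed it builds a
#' default synthetic world (known Gaussian niche on `v1` and `v2`, nuisance
#' variables with one strongly collinear pair), runs the full pipeline —
#' background sampling, exhaustive AICc selection, k-fold cross-validation,
#' consensus refinement — and scores the run against the known truth:
#' whether the selected subset contains both true drivers, the
#' cross-validated AUC, the Jaccard overlap between the refined present-day
#' binary map and the true range (true suitability binarized at its own MSS
#' threshold), and whether a warming-shifted scenario projects a smaller
#' suitable area than the present.
#'
#' @param seeds integer vector of world seeds (one replicate per seed).
#' @param background_n background sample size per replicate (default 2000,
#'   the default-world setting).
#' @param k cross-validation folds (default 20).
#' @param n_raw raw occurrence draws per world (default 250).
#' @param n_rows,n_cols,n_vars world dimensions (defaults 150 x 150, 8).
#' @return data frame with one row per seed: `seed`, `winner`,
#'   `drivers_selected`, `auc`, `jaccard`, `present_km2`, `warming_km2`,
#'   `contracted`, `success` (drivers selected & AUC >= 0.9 &
#'   Jaccard >= 0.6).
#' @export
recovery_experiment <- function(seeds = 1:20, background_n = 2000, k = 20,
                                n_raw = 250, n_rows = 150, n_cols = 150,
                                n_vars = 8) {
  rows <- lapply(seeds, function(sd) {
    w <- synthetic_world(n_vars = n_vars, n_rows = n_rows, n_cols = n_cols,
                         n_raw = n_raw, seed = sd)
    bg <- sample_background(w$stack, background_n, seed = sd + 5000L)
    sel <- select_variables(w$occurrences, bg, w$stack)
    cv <- cross_validate(w$occurrences, bg, w$stack,
                         variables = sel$winner, k = k, seed = sd)
    pres <- project_cv(cv, w$stack)
    warm <- project_cv(cv, w$scenarios$warming2070)
    areas <- cell_areas(w$stack)
    a_pres <- band_areas(pres$refined$values, cv$threshold, areas)$total_km2
    a_warm <- band_areas(warm$refined$values, cv$threshold, areas)$total_km2
    # true range: the known suitability surface binarized at its own MSS
    # threshold (presence scores vs background scores on the true surface)
    ts <- w$truth$present
    tau_true <- mss_threshold(ts[cbind(w$occurrences$row, w$occurrences$col)],
                              ts[cbind(bg$cells[, 1], bg$cells[, 2])])
    true_bin <- binarize(ts, tau_true)
    pb <- pres$binary_map
    A <- !is.na(pb) & pb; B <- !is.na(true_bin) & true_bin
    jac <- sum(A & B) / sum(A | B)
    drivers <- all(c("v1", "v2") %in% sel$winner)
    data.frame(seed = sd, winner = paste(sel$winner, collapse = "+"),
               drivers_selected = drivers, auc = cv$auc_mean, jaccard = jac,
               present_km2 = a_pres, warming_km2 = a_warm,
               contracted = a_warm < a_pres,
               success = drivers && cv$auc_mean >= 0.9 && jac >= 0.6,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
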
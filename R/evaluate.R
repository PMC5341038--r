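#' Random k-fold plan for occurrence records
#'
#' Random partition into k folds whose sizes differ by at most one,
#' reproducible by seed.
#'
#' @param n number of occurrence records (or an `occurrence_set`).
#' @param k number of folds (default 20).
#' @param seed integer seed.
#' @return integer vector of fold indices (1..k), one per record.
#' @export
make_folds <- function(n, k = 20, seed = 1) {
  if (inherits(n, "occurrence_set")) n <- nrow(n)
  if (n < k) stop("fold error: n = ", n, " records for k = ", k, " folds")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Rank-based AUC (Mann-Whitney, ties count one half)
#'
#' The probability that a random presence outscores a random background
#' point, with ties counted 1/2 — the standard presence/background ROC AUC.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("evaluation error: empty score vector")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans the unique observed scores as candidate cutoffs under the inclusive
#' classification rule `score >= tau`, and returns the cutoff maximizing
#' sensitivity + specificity; ties go to the smallest cutoff.
#'
#' @param presence_scores,background_scores numeric score vectors
#'   (presences are positives, background negatives).
#' @return the MSS threshold.
#' @export
mss_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("evaluation error: empty score vector")
  cand <- sort(unique(c(presence_scores, background_scores)))
  np <- length(presence_scores); nb <- length(background_scores)
  # vectorized: for each candidate tau, sens = P(pres >= tau), spec = P(bg < tau)
  sens <- 1 - (findInterval(cand, sort(presence_scores), left.open = TRUE)) / np
  spec <- findInterval(cand, sort(background_scores), left.open = TRUE) / nb
  ss <- sens + spec
  cand[which.max(ss)]   # which.max returns the first (smallest) maximizer
}

#' k-fold cross-validation of a maxent model
#'
#' Fits one model per fold on the k-1 training bins of presences against the
#' shared background, scores the held-out presences against the background
#' for the fold AUC, and computes each fold's MSS threshold on its own
#' *training* presences vs the background.  The "standard" continuous map is
#' the pixelwise mean of the k logistic fold maps; its display threshold is
#' the mean of the k fold thresholds.
#'
#' @param occurrences an `occurrence_set` on `stack`.
#' @param background shared [sample_background()] sample (not re-sampled per
#'   fold).
#' @param stack training [align_stack()] stack.
#' @param variables variables to fit.
#' @param k number of folds (default 20).
#' @param seed fold-assignment seed.
#' @param beta_multiplier,include_presence passed to [maxent_fit()].
#' @return a `maxent_cv` object: `models` (list of k fits), `folds`,
#'   `fold_stats` (data frame: fold, n_train, n_test, auc, mss_threshold),
#'   `auc_mean`, `auc_sd`, `threshold` (mean of fold thresholds),
#'   `standard_map` (matrix), `binary_maps` (list of k logical matrices,
#'   each fold's logistic map cut at its own threshold).
#' @export
cross_validate <- function(occurrences, background, stack,
                           variables = names(stack$layers), k = 20,
                           seed = 1, beta_multiplier = 1.0,
                           include_presence = TRUE) {
  folds <- make_folds(nrow(occurrences), k, seed)
  cells <- occ_cells(occurrences)
  bg_raw <- background$values[, variables, drop = FALSE]
  models <- vector("list", k)
  stats_rows <- vector("list", k)
  maps <- vector("list", k)
  binmaps <- vector("list", k)
  for (f in seq_len(k)) {
    train <- cells[folds != f, , drop = FALSE]
    test <- cells[folds == f, , drop = FALSE]
    fit <- tryCatch(
      maxent_fit(train, background, stack, variables = variables,
                 beta_multiplier = beta_multiplier,
                 include_presence = include_presence),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e)))
    train_sc <- predict(fit, newdata = stack_values(stack, train, variables))
    test_sc <- predict(fit, newdata = stack_values(stack, test, variables))
    bg_sc <- predict(fit, newdata = bg_raw)
    tau <- mss_threshold(train_sc, bg_sc)
    a <- auc(test_sc, bg_sc)
    map <- predict(fit, stack = stack)
    models[[f]] <- fit
    maps[[f]] <- map
    binmaps[[f]] <- binarize(map, tau)
    stats_rows[[f]] <- data.frame(fold = f, n_train = nrow(train),
                                  n_test = nrow(test), auc = a,
                                  mss_threshold = tau)
  }
  fold_stats <- do.call(rbind, stats_rows)
  standard <- Reduce(`+`, maps) / k
  structure(list(models = models, folds = folds, fold_stats = fold_stats,
                 auc_mean = mean(fold_stats$auc),
                 auc_sd = stats::sd(fold_stats$auc),
                 threshold = mean(fold_stats$mss_threshold),
                 standard_map = standard, binary_maps = binmaps,
                 variables = variables, k = k, seed = seed),
            class = "maxent_cv")
}

#' @export
print.maxent_cv <- function(x, ...) {
  cat(sprintf("<maxent_cv: %d folds on {%s}>\n", x$k,
              paste(x$variables, collapse = ", ")))
  cat(sprintf("  AUC = %.3f +/- %.3f   mean MSS threshold = %.4f\n",
              x$auc_mean, x$auc_sd, x$threshold))
  invisible(x)
}

#' @export
summary.maxent_cv <- function(object, ...) {
  out <- object$fold_stats
  out <- rbind(out, data.frame(fold = NA, n_train = NA, n_test = NA,
                               auc = object$auc_mean,
                               mss_threshold = object$threshold))
  rownames(out) <- c(paste0("fold", seq_len(object$k)), "mean")
  out
}

#' Binarize a continuous suitability map
#'
#' Presence iff `value >= tau` (inclusive) on valid pixels; invalid (`NA`)
#' pixels stay `NA`.
#'
#' @param map numeric matrix.
#' @param tau threshold.
#' @return logical matrix with `NA` preserved.
#' @export
binarize <- function(map, tau) {
  if (!is.finite(tau)) stop("threshold must be finite")
  map >= tau
}

#' Model-agreement (uncertainty) map
#'
#' Pixelwise count of how many of the k binary maps predict suitability,
#' plus the count expressed as a probability (count / k).
#'
#' @param binary_maps list of k logical matrices with identical geometry.
#' @return list with `counts` (integer matrix in `[0, k]`), `probability`
#'   (`counts / k`), `k`.
#' @export
agreement <- function(binary_maps) {
  k <- length(binary_maps)
  dm <- dim(binary_maps[[1]])
  for (b in binary_maps)
    if (!all(dim(b) == dm)) stop("geometry mismatch among binary maps")
  counts <- Reduce(`+`, lapply(binary_maps, function(b) {
    m <- matrix(0L, dm[1], dm[2]); m[which(b)] <- 1L; m
  }))
  counts[is.na(binary_maps[[1]])] <- NA_integer_
  list(counts = counts, probability = counts / k, k = k)
}

#' Consensus-refined suitability map
#'
#' Retains the standard (averaged) map only where at least
#' `ceiling(min_agreement * k)` of the k models predict presence (19 of 20
#' at the default 95% consensus); all other pixels are marked unsuitable
#' (`NA`).  The refined suitable area can only shrink relative to the
#' standard map.
#'
#' @param standard_map pixelwise mean of the k logistic maps.
#' @param agreement output of [agreement()].
#' @param min_agreement consensus fraction (default 0.95).
#' @return list with `values` (masked standard map), `min_agreement`,
#'   `min_count`.
#' @export
refine <- function(standard_map, agreement, min_agreement = 0.95) {
  if (!all(dim(standard_map) == dim(agreement$counts)))
    stop("geometry mismatch between standard map and agreement map")
  min_count <- ceiling(min_agreement * agreement$k)
  out <- standard_map
  out[is.na(agreement$counts) | agreement$counts < min_count] <- NA_real_
  list(values = out, min_agreement = min_agreement, min_count = min_count)
}
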
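#' Sample background (pseudo-absence) cells
#'
#' Uniform sampling without replacement over the valid cells of a stack.
#'
#' @param stack a [align_stack()] output.
#' @param n number of background cells (default 10000).
#' @param seed integer seed; the sample is reproducible given the seed.
#' @return a `background_sample`: list with `cells` (row/col matrix),
#'   `values` (cells x variables matrix of raw layer values), `n`, `seed`.
#' @export
sample_background <- function(stack, n = 10000, seed = 1) {
  valid_idx <- which(stack$valid_mask)
  if (n > length(valid_idx))
    stop("sampling error: n = ", n, " exceeds the ", length(valid_idx),
         " valid cells")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  take <- if (n == length(valid_idx)) valid_idx else sort(sample(valid_idx, n))
  nr <- nrow(stack$valid_mask)
  cells <- cbind(row = ((take - 1L) %% nr) + 1L,
                 col = ((take - 1L) %/% nr) + 1L)
  structure(list(cells = cells,
                 values = stack_values(stack, cells),
                 n = n, seed = seed),
            class = "background_sample")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pearson correlation matrix over pooled presence + background values
#'
#' @param values numeric matrix, rows = points (presence and background
#'   pooled), columns = variables.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("need at least 3 points for correlations")
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate-variable error: zero variance in ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  r <- stats::cor(values)
  diag(r) <- 1
  r
}

#' Group collinear variables by correlation threshold
#'
#' Variables are grouped as the connected components of the graph with an
#' edge wherever `|r| >= r_threshold` — the transitive closure of "strongly
#' collinear with".
#'
#' @param corr correlation matrix (from [pearson_matrix()]).
#' @param r_threshold absolute-correlation threshold, default 0.85.
#' @return list of character vectors, a partition of the variable names.
#' @export
group_correlated <- function(corr, r_threshold = 0.85) {
  vars <- colnames(corr)
  if (is.null(vars)) vars <- paste0("v", seq_len(ncol(corr)))
  adj <- abs(corr) >= r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(vars, comp))
}

#' Enumerate candidate variable subsets
#'
#' All subsets of size `>= min_size` that contain at most `max_per_group`
#' variables from any single collinearity group, in lexicographic order of
#' the input variable ordering.
#'
#' @param variables character vector of variable names.
#' @param grouping partition from [group_correlated()].
#' @param max_per_group maximum members of one group per subset (default 2).
#' @param min_size minimum subset size (default 2).
#' @return list of character vectors.
#' @export
enumerate_candidates <- function(variables, grouping,
                                 max_per_group = 2, min_size = 2) {
  group_of <- integer(length(variables))
  names(group_of) <- variables
  for (i in seq_along(grouping)) group_of[grouping[[i]]] <- i
  if (any(group_of == 0))
    stop("grouping does not cover variable(s): ",
         paste(variables[group_of == 0], collapse = ", "))
  p <- length(variables)
  out <- vector("list", 0)
  # lexicographic enumeration by increasing size, combn order within size
  for (size in seq(max(min_size, 1L), p)) {
    cmb <- utils::combn(p, size)
    for (j in seq_len(ncol(cmb))) {
      idx <- cmb[, j]
      if (max(tabulate(group_of[idx], nbins = length(grouping))) <= max_per_group)
        out[[length(out) + 1L]] <- variables[idx]
    }
  }
  out
}

#' Variance inflation factors for a variable subset
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of variable `j` on the remaining subset members.  Perfect
#' collinearity yields `Inf` (and a failed screen), not an error.
#'
#' @param values pooled presence + background value matrix (columns named).
#' @param subset character vector of variable names, length >= 2.
#' @param vif_max screening threshold, default 10.
#' @return list with `vif` (named vector), `max_vif`, `pass`.
#' @export
vif_screen <- function(values, subset, vif_max = 10) {
  if (length(subset) < 2) stop("VIF needs a subset of at least 2 variables")
  X <- as.matrix(values[, subset, drop = FALSE])
  if (nrow(X) <= length(subset) + 1)
    stop("sample too small for VIF on ", length(subset), " variables")
  v <- vapply(seq_along(subset), function(j) {
    y <- X[, j]
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(v) <- subset
  list(vif = v, max_vif = max(v), pass = all(v <= vif_max))
}

#' AICc of a fitted maximum-entropy model
#'
#' The likelihood follows the established convention for information-criterion
#' scoring of presence-background maxent models: the raw exponential model is
#' normalized over *all* valid study-area cells, the log-likelihood is the sum
#' of log normalized scores at the occurrence cells, and `k` counts the
#' coefficients with nonzero weight after L1 fitting.
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`.
#'
#' @param model a fitted [maxent_fit()] object.
#' @param occurrences an `occurrence_set` (or row/col matrix) of the `n`
#'   training presences.
#' @param stack the training [align_stack()] stack defining the valid cells.
#' @return list with `log_likelihood`, `k`, `n`, `aicc`.
#' @export
score_aicc <- function(model, occurrences, stack) {
  cells <- if (inherits(occurrences, "occurrence_set"))
    occ_cells(occurrences) else as.matrix(occurrences)
  n <- nrow(cells)
  k <- sum(model$coefficients != 0)
  if (n - k - 1 <= 0)
    stop("AICc undefined: n = ", n, " occurrences for k = ", k, " parameters")
  eta_all <- feature_eta(model, stack_values(stack, NULL, model$variables))
  eta_occ <- feature_eta(model, stack_values(stack, cells, model$variables))
  lnZ_cells <- logsumexp(eta_all)
  lnL <- sum(eta_occ) - n * lnZ_cells
  list(log_likelihood = lnL, k = k, n = n,
       aicc = 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1))
}

#' Exhaustive AICc-based variable selection
#'
#' The full selection sequence: Pearson correlations on pooled presence +
#' background points, correlation grouping at `|r| >= r_threshold`,
#' enumeration of candidate subsets (at most `max_per_group` per group),
#' VIF screening, a maxent fit per surviving candidate, and AICc ranking.
#' Ties in AICc are broken by smaller `k`, then lexicographic subset order.
#'
#' @param occurrences an `occurrence_set` on `stack`.
#' @param background a [sample_background()] sample.
#' @param stack training [align_stack()] stack.
#' @param r_threshold correlation-grouping threshold (default 0.85).
#' @param vif_max VIF exclusion threshold (default 10).
#' @param max_per_group,min_size candidate-subset constraints.
#' @param beta_multiplier L1 regularization multiplier passed to the fits.
#' @return an `sdm_selection`: list with `winner` (character subset),
#'   `ranked` (data frame: subset, k, max_vif, vif_pass, logL, AICc,
#'   delta_AICc, rank), `grouping`, `correlation`, `n_candidates`.
#' @export
select_variables <- function(occurrences, background, stack,
                             r_threshold = 0.85, vif_max = 10,
                             max_per_group = 2, min_size = 2,
                             beta_multiplier = 1.0) {
  pres_vals <- stack_values(stack, occ_cells(occurrences))
  pooled <- rbind(pres_vals, background$values)
  corr <- pearson_matrix(pooled)
  grouping <- group_correlated(corr, r_threshold)
  vars <- colnames(pooled)
  cands <- enumerate_candidates(vars, grouping, max_per_group, min_size)
  all_vals <- stack_values(stack)  # all valid cells, for AICc normalization
  occ_vals <- pres_vals
  rows <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    sub <- cands[[i]]
    vf <- vif_screen(pooled, sub, vif_max)
    row <- data.frame(subset = paste(sub, collapse = "+"),
                      size = length(sub), max_vif = vf$max_vif,
                      vif_pass = vf$pass, k = NA_real_,
                      logL = NA_real_, AICc = NA_real_,
                      stringsAsFactors = FALSE)
    if (vf$pass) {
      fit <- maxent_fit(occurrences, background, stack, variables = sub,
                        beta_multiplier = beta_multiplier)
      sc <- score_aicc_values(fit, occ_vals[, sub, drop = FALSE],
                              all_vals[, sub, drop = FALSE],
                              nrow(occ_vals))
      row$k <- sc$k; row$logL <- sc$log_likelihood; row$AICc <- sc$aicc
    }
    rows[[i]] <- row
  }
  ranked <- do.call(rbind, rows)
  ok <- which(ranked$vif_pass & is.finite(ranked$AICc))
  if (!length(ok)) stop("selection error: no candidate passes the VIF screen")
  ord <- ok[order(ranked$AICc[ok], ranked$k[ok], ranked$subset[ok])]
  ranked$delta_AICc <- ranked$AICc - ranked$AICc[ord[1]]
  ranked$rank <- NA_integer_
  ranked$rank[ord] <- seq_along(ord)
  structure(list(winner = cands[[ord[1]]],
                 ranked = ranked[order(ranked$rank, na.last = TRUE), ],
                 grouping = grouping, correlation = corr,
                 n_candidates = length(cands)),
            class = "sdm_selection")
}

# AICc from precomputed raw-value matrices (avoids re-extracting per subset)
score_aicc_values <- function(model, occ_vals, all_vals, n) {
  k <- sum(model$coefficients != 0)
  if (n - k - 1 <= 0)
    stop("AICc undefined: n = ", n, " occurrences for k = ", k, " parameters")
  lnZ_cells <- logsumexp(feature_eta(model, all_vals))
  lnL <- sum(feature_eta(model, occ_vals)) - n * lnZ_cells
  list(log_likelihood = lnL, k = k, n = n,
       aicc = 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1))
}

#' Rank already-scored candidates
#'
#' Minimum AICc among VIF-passing candidates; ties broken by smaller `k`,
#' then lexicographic subset label.  Permutation-invariant over input order.
#'
#' @param scored data frame with columns `subset`, `k`, `vif_pass`, `AICc`.
#' @return the winning row.
#' @export
select_best <- function(scored) {
  ok <- which(scored$vif_pass & is.finite(scored$AICc))
  if (!length(ok)) stop("selection error: no candidate passes the VIF screen")
  ord <- ok[order(scored$AICc[ok], scored$k[ok], scored$subset[ok])]
  scored[ord[1], , drop = FALSE]
}

#' @export
print.sdm_selection <- function(x, ...) {
  cat(sprintf("<sdm_selection: %d candidates, winner = {%s}>\n",
              x$n_candidates, paste(x$winner, collapse = ", ")))
  cat("  groups:", paste(vapply(x$grouping, paste, "", collapse = "+"),
                         collapse = " | "), "\n")
  print(utils::head(x$ranked[, c("subset", "k", "max_vif", "AICc",
                                 "delta_AICc", "rank")], 5))
  invisible(x)
}
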
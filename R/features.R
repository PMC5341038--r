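#' Build linear + quadratic feature specification
#'
#' Each source variable contributes a scaled linear feature
#' `f = (x - min) / (max - min)` and a quadratic feature `g = f^2`, with
#' (min, max) taken over the *training* stack's valid cells, so all features
#' lie in `[0, 1]` on the training data.  When a model is transferred to
#' another climate, scaled features can be clamped back into `[0, 1]`.
#'
#' @param stack training [align_stack()] stack.
#' @param subset variable names to use.
#' @return a `feature_spec`: data frame with columns `variable`, `min`,
#'   `max`.
#' @export
build_features <- function(stack, subset = names(stack$layers)) {
  vals <- stack_values(stack, NULL, subset)
  mins <- apply(vals, 2, min)
  maxs <- apply(vals, 2, max)
  if (any(maxs - mins <= 0))
    stop("degenerate-feature error: constant variable(s): ",
         paste(subset[maxs - mins <= 0], collapse = ", "))
  structure(data.frame(variable = subset, min = mins, max = maxs,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("feature_spec", "data.frame"))
}

#' Feature matrix from raw variable values
#'
#' @param spec a [build_features()] spec.
#' @param raw matrix of raw values, columns named by variable.
#' @param clamp truncate scaled features to `[0, 1]` (used when projecting
#'   beyond the training range).
#' @return list: `X` the cells x (2 p) feature matrix (columns
#'   `<var>.lin`, `<var>.quad`), `clamped` logical per row (any feature
#'   clamped there).
#' @export
feature_matrix <- function(spec, raw, clamp = FALSE) {
  p <- nrow(spec)
  raw <- as.matrix(raw)[, spec$variable, drop = FALSE]
  lin <- sweep(sweep(raw, 2, spec$min), 2, spec$max - spec$min, `/`)
  clamped <- rep(FALSE, nrow(lin))
  if (clamp) {
    out <- lin < 0 | lin > 1
    clamped <- rowSums(out) > 0
    lin[lin < 0] <- 0
    lin[lin > 1] <- 1
  }
  X <- matrix(0, nrow(lin), 2L * p)
  X[, seq(1, 2 * p, by = 2)] <- lin
  X[, seq(2, 2 * p, by = 2)] <- lin^2
  colnames(X) <- as.vector(rbind(paste0(spec$variable, ".lin"),
                                 paste0(spec$variable, ".quad")))
  list(X = X, clamped = clamped)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# linear predictor eta . f(x) for a fitted model, from raw values
feature_eta <- function(model, raw, clamp = FALSE) {
  fm <- feature_matrix(model$feature_spec, raw, clamp = clamp)
  drop(fm$X %*% model$coefficients)
}
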
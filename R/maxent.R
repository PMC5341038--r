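#' Fit a maximum-entropy presence/background model
#'
#' Fits the Gibbs distribution `q(x) = exp(eta . f(x)) / Z` over background
#' cells, with linear + quadratic features only, by minimizing the convex
#' L1-penalized objective
#'
#'   `J(eta) = -mean_presence(eta . f) + log sum_background exp(eta . f)
#'             + sum_j beta_j |eta_j|`
#'
#' (the constant `-log m` is dropped).  The solver is a proximal-Newton
#' iteration: at each step the smooth part is replaced by its local quadratic
#' model, the L1-penalized quadratic is solved by coordinate descent with
#' soft-thresholding, and a backtracking line search guarantees monotone
#' decrease of the true objective.  Convergence is declared when the L1
#' subgradient optimality conditions hold within `tol`.
#'
#' Presence cells are appended to the background sample by default
#' (the "target-group" convention of presence-background maxent software);
#' set `include_presence = FALSE` to keep them out.
#'
#' Per-feature regularization follows the convention standard for
#' linear+quadratic maxent feature sets:
#' `beta_j = beta_multiplier * b(n) * s_j / sqrt(n)` where `s_j` is the
#' feature's standard deviation over the presence sample and `b(n)` the
#' feature-class base weight interpolated over sample size
#' (0.22 at n = 10 down to 0.05 at n >= 100).  `beta_multiplier = 1` is the
#' default; larger values shrink harder.
#'
#' @param presence an `occurrence_set` (or row/col cell matrix) on `stack`.
#' @param background a [sample_background()] sample.
#' @param stack training [align_stack()] stack (supplies feature bounds).
#' @param variables variables to use (default: all stack layers).
#' @param beta_multiplier scales all regularization weights (default 1).
#' @param include_presence append presence cells to the background.
#' @param tol KKT subgradient tolerance (default 1e-6).
#' @param max_iter outer Newton iteration cap.
#' @return an object of class `maxent_sdm` with elements `coefficients`
#'   (named, one per feature), `beta`, `feature_spec`, `variables`, `lnZ`
#'   (log normalizer over the background), `entropy` (of the background raw
#'   distribution), `n_presence`, `m_background`, `objective_trace`,
#'   `converged`, `iterations`.
#' @seealso [predict.maxent_sdm()], [jackknife_gain()], [write_lambdas()]
#' @export
maxent_fit <- function(presence, background, stack,
                       variables = names(stack$layers),
                       beta_multiplier = 1.0, include_presence = TRUE,
                       tol = 1e-6, max_iter = 200) {
  pres_cells <- if (inherits(presence, "occurrence_set"))
    occ_cells(presence) else as.matrix(presence)
  if (nrow(pres_cells) < 2) stop("need at least 2 presence cells")
  spec <- build_features(stack, variables)
  pres_raw <- stack_values(stack, pres_cells, variables)
  bg_raw <- background$values[, variables, drop = FALSE]
  if (include_presence) bg_raw <- rbind(bg_raw, pres_raw)
  Xb <- feature_matrix(spec, bg_raw)$X
  Xp <- feature_matrix(spec, pres_raw)$X
  fbar <- colMeans(Xp)
  n <- nrow(pres_cells); m <- nrow(Xb)
  sds <- apply(Xp, 2, stats::sd)
  sds <- pmax(sds, 1e-4)        # floor keeps separated features penalized
  beta <- beta_multiplier * lq_base_beta(n) * sds / sqrt(n)
  sol <- maxent_solve(Xb, fbar, beta, tol = tol, max_iter = max_iter)
  s <- drop(Xb %*% sol$eta)
  lnZ <- logsumexp(s)
  q <- exp(s - lnZ)
  # H = -sum q log q written as lnZ - sum(q s): exact for the uniform model
  entropy <- lnZ - sum(q * s)
  structure(list(coefficients = stats::setNames(sol$eta, colnames(Xb)),
                 beta = stats::setNames(beta, colnames(Xb)),
                 feature_spec = spec, variables = spec$variable,
                 lnZ = lnZ, entropy = entropy,
                 n_presence = n, m_background = m,
                 include_presence = include_presence,
                 objective_trace = sol$trace,
                 converged = sol$converged, iterations = sol$iterations,
                 call = match.call()),
            class = "maxent_sdm")
}

# base regularization weight for the linear+quadratic feature class,
# interpolated over presence sample size (constant outside the knots)
lq_base_beta <- function(n) {
  stats::approx(c(10, 17, 30, 100), c(0.22, 0.18, 0.14, 0.05),
                xout = n, rule = 2)$y
}

# Proximal-Newton solver for J(eta) = -fbar.eta + lse(X eta) + sum beta|eta|
maxent_solve <- function(X, fbar, beta, tol = 1e-6, max_iter = 200) {
  p <- ncol(X)
  eta <- numeric(p)
  s <- numeric(nrow(X))
  objective <- function(eta, s) -sum(fbar * eta) + logsumexp(s) + sum(beta * abs(eta))
  J <- objective(eta, s)
  trace <- J
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    lz <- logsumexp(s)
    q <- exp(s - lz)
    g <- drop(crossprod(X, q)) - fbar
    kkt <- ifelse(eta != 0, abs(g + beta * sign(eta)),
                  pmax(abs(g) - beta, 0))
    if (max(kkt) <= tol) { converged <- TRUE; break }
    Xq <- drop(crossprod(X, q))
    H <- crossprod(X * sqrt(q)) - tcrossprod(Xq)
    diag(H) <- diag(H) + 1e-9
    # coordinate descent on the L1-penalized quadratic model (compiled)
    z <- cd_quadratic(eta, g, H, beta)
    dir <- z - eta
    if (max(abs(dir)) < 1e-14) break
    decr <- sum(g * dir) + sum(beta * abs(z)) - sum(beta * abs(eta))
    Xdir <- drop(X %*% dir)
    t_step <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      s_new <- s + t_step * Xdir
      eta_new <- eta + t_step * dir
      J_new <- objective(eta_new, s_new)
      if (J_new <= J + 0.25 * t_step * decr || J_new < J - 1e-14) {
        accepted <- TRUE; break
      }
      t_step <- t_step / 2
    }
    if (!accepted) break
    eta <- eta_new; s <- s_new; J <- J_new
    trace <- c(trace, J)
  }
  if (!converged) {
    lz <- logsumexp(s); q <- exp(s - lz)
    g <- drop(crossprod(X, q)) - fbar
    kkt <- ifelse(eta != 0, abs(g + beta * sign(eta)),
                  pmax(abs(g) - beta, 0))
    if (max(kkt) <= tol) converged <- TRUE
    else stop(sprintf(
      "convergence error: maxent solver stopped after %d iterations (max KKT violation %.3g > tol %.3g)",
      it, max(kkt), tol))
  }
  list(eta = eta, trace = trace, iterations = it, converged = converged)
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' Predict suitability from a fitted maxent model
#'
#' `type = "raw"` gives the Gibbs density `q(x) = exp(eta . f(x)) / Z`
#' (normalized so it sums to 1 over the *training* background);
#' `type = "logistic"` gives `p = exp(H) q / (1 + exp(H) q)` with `H` the
#' training background entropy (so a no-signal model scores exactly 0.5
#' everywhere); `type = "link"` gives the linear predictor `eta . f(x)`.
#'
#' @param object a [maxent_fit()] model.
#' @param stack a [align_stack()] stack to predict over (all valid cells).
#' @param newdata alternatively, a raw-value matrix (columns named by
#'   variable); overrides `stack`.
#' @param type `"logistic"`, `"raw"` or `"link"`.
#' @param clamp truncate scaled features to the training `[0, 1]` box
#'   (default `TRUE`; only matters off the training stack).
#' @param ... unused.
#' @return with `stack`: a numeric matrix map (`NA` on invalid cells) with
#'   attribute `clamped_fraction`; with `newdata`: a numeric vector.
#' @export
predict.maxent_sdm <- function(object, stack = NULL, newdata = NULL,
                               type = c("logistic", "raw", "link"),
                               clamp = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata) && is.null(stack))
    stop("supply a layer stack or a newdata value matrix")
  if (!is.null(newdata)) {
    fm <- feature_matrix(object$feature_spec, newdata, clamp = clamp)
  } else {
    fm <- feature_matrix(object$feature_spec,
                         stack_values(stack, NULL, object$variables),
                         clamp = clamp)
  }
  eta <- drop(fm$X %*% object$coefficients)
  out <- switch(type,
    link = eta,
    raw = exp(eta - object$lnZ),
    logistic = stats::plogis(object$entropy + eta - object$lnZ))
  if (!is.null(newdata)) return(out)
  map <- matrix(NA_real_, nrow(stack$valid_mask), ncol(stack$valid_mask))
  map[stack$valid_mask] <- out
  attr(map, "clamped_fraction") <- mean(fm$clamped)
  map
}

#' @export
coef.maxent_sdm <- function(object, ...) object$coefficients

#' @export
print.maxent_sdm <- function(x, ...) {
  cat(sprintf("<maxent_sdm: %d variable(s), %d/%d nonzero features, n = %d presences, m = %d background>\n",
              length(x$variables), sum(x$coefficients != 0),
              length(x$coefficients), x$n_presence, x$m_background))
  cat(sprintf("  lnZ = %.4f, background entropy H = %.4f, %s in %d iteration(s)\n",
              x$lnZ, x$entropy,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @export
summary.maxent_sdm <- function(object, ...) {
  co <- data.frame(feature = names(object$coefficients),
                   coefficient = unname(object$coefficients),
                   beta = unname(object$beta), row.names = NULL)
  structure(list(coefficients = co, entropy = object$entropy,
                 lnZ = object$lnZ, n_presence = object$n_presence,
                 m_background = object$m_background,
                 converged = object$converged,
                 iterations = object$iterations),
            class = "summary.maxent_sdm")
}

#' @export
print.summary.maxent_sdm <- function(x, ...) {
  cat(sprintf("Maximum-entropy SDM (linear + quadratic features)\n"))
  cat(sprintf("  n presences: %d   background size: %d\n",
              x$n_presence, x$m_background))
  cat(sprintf("  background entropy H: %.4f   lnZ: %.4f   converged: %s (%d iter)\n",
              x$entropy, x$lnZ, x$converged, x$iterations))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
plot.maxent_sdm <- function(x, stack, type = "logistic", ...) {
  map <- predict(x, stack = stack, type = type)
  plot_map(map, stack, main = paste("maxent", type, "suitability"), ...)
  invisible(map)
}

plot_map <- function(map, stack, ...) {
  g <- stack$layers[[1]]
  nr <- nrow(map); nc <- ncol(map)
  lon <- g$origin_lon + (seq_len(nc) - 0.5) * g$cell_size
  lat <- g$origin_lat - (seq_len(nr) - 0.5) * g$cell_size
  graphics::image(lon, rev(lat), t(map[nr:1, , drop = FALSE]),
                  xlab = "longitude", ylab = "latitude",
                  col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...)
}

#' Jackknife variable-importance gains
#'
#' Training gain of each variable when used in isolation:
#' `gain(v) = log m + fbar . eta - log sum exp(eta . f)` for the model using
#' only `v`'s two features at the penalized optimum (the standard maxent
#' "gain with only this variable" jackknife).  Gains are nonnegative.
#'
#' @inheritParams maxent_fit
#' @return data frame (`variable`, `gain`) sorted by decreasing gain.
#' @export
jackknife_gain <- function(presence, background, stack,
                           variables = names(stack$layers),
                           beta_multiplier = 1.0, include_presence = TRUE) {
  gains <- vapply(variables, function(v) {
    fit <- maxent_fit(presence, background, stack, variables = v,
                      beta_multiplier = beta_multiplier,
                      include_presence = include_presence)
    pres_cells <- if (inherits(presence, "occurrence_set"))
      occ_cells(presence) else as.matrix(presence)
    Xp <- feature_matrix(fit$feature_spec,
                         stack_values(stack, pres_cells, v))$X
    log(fit$m_background) + sum(colMeans(Xp) * fit$coefficients) - fit$lnZ
  }, numeric(1))
  out <- data.frame(variable = variables, gain = unname(gains),
                    stringsAsFactors = FALSE)
  out[order(-out$gain), , drop = FALSE]
}

#' Serialize a fitted model to a plain-text "lambdas" file
#'
#' Key/value text listing each variable's training bounds, each feature's
#' coefficient and regularization weight, and the model normalizer and
#' entropy, at full double precision so the round-trip is exact.
#'
#' @param model a [maxent_fit()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lambdas <- function(model, path) {
  ln <- c("maxsdm-lambdas 1",
          sprintf("variable, %s, %.17g, %.17g", model$feature_spec$variable,
                  model$feature_spec$min, model$feature_spec$max),
          sprintf("feature, %s, %.17g, %.17g", names(model$coefficients),
                  unname(model$coefficients), unname(model$beta)),
          sprintf("lnZ, %.17g", model$lnZ),
          sprintf("entropy, %.17g", model$entropy),
          sprintf("n_presence, %d", model$n_presence),
          sprintf("m_background, %d", model$m_background))
  writeLines(ln, path)
  invisible(path)
}

#' Read a model back from a lambdas file
#'
#' @param path file written by [write_lambdas()].
#' @return a `maxent_sdm` object (usable with [predict.maxent_sdm()]).
#' @export
read_lambdas <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!grepl("^maxsdm-lambdas", ln[1]))
    stop("not a maxsdm lambdas file: ", path)
  fields <- strsplit(ln[-1], ",\\s*")
  key <- vapply(fields, `[`, "", 1)
  vrows <- fields[key == "variable"]
  spec <- data.frame(variable = vapply(vrows, `[`, "", 2),
                     min = as.numeric(vapply(vrows, `[`, "", 3)),
                     max = as.numeric(vapply(vrows, `[`, "", 4)),
                     stringsAsFactors = FALSE)
  class(spec) <- c("feature_spec", "data.frame")
  frows <- fields[key == "feature"]
  coefs <- stats::setNames(as.numeric(vapply(frows, `[`, "", 3)),
                           vapply(frows, `[`, "", 2))
  beta <- stats::setNames(as.numeric(vapply(frows, `[`, "", 4)),
                          names(coefs))
  getv <- function(k) as.numeric(fields[[which(key == k)]][2])
  structure(list(coefficients = coefs, beta = beta, feature_spec = spec,
                 variables = spec$variable, lnZ = getv("lnZ"),
                 entropy = getv("entropy"),
                 n_presence = as.integer(getv("n_presence")),
                 m_background = as.integer(getv("m_background")),
                 include_presence = NA, objective_trace = numeric(0),
                 converged = TRUE, iterations = 0L,
                 call = quote(read_lambdas())),
            class = "maxent_sdm")
}
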
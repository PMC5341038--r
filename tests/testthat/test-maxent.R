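test_that("feature building scales, squares, and clamps correctly", {
  g <- climate_grid(matrix(c(0, 5, 10, NA), 2, 2), 0, 2, 1, variable = "t")
  s <- align_stack(list(g))
  spec <- build_features(s)
  expect_equal(spec$min, 0)
  expect_equal(spec$max, 10)
  fm <- feature_matrix(spec, cbind(t = c(0, 5, 10)))
  expect_equal(fm$X[, "t.lin"], c(0, 0.5, 1))
  expect_equal(fm$X[, "t.quad"], c(0, 0.25, 1))

  # two variables -> four features
  w <- small_world()
  spec2 <- build_features(w$stack, c("v1", "v2"))
  expect_equal(ncol(feature_matrix(spec2, maxsdm:::stack_values(w$stack, NULL,
                                                                c("v1", "v2")))$X), 4)

  # projection values beyond the training range clamp to [0, 1]
  fmc <- feature_matrix(spec, cbind(t = c(-5, 15)), clamp = TRUE)
  expect_equal(fmc$X[, "t.lin"], c(0, 1))
  expect_equal(fmc$X[, "t.quad"], c(0, 1))
  expect_true(all(fmc$clamped))

  gc <- climate_grid(matrix(7, 2, 2), 0, 2, 1, variable = "const")
  expect_error(build_features(align_stack(list(gc))), "degenerate-feature")
})

test_that("no-signal fits are uniform: eta = 0, raw = 1/m, logistic = 0.5", {
  w <- small_world()
  bg <- small_background()
  # presences drawn uniformly from the background cells + strong penalty
  set.seed(4)
  pres <- bg$cells[sample(nrow(bg$cells), 60), ]
  fit <- maxent_fit(pres, bg, w$stack, variables = c("v1", "v3"),
                    beta_multiplier = 50)
  expect_true(all(coef(fit) == 0))
  m <- fit$m_background
  raw <- predict(fit, newdata = bg$values, type = "raw")
  expect_equal(raw, rep(1 / m, nrow(bg$values)), tolerance = 1e-12)
  lg <- predict(fit, newdata = bg$values, type = "logistic")
  expect_identical(unique(lg), 0.5)  # exactly 0.5, e^H q = 1
  expect_equal(fit$entropy, log(m), tolerance = 1e-12)
})

test_that("solver matches brute-force grid search on tiny instances", {
  # 1 feature, 20 background cells: dense 1-D grid over eta
  set.seed(7)
  X <- matrix(runif(20), 20, 1)
  fbar <- 0.7
  beta <- 0.05
  gs <- seq(-50, 50, by = 0.001)
  lse <- vapply(gs, function(e) maxsdm:::logsumexp(X * e), 0)
  eta_grid <- gs[which.min(-fbar * gs + lse + beta * abs(gs))]
  sol <- maxsdm:::maxent_solve(X, fbar, beta)
  expect_lt(abs(sol$eta - eta_grid), 1e-3)

  # 2 features, 50 cells: multi-resolution 2-D grid search oracle
  set.seed(21)
  X2 <- cbind(runif(50), runif(50)^2)
  fbar2 <- c(0.6, 0.45)
  beta2 <- c(0.02, 0.02)
  obj2 <- function(e) -sum(fbar2 * e) + maxsdm:::logsumexp(X2 %*% e) +
    sum(beta2 * abs(e))
  ctr <- c(0, 0); hw <- 50
  for (lev in 1:8) {
    cand <- as.matrix(expand.grid(ctr[1] + seq(-hw, hw, length.out = 41),
                                  ctr[2] + seq(-hw, hw, length.out = 41)))
    vals <- apply(cand, 1, obj2)
    ctr <- cand[which.min(vals), ]
    hw <- hw / 10
  }
  sol2 <- maxsdm:::maxent_solve(X2, fbar2, beta2)
  expect_lt(max(abs(sol2$eta - ctr)), 1e-3)
})

test_that("objective trace is monotone and raw output is normalized", {
  w <- small_world()
  bg <- small_background()
  fit <- maxent_fit(w$occurrences, bg, w$stack, variables = c("v1", "v2"))
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
  expect_gt(length(fit$objective_trace), 1)
  # raw distribution sums to 1 over the training background (incl. presences)
  pres_vals <- maxsdm:::stack_values(w$stack, cbind(w$occurrences$row,
                                                    w$occurrences$col))
  all_bg <- rbind(bg$values, pres_vals)
  expect_equal(sum(predict(fit, newdata = all_bg, type = "raw")), 1,
               tolerance = 1e-9)
  # logistic agrees with the direct formula e^H q / (1 + e^H q) at 5 cells
  q5 <- predict(fit, newdata = all_bg[1:5, ], type = "raw")
  p5 <- predict(fit, newdata = all_bg[1:5, ], type = "logistic")
  expect_equal(p5, exp(fit$entropy) * q5 / (1 + exp(fit$entropy) * q5),
               tolerance = 1e-12)
  # entropy bounds for a distribution over m cells
  expect_gt(fit$entropy, 0)
  expect_lt(fit$entropy, log(fit$m_background) + 1e-12)
})

test_that("sign recovery and sparsity respond to the data and penalty", {
  # monotone response to v1 -> positive linear coefficient, across seeds
  hits <- 0
  for (seed in 1:10) {
    s <- generate_landscape(n_vars = 2, n_rows = 40, n_cols = 40, seed = seed,
                            correlation = diag(2))
    suit <- 1 / (1 + exp(-2 * s$layers$v1$values))  # increasing in v1
    occd <- sample_occurrences(suit, s, n_raw = 80, seed = seed)
    occ <- load_occurrences(occd, s)
    bg <- sample_background(s, 400, seed = seed + 50)
    fit <- maxent_fit(occ, bg, s, variables = "v1")
    sc <- predict(fit, newdata = cbind(v1 = c(-2, 2)))
    if (sc[2] > sc[1]) hits <- hits + 1
  }
  expect_equal(hits, 10)

  # raising the penalty never increases the number of nonzero coefficients
  w <- small_world()
  bg <- small_background()
  nnz <- vapply(c(0.1, 1, 5, 25, 100), function(b)
    sum(coef(maxent_fit(w$occurrences, bg, w$stack,
                        variables = c("v1", "v2", "v3"),
                        beta_multiplier = b)) != 0), 0)
  expect_true(all(diff(nnz) <= 0))
})

test_that("lambdas serialization round-trips the model exactly", {
  w <- small_world()
  fit <- maxent_fit(w$occurrences, small_background(), w$stack,
                    variables = c("v1", "v2"))
  tmp <- withr::local_tempfile(fileext = ".lambdas")
  write_lambdas(fit, tmp)
  back <- read_lambdas(tmp)
  expect_identical(back$coefficients, fit$coefficients)
  expect_identical(back$lnZ, fit$lnZ)
  expect_identical(back$entropy, fit$entropy)
  expect_identical(back$feature_spec$min, fit$feature_spec$min)
  nd <- maxsdm:::stack_values(w$stack, NULL, c("v1", "v2"))[1:20, ]
  expect_identical(predict(back, newdata = nd), predict(fit, newdata = nd))
})

test_that("jackknife gain isolates the niche-driving variable", {
  hits <- 0
  for (seed in 1:10) {
    world <- synthetic_world(n_vars = 4, n_rows = 50, n_cols = 50,
                             correlation = diag(4), n_raw = 120, seed = seed)
    bg <- sample_background(world$stack, 500, seed = seed + 30)
    gains <- jackknife_gain(world$occurrences, bg, world$stack,
                            variables = c("v1", "v3", "v4"))
    expect_true(all(gains$gain >= -1e-8))
    if (gains$variable[1] == "v1") hits <- hits + 1
    # nuisance variables carry much less information than the driver
    expect_lt(min(gains$gain), max(gains$gain))
  }
  expect_gte(hits, 9)
})
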
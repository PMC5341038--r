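test_that("background sampling is uniform, seeded, and exhaustive at n = N", {
  w <- small_world()
  nv <- sum(w$stack$valid_mask)

  b1 <- sample_background(w$stack, 500, seed = 3)
  b2 <- sample_background(w$stack, 500, seed = 3)
  expect_identical(b1$cells, b2$cells)
  expect_equal(nrow(unique(b1$cells)), 500)

  ball <- sample_background(w$stack, nv, seed = 99)
  expect_equal(nrow(ball$cells), nv)
  expect_error(sample_background(w$stack, nv + 1, seed = 1), "sampling error")

  # quadrant uniformity: expected counts proportional to valid cells/quadrant
  b <- sample_background(w$stack, 2000, seed = 12)
  quad <- function(cells) paste(cells[, 1] > 30, cells[, 2] > 30)
  obs <- table(quad(b$cells))
  vm <- which(w$stack$valid_mask, arr.ind = TRUE)
  expv <- table(quad(vm)) / nrow(vm)
  p <- stats::chisq.test(obs, p = expv[names(obs)])$p.value
  expect_gt(p, 0.01)
})

test_that("pearson matrix reproduces exact and sampled correlations", {
  x <- rnorm(100)
  m <- cbind(a = x, b = 2 * x + 1, c = -x)
  r <- pearson_matrix(m)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r, t(r))

  set.seed(5)
  ind <- cbind(u = rnorm(5000), v = rnorm(5000))
  expect_lt(abs(pearson_matrix(ind)["u", "v"]), 0.05)

  expect_error(pearson_matrix(cbind(a = rep(1, 10), b = rnorm(10))),
               "degenerate-variable.*a")
})

test_that("correlation grouping equals brute-force connected components", {
  mk <- function(r_ab, r_bc, r_ac) {
    r <- diag(3)
    r[1, 2] <- r[2, 1] <- r_ab
    r[2, 3] <- r[3, 2] <- r_bc
    r[1, 3] <- r[3, 1] <- r_ac
    dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
    r
  }
  # transitive chain: a-b and b-c strong, a-c weak -> one group
  g <- group_correlated(mk(0.9, 0.9, 0.5))
  expect_length(g, 1)
  expect_setequal(g[[1]], c("a", "b", "c"))
  # all weak -> singletons; all strong -> one group
  expect_length(group_correlated(mk(0.5, 0.4, 0.3)), 3)
  expect_length(group_correlated(mk(0.95, 0.9, 0.99)), 1)
  # negative correlations count by absolute value
  expect_length(group_correlated(mk(-0.9, 0.2, 0.1)), 2)

  # randomized oracle: BFS connected components on |r| >= t
  set.seed(11)
  for (rep in 1:10) {
    p <- 6
    r <- diag(p)
    for (i in 1:(p - 1)) for (j in (i + 1):p)
      r[i, j] <- r[j, i] <- runif(1, -1, 1)
    colnames(r) <- rownames(r) <- letters[1:p]
    adj <- abs(r) >= 0.85; diag(adj) <- FALSE
    comp <- rep(0L, p)
    cid <- 0L
    for (s in 1:p) if (comp[s] == 0L) {
      cid <- cid + 1L; queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v]) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & comp == 0L))
      }
    }
    oracle <- unname(lapply(split(letters[1:p], comp), sort))
    got <- lapply(group_correlated(r), sort)
    expect_setequal(got, oracle)
  }
})

test_that("candidate enumeration honours group caps and minimum size", {
  grouping <- list(c("a", "b", "c"), "d")
  cands <- enumerate_candidates(c("a", "b", "c", "d"), grouping,
                                max_per_group = 2, min_size = 2)
  # brute-force oracle over all 16 subsets
  oracle <- Filter(function(s) length(s) >= 2 && sum(s %in% c("a", "b", "c")) <= 2,
                   unlist(lapply(0:15, function(m)
                     list(c("a", "b", "c", "d")[bitwAnd(m, c(1, 2, 4, 8)) > 0])),
                     recursive = FALSE))
  expect_length(cands, 9)
  expect_setequal(lapply(cands, sort), lapply(oracle, sort))

  # unconstrained: 2^p - 1 subsets
  vars <- letters[1:5]
  all_sub <- enumerate_candidates(vars, as.list(vars), max_per_group = 5,
                                  min_size = 1)
  expect_length(all_sub, 2^5 - 1)

  # brute-force count agreement on randomized groupings, p <= 12
  set.seed(2)
  for (rep in 1:5) {
    p <- sample(5:9, 1)
    vars <- paste0("x", 1:p)
    gid <- sample(1:3, p, replace = TRUE)
    grouping <- unname(split(vars, gid))
    got <- enumerate_candidates(vars, grouping, max_per_group = 2, min_size = 2)
    cnt <- 0
    for (m in 1:(2^p - 1)) {
      s <- vars[bitwAnd(m, 2^(0:(p - 1))) > 0]
      if (length(s) >= 2 &&
          all(vapply(grouping, function(g) sum(s %in% g), 0) <= 2))
        cnt <- cnt + 1
    }
    expect_length(got, cnt)
  }
})

test_that("VIF matches the inverse-correlation-matrix oracle", {
  set.seed(8)
  n <- 400
  a <- rnorm(n); b <- rnorm(n)
  # orthogonalize exactly -> VIF 1
  b <- residuals(lm(b ~ a))
  m <- cbind(a = a, b = b)
  v <- vif_screen(m, c("a", "b"))
  expect_equal(unname(v$vif), c(1, 1), tolerance = 1e-10)
  expect_true(v$pass)

  # exact collinearity -> Inf, screened out, no exception
  m2 <- cbind(a = a, b = b, c = a + b)
  v2 <- vif_screen(m2, c("a", "b", "c"))
  expect_true(all(is.infinite(v2$vif)))
  expect_false(v2$pass)

  # 2-subset closed form 1/(1 - r^2)
  x <- rnorm(n); y <- 0.7 * x + rnorm(n)
  r <- cor(x, y)
  v3 <- vif_screen(cbind(x = x, y = y), c("x", "y"))
  expect_equal(unname(v3$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-8)

  # general oracle: diagonal of the inverted correlation matrix
  S <- matrix(c(1, .6, .3, .6, 1, .5, .3, .5, 1), 3)
  X <- matrix(rnorm(3 * 600), ncol = 3) %*% chol(S)
  colnames(X) <- c("p", "q", "r")
  v4 <- vif_screen(X, c("p", "q", "r"))
  expect_equal(unname(v4$vif), unname(diag(solve(cor(X)))), tolerance = 1e-8)
  expect_true(all(v4$vif >= 1))
})

test_that("AICc of the maxent likelihood matches closed forms and oracles", {
  w <- small_world()
  bg <- small_background()
  occ <- w$occurrences

  # a no-signal model (huge penalty -> all coefficients zero) has the
  # uniform-distribution likelihood: lnL = -n log(N valid cells)
  fit0 <- maxent_fit(occ, bg, w$stack, variables = c("v1", "v2"),
                     beta_multiplier = 1e6)
  expect_true(all(coef(fit0) == 0))
  sc0 <- score_aicc(fit0, occ, w$stack)
  n <- nrow(occ); N <- sum(w$stack$valid_mask)
  expect_equal(sc0$log_likelihood, -n * log(N), tolerance = 1e-10)
  expect_equal(sc0$k, 0)
  expect_equal(sc0$aicc, 2 * n * log(N), tolerance = 1e-10)

  # independent re-evaluation of a fitted model's normalized raw scores
  fit <- maxent_fit(occ, bg, w$stack, variables = c("v1", "v2"))
  sc <- score_aicc(fit, occ, w$stack)
  vals <- maxsdm:::stack_values(w$stack, NULL, fit$variables)
  eta <- drop(feature_matrix(fit$feature_spec, vals)$X %*% coef(fit))
  q <- exp(eta) / sum(exp(eta))
  idx_valid <- which(w$stack$valid_mask)
  occ_idx <- match((occ$col - 1) * nrow(w$stack$valid_mask) + occ$row,
                   idx_valid)
  lnL_oracle <- sum(log(q[occ_idx]))
  expect_equal(sc$log_likelihood, lnL_oracle, tolerance = 1e-8)
  k <- sum(coef(fit) != 0)
  expect_equal(sc$aicc,
               2 * k - 2 * lnL_oracle + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-8)
})

test_that("best-candidate choice follows AICc with k and lexicographic ties", {
  scored <- data.frame(subset = c("a+b", "a+c", "b+c"),
                       k = c(3, 2, 2),
                       vif_pass = c(TRUE, TRUE, FALSE),
                       AICc = c(100, 100, 50))
  # b+c would win on AICc but fails VIF; tie a+b vs a+c broken by smaller k
  expect_equal(select_best(scored)$subset, "a+c")
  # permutation invariance
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(select_best(scored[perm, ])$subset, "a+c")
  # equal k ties break lexicographically
  scored2 <- data.frame(subset = c("b+d", "a+c"), k = 2, vif_pass = TRUE,
                        AICc = 10)
  expect_equal(select_best(scored2)$subset, "a+c")
  expect_error(select_best(data.frame(subset = "a+b", k = 2,
                                      vif_pass = FALSE, AICc = 1)),
               "selection error")
  # single candidate wins trivially
  expect_equal(select_best(scored[1, ])$subset, "a+b")
})

test_that("selection recovers the true drivers on the small world", {
  w <- small_world()
  sel <- select_variables(w$occurrences, small_background(), w$stack)
  expect_true(all(c("v1", "v2") %in% sel$winner))
  expect_equal(sel$n_candidates, length(enumerate_candidates(
    paste0("v", 1:5), sel$grouping)))
  # the collinear pair is grouped together
  sizes <- lengths(sel$grouping)
  expect_true(any(sizes == 2))
  # winner AICc is the minimum over VIF-passing candidates
  ok <- sel$ranked[sel$ranked$vif_pass & is.finite(sel$ranked$AICc), ]
  expect_equal(min(ok$AICc), ok$AICc[which(ok$rank == 1)])
})
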
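make_pse_tab <- function(values, objects = paste0("o", seq_len(ncol(values)))) {
  # values: responders x objects matrix of PSEs
  dplyr::bind_rows(lapply(seq_len(nrow(values)), function(i) {
    tibble::tibble(responder_id = paste0("r", i), object_id = objects,
                   pse = values[i, ])
  }))
}

test_that("PSE-truth differences: null identity, closed-form t, exact shift", {
  truth <- tibble::tibble(object_id = c("o1", "o2"), critical_angle = c(40, 50))
  # all differences zero
  tab0 <- make_pse_tab(matrix(rep(c(40, 50), each = 5), 5), c("o1", "o2"))
  res0 <- pse_truth_difference(tab0, truth)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_equal(res0$cohens_d, 0)

  # responder means exactly -5 with sd exactly 1, n = 20: t = -5 sqrt(20)
  dev <- as.numeric(scale(1:20))
  vals <- cbind(40 + dev - 5, 50 + dev - 5)
  res <- pse_truth_difference(make_pse_tab(vals, c("o1", "o2")), truth)
  expect_equal(res$t, -5 * sqrt(20), tolerance = 1e-10)
  expect_equal(res$mean_difference, -5, tolerance = 1e-12)
  expect_equal(res$cohens_d, -5, tolerance = 1e-10)

  # identical nonzero shift: flagged, no infinite t
  tabs <- make_pse_tab(matrix(rep(c(37, 47), each = 4), 4), c("o1", "o2"))
  ress <- pse_truth_difference(tabs, truth)
  expect_true(ress$exact_shift)
  expect_true(is.na(ress$t))
})

test_that("safe-side cohort shows a significantly negative difference", {
  cat0 <- stimulus_catalog()[1:4, ]
  des <- small_design(cat0$object_id, 5, 105, 10, repetitions = 8L)
  tr <- simulate_cohort(des, cat0, observer_params(-4, 4), n_observers = 10,
                        seed = 44)
  tab <- pse_table(tr)
  res <- pse_truth_difference(tab, ground_truth(cat0))
  expect_lt(res$mean_difference, 0)
  expect_lt(res$p, 0.01)
})

test_that("linear trends: flat, order-embedding, and the OLS oracle", {
  truth <- tibble::tibble(object_id = paste0("o", 1:4),
                          critical_angle = c(70, 55, 45, 30))
  flat <- make_pse_tab(matrix(50, 6, 4))
  expect_equal(suppressWarnings(linear_trend(flat, truth))$b, 0,
               tolerance = 1e-12)

  # PSEs equal to strictly decreasing ground truths: negative slope
  exact <- make_pse_tab(matrix(rep(c(70, 55, 45, 30), each = 3), 3))
  expect_lt(linear_trend(exact, truth)$b, 0)

  # slope equals the normal-equations solution on an arbitrary small table
  set.seed(2)
  vals <- matrix(rnorm(12, 45, 8), 3, 4)
  tab <- make_pse_tab(vals)
  res <- linear_trend(tab, truth)
  contrast <- stats::contr.poly(4)[, 1]
  z <- contrast[match(tab$object_id, paste0("o", 1:4))]
  X <- cbind(1, z)
  beta <- solve(t(X) %*% X, t(X) %*% tab$pse)
  expect_equal(res$b, beta[2], tolerance = 1e-10)

  expect_error(linear_trend(make_pse_tab(matrix(1, 2, 2)),
                            truth[1:2, ]), "trend undefined")
})

test_that("human-model regression: identity fit and rank deficiency", {
  grid <- tidyr::expand_grid(object_id = paste0("o", 1:4),
                             angle_deg = seq(10, 80, 10))
  set.seed(3)
  centroid <- dplyr::mutate(grid, prop_green = stats::plogis((angle_deg - 45) / 8)
                            + rnorm(nrow(grid), 0, 0.02))
  other <- dplyr::mutate(grid, prop_green = runif(nrow(grid)))
  human <- centroid
  res <- suppressWarnings(
    human_model_regression(human, list(centroid = centroid, other = other)))
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  b <- res$coefficients
  expect_equal(b$b[b$term == "centroid"], 1, tolerance = 1e-8)
  expect_equal(b$b[b$term == "other"], 0, tolerance = 1e-8)
  expect_gt(b$bf10[b$term == "centroid"], 100)

  expect_warning(
    human_model_regression(human, list(a = centroid, b = centroid)),
    "rank-deficient"
  )
})

test_that("null regression explains nothing on average", {
  grid <- tidyr::expand_grid(object_id = paste0("o", 1:4),
                             angle_deg = seq(10, 80, 10))
  r2s <- vapply(1:30, function(i) {
    set.seed(400 + i)
    human <- dplyr::mutate(grid, prop_green = runif(nrow(grid)))
    model <- dplyr::mutate(grid, prop_green = runif(nrow(grid)))
    human_model_regression(human, list(m = model))$r_squared
  }, numeric(1))
  # E[R2] under the null is 1/(n-2) for one predictor
  expect_lt(mean(r2s), 3 / (nrow(grid) - 2))
})

test_that("variance partitioning identities", {
  set.seed(4)
  n <- 200
  x1 <- rnorm(n)
  x2 <- stats::residuals(stats::lm(rnorm(n) ~ x1))  # exactly orthogonal
  y <- x1 + x2 + rnorm(n)
  vp <- variance_partitioning(y, list(a = x1, b = x2))
  comp <- stats::setNames(vp$components$value, vp$components$component)
  expect_equal(sum(vp$components$value), vp$r2_full, tolerance = 1e-10)
  expect_equal(unname(comp["a:b"]), 0, tolerance = 1e-10)
  r2_marg_a <- summary(stats::lm(y ~ x1))$r.squared
  expect_equal(unname(comp["a"]), r2_marg_a, tolerance = 1e-10)

  # perfect redundancy: y = x1 and x2 = x1
  vp2 <- variance_partitioning(x1, list(a = x1, b = x1))
  comp2 <- stats::setNames(vp2$components$value, vp2$components$component)
  expect_equal(unname(comp2["a"]), 0, tolerance = 1e-10)
  expect_equal(unname(comp2["b"]), 0, tolerance = 1e-10)
  expect_equal(unname(comp2["a:b"]), 1, tolerance = 1e-10)

  expect_error(variance_partitioning(y, list(a = x1)), "2 or 3")
  expect_error(variance_partitioning(y, list(a = x1, b = rep(1, n))),
               "constant")
})

test_that("3-predictor components match the all-subsets oracle", {
  # oracle: solve the linear system R2(A) = sum of components intersecting A
  # over all 7 nonempty predictor subsets
  oracle <- function(y, xs) {
    p <- 3
    subsets <- lapply(1:7, function(m) which(bitwAnd(m, c(1, 2, 4)) > 0))
    r2 <- vapply(subsets, function(S) {
      summary(stats::lm(y ~ do.call(cbind, xs[S])))$r.squared
    }, numeric(1))
    A <- matrix(0, 7, 7)
    for (i in 1:7) for (j in 1:7) {
      A[i, j] <- as.numeric(length(intersect(subsets[[i]], subsets[[j]])) > 0)
    }
    sol <- solve(A, r2)
    stats::setNames(sol, vapply(subsets, function(S)
      paste(c("a", "b", "c")[S], collapse = ":"), character(1)))
  }
  for (i in 1:10) {
    set.seed(500 + i)
    n <- 60
    x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n); x3 <- rnorm(n)
    y <- x1 + 0.3 * x2 - 0.5 * x3 + rnorm(n)
    vp <- variance_partitioning(y, list(a = x1, b = x2, c = x3))
    comp <- stats::setNames(vp$components$value, vp$components$component)
    orc <- oracle(y, list(x1, x2, x3))
    expect_equal(comp[names(orc)], orc, tolerance = 1e-8)
  }
})

test_that("unique-variance permutation: identity null and power", {
  set.seed(6)
  n <- 200
  x1 <- rnorm(n)
  y <- x1 + rnorm(n)
  res_same <- unique_variance_permutation(y, x1, x1, n_perm = 99, seed = 2)
  expect_equal(res_same$observed, 0, tolerance = 1e-12)
  expect_equal(res_same$p, 1)

  x2 <- rnorm(n)  # pure noise predictor
  res_pow <- unique_variance_permutation(y, x1, x2, n_perm = 1000, seed = 3)
  expect_gt(res_pow$observed, 0)
  expect_lte(res_pow$p, 0.01)
})

test_that("fast R2 agrees with the normal-equations oracle", {
  for (i in 1:20) {
    set.seed(600 + i)
    n <- 40
    X <- matrix(rnorm(n * 3), n)
    y <- X %*% c(1, -0.5, 0.2) + rnorm(n)
    Xd <- cbind(1, X)
    beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
    r2_oracle <- 1 - sum((y - Xd %*% beta)^2) / sum((y - mean(y))^2)
    expect_equal(tiltfall:::r_squared(y, X), r2_oracle, tolerance = 1e-8)
  }
})

test_that("weighted PCA correlations: perfect encoding and recovery", {
  set.seed(7)
  n <- 200
  feats <- data.frame(base = runif(n, 1, 3), centroid = runif(n, 0.3, 2),
                      height = runif(n, 1, 4), tb_ratio = runif(n))
  # single-column embedding identical to the centroid feature
  res1 <- weighted_pca_correlation(cbind(feats$centroid), feats,
                                   n_boot = 50, seed = 1)
  cc <- res1$coefficients
  expect_equal(cc$estimate[cc$feature == "centroid"], 1, tolerance = 1e-8)

  # i.i.d. noise embedding: all coefficients small
  noise <- matrix(rnorm(n * 30), n)
  res2 <- weighted_pca_correlation(noise, feats, n_boot = 100, seed = 2)
  expect_true(all(res2$coefficients$estimate < 0.25))

  # centroid-dominant mixture: centroid coefficient strictly largest
  emb <- cbind(feats$centroid + rnorm(n, 0, 0.05),
               feats$centroid + rnorm(n, 0, 0.05),
               matrix(rnorm(n * 8, 0, 0.3), n))
  res3 <- weighted_pca_correlation(emb, feats, n_boot = 100, seed = 3)
  est <- stats::setNames(res3$coefficients$estimate, res3$coefficients$feature)
  expect_equal(names(which.max(est)), "centroid")
})

test_that("weighted PCA correlation is invariant to sign flips", {
  set.seed(8)
  n <- 80
  feats <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  emb <- cbind(feats$f1 + rnorm(n, 0, 0.3), rnorm(n), rnorm(n))
  r1 <- weighted_pca_correlation(emb, feats, n_boot = 40, seed = 5)
  flipped <- emb %*% diag(c(-1, 1, -1))
  r2 <- weighted_pca_correlation(flipped, feats, n_boot = 40, seed = 5)
  expect_equal(r1$coefficients$estimate, r2$coefficients$estimate,
               tolerance = 1e-8)
})
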
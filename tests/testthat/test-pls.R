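# Standardization and multivariate PLS synthetic covariates.

test_that("standardization uses reference statistics only and is idempotent", {
  # two locations, one covariate with values (1,3): sample-sd z-scores
  ec <- ec_table(c("A", "B"), matrix(c(1, 3), 2, dimnames = list(NULL, "x")))
  z <- standardize_ecs(ec)$z
  expect_equal(unname(z[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # already-standardized covariates are unchanged
  set.seed(3)
  v <- scale(matrix(rnorm(12), 6))  # scale() uses sample sd too
  colnames(v) <- c("a", "b")
  ec <- ec_table(sprintf("L%d", 1:6), v)
  z <- standardize_ecs(ec)$z
  expect_equal(unname(z), unname(v[order(sprintf("L%d", 1:6)), ]),
               tolerance = 1e-12)

  # held-out location standardized with training statistics
  ec7 <- simulate_ecs(M = 7, P = 5, seed = 8)
  train <- ec7$locations[1:6]
  std <- standardize_ecs(ec7, reference_locations = train)
  ho <- setdiff(ec7$locations, train)
  manual <- (ec7$values[ec7$locations == ho, ] - std$center) / std$scale
  expect_equal(std$z[ho, ], manual, tolerance = 1e-12)
  # held-out row does not influence the statistics
  expect_equal(colMeans(std$z[train, ]), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(std$z[train, ], 2, sd), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)

  ecc <- ec_table(c("A", "B", "C"),
                  matrix(c(1, 2, 3, 5, 5, 6), 3,
                         dimnames = list(NULL, c("x", "y"))))
  expect_error(standardize_ecs(ecc, c("A", "B")), "y")
})

test_that("rank-1 X is recovered exactly by the first component", {
  set.seed(4)
  t_true <- rnorm(6)
  p_true <- rnorm(10)
  X <- tcrossprod(t_true, p_true)
  Y <- matrix(t_true, 6, 3) + matrix(rnorm(18, sd = 1e-8), 6)
  m <- fit_pls(X, Y, n_components = 1)
  expect_gt(abs(cor(m$x_scores[, 1], t_true)), 1 - 1e-10)
  expect_equal(m$x_variance_explained[1], 100, tolerance = 1e-6)
})

test_that("scores are orthogonal and deflation exhausts X at full rank", {
  set.seed(6)
  X <- matrix(rnorm(6 * 65), 6)
  colnames(X) <- sprintf("ec%02d", 1:65)
  X <- scale(X)
  Y <- matrix(rnorm(6 * 20), 6)
  m <- fit_pls(X, Y, n_components = 5)
  Tm <- m$x_scores
  for (k in 1:4) for (l in (k + 1):5)
    expect_lt(abs(sum(Tm[, k] * Tm[, l])),
              1e-8 * sqrt(sum(Tm[, k]^2) * sum(Tm[, l]^2)))
  # centered X has rank 5 over 6 rows; 5 components absorb all of it
  expect_equal(sum(m$x_variance_explained), 100, tolerance = 1e-8)
  resid <- X
  for (k in 1:5) resid <- resid - tcrossprod(Tm[, k], m$x_loadings[, k])
  expect_lt(max(abs(resid)), 1e-8)
  expect_error(fit_pls(X, Y, n_components = 6), "n_components")
})

test_that("NIPALS agrees with the mixOmics PLS oracle", {
  skip_if_not_installed("mixOmics")
  set.seed(7)
  X <- scale(matrix(rnorm(6 * 12), 6))
  colnames(X) <- sprintf("ec%02d", 1:12)
  Y <- matrix(rnorm(6 * 9), 6)
  K <- 3
  m <- fit_pls(X, Y, n_components = K)
  o <- mixOmics::pls(X, Y, ncomp = K, scale = FALSE, mode = "regression")
  for (k in seq_len(K)) {
    sgn <- sign(sum(m$x_weights[, k] * o$loadings$X[, k]))
    expect_equal(m$x_weights[, k], sgn * unname(o$loadings$X[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(m$x_scores[, k], sgn * unname(o$variates$X[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("projection reproduces training scores and maps zero to zero", {
  set.seed(8)
  X <- scale(matrix(rnorm(6 * 10), 6))
  colnames(X) <- sprintf("e%02d", 1:10)
  Y <- matrix(rnorm(6 * 4), 6)
  m <- fit_pls(X, Y, n_components = 3)
  for (r in 1:6)
    expect_equal(project_location(m, X[r, ]), m$x_scores[r, ],
                 tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(project_location(m, rep(0, 10)), rep(0, 3))
  expect_error(project_location(m, rep(0, 9)), "length")
})

test_that("coefficient ranking follows |w1 * sum(q1)| and caps top_n", {
  set.seed(9)
  X <- scale(matrix(rnorm(8 * 5), 8))
  colnames(X) <- sprintf("cov%d", 1:5)
  y <- matrix(rnorm(8), 8, 1)
  m <- fit_pls(X, y, n_components = 1)
  rk <- coefficient_ranking(m, top_n = 3)
  manual <- m$x_weights[, 1] * sum(m$y_loadings[, 1])
  ord <- order(abs(manual), decreasing = TRUE)
  expect_equal(rk$covariate, sprintf("cov%d", 1:5)[ord[1:3]])
  expect_equal(rk$coefficient, unname(manual[ord[1:3]]), tolerance = 1e-12)
  expect_equal(rk$rank, 1:3)
  expect_equal(nrow(coefficient_ranking(m, top_n = 99)), 5)
})

test_that("extract_sc keeps held-out locations out of the training statistics", {
  sim <- sim_scenario("tiny", seed = 12)
  train <- sim$means[1:3]
  scx <- extract_sc(sim$ec, train, n_sc = 2)
  expect_setequal(scx$train_locations,
                  vapply(train, function(s) s$location, character(1)))
  expect_equal(nrow(scx$sc), 4)   # scores for every EC location
  sds <- apply(scx$sc[scx$train_locations, ], 2, sd)
  expect_equal(unname(sds), c(1, 1), tolerance = 1e-10)
})
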
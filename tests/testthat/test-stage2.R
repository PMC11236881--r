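# Stage II weighted REML engine: covariance assembly, likelihood, BLUPs.

test_that("assembled covariance matches the printed Kronecker structures", {
  # I = 2 full sibs, M = 2: var(s) under kinship has 0.5*sigma_s^2 between
  # sib-same-location cells and zero across locations (identity Pi)
  ped <- pedigree_table(c("p1", "p2", "s1", "s2"),
                        c(NA, NA, "p1", "p1"), c(NA, NA, "p2", "p2"))
  A <- submatrix(numerator_relationship(ped), c("s1", "s2"))
  m1 <- mean_set("L1", c("s1", "s2"), c(3, 3.1), c(4, 4))
  m2 <- mean_set("L2", c("s1", "s2"), c(2.9, 3.0), c(4, 4))
  stk <- stack_means(list(m1, m2))
  spec <- model_spec("kinship", "identity", n_sc = 0)
  mm <- build_stage2(stk, spec, A = A)
  params <- list(G = matrix(0.04), L = matrix(0.2), sigma2_l = 0.09,
                 pi = list(type = "identity", sigma2_s = 0.02))
  # explicit cell-by-cell Kronecker expansion of the marginal covariance
  V_manual <- matrix(0, 4, 4)
  Gam <- A$values
  for (m in 1:2) for (mp in 1:2) for (i in 1:2) for (ip in 1:2) {
    r <- (m - 1) * 2 + i; c <- (mp - 1) * 2 + ip
    V_manual[r, c] <- 0.04 * Gam[i, ip] +                  # genotype main
      0.09 * (m == mp) +                                   # location
      0.02 * Gam[i, ip] * (m == mp)                        # A (x) I sigma_s^2
  }
  diag(V_manual) <- diag(V_manual) + 1 / 4
  ev <- metstage:::stage2_eval(mm, params)
  # recompute loglik from the manual V: identical means identical structure
  X <- mm$X; y <- mm$y
  Vi <- solve(V_manual)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  quad <- drop(crossprod(y - X %*% beta, Vi %*% (y - X %*% beta)))
  ll_manual <- -0.5 * (determinant(V_manual)$modulus + log(det(XtViX)) +
                       quad + (4 - 1) * log(2 * pi))
  expect_equal(ev$ll, as.numeric(ll_manual), tolerance = 1e-10)
})

test_that("with one SC the fixed row is (1, t_m) and slopes load genotype-wise", {
  tt <- tiny_stage2(seed = 3, n_sc = 1)
  mm <- tt$mm
  I <- mm$I
  for (m in seq_along(mm$locations)) {
    rows <- ((m - 1) * I + 1):(m * I)
    expect_true(all(mm$X[rows, 1] == 1))
    expect_true(all(mm$X[rows, 2] == tt$sc[mm$locations[m], 1]))
  }
})

test_that("BLUPs at frozen variance parameters equal the dense MME oracle", {
  for (cfg in list(list(gamma = "identity", pi = "identity", n_sc = 0),
                   list(gamma = "kinship", pi = "diagonal", n_sc = 1),
                   list(gamma = "kinship", pi = "fa", n_sc = 1))) {
    tt <- tiny_stage2(seed = 5, n_sc = cfg$n_sc, gamma = cfg$gamma,
                      pi_structure = cfg$pi, fa_order = 1)
    mm <- tt$mm
    M <- mm$M
    q1 <- cfg$n_sc + 1
    G <- diag(c(0.04, rep(0.01, cfg$n_sc)), q1)
    if (cfg$n_sc == 1) G[1, 2] <- G[2, 1] <- 0.005
    params <- list(G = G, L = t(chol(G)), sigma2_l = 0.09,
                   pi = switch(cfg$pi,
                     identity = list(type = "identity", sigma2_s = 0.02),
                     diagonal = list(type = "diagonal",
                                     phi = seq(0.01, 0.03, length.out = M)),
                     fa = list(type = "fa",
                               Lambda = matrix(seq(-0.15, 0.15,
                                                   length.out = M), M, 1),
                               phi = rep(0.01, M))))
    at <- stage2_at(mm, params)
    orc <- mme_oracle(mm, params)
    expect_equal(unname(at$fixef), unname(orc$beta), tolerance = 1e-8)
    expect_equal(unname(at$blup$a), unname(orc$a), tolerance = 1e-8)
    expect_equal(unname(at$blup$l), unname(orc$l), tolerance = 1e-8)
    expect_equal(unname(at$blup$s), unname(orc$s), tolerance = 1e-8)
    if (cfg$n_sc == 1)
      expect_equal(unname(at$blup$b), unname(orc$b), tolerance = 1e-8)
  }
})

test_that("REML fit improves on the start, and BLUPs average to about zero", {
  tt <- tiny_stage2(seed = 6, n_sc = 0, pi_structure = "diagonal")
  mm <- tt$mm
  start <- metstage:::stage2_start(mm)
  ll0 <- stage2_at(mm, start)$loglik
  fit <- reml_fit(mm)
  expect_true(fit$converged)
  expect_gte(fit$loglik, ll0)
  expect_equal(fit$aic, -2 * fit$loglik +
                 2 * metstage:::n_varpar(mm$spec, mm$M), tolerance = 1e-12)
  # BLUPs are shrunken, not constrained to sum to zero; they should still be
  # centered within a fraction of their spread
  expect_lt(abs(mean(fit$blup$a)), 0.3 * sd(fit$blup$a) + 1e-8)
  expect_lt(abs(mean(fit$blup$s)), 0.3 * sd(fit$blup$s) + 1e-8)
})

test_that("identity fits coincide whether Gamma is implicit or an explicit I", {
  tt <- tiny_stage2(seed = 7, n_sc = 0)
  mm1 <- tt$mm
  gen <- tt$stk$genotypes
  Aident <- structure(list(genotypes = gen,
                           values = diag(length(gen)) |>
                             (\(m) {dimnames(m) <- list(gen, gen); m})()),
                      class = "a_matrix")
  spec2 <- model_spec("kinship", "identity", n_sc = 0)
  mm2 <- build_stage2(tt$stk, spec2, A = Aident)
  f1 <- reml_fit(mm1); f2 <- reml_fit(mm2)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
  expect_equal(f1$blup$a, f2$blup$a, tolerance = 1e-5)
})

test_that("nested structures order the REML log-likelihood", {
  tt <- tiny_stage2(seed = 8, n_sc = 0, pi_structure = "identity")
  f_id <- reml_fit(tt$mm)
  mm_diag <- build_stage2(tt$stk, model_spec("identity", "diagonal"), A = NULL)
  f_diag <- reml_fit(mm_diag)
  expect_gte(f_diag$loglik, f_id$loglik - 1e-6)
  # FA with Lambda = 0 and shared Phi reproduces the identity fit exactly
  params_fa <- list(G = matrix(f_id$params$G), sigma2_l = f_id$params$sigma2_l,
                    pi = list(type = "fa",
                              Lambda = matrix(0, tt$mm$M, 1),
                              phi = rep(f_id$params$pi$sigma2_s, tt$mm$M)))
  mm_fa <- build_stage2(tt$stk, model_spec("identity", "fa", fa_order = 1),
                        A = NULL)
  expect_equal(stage2_at(mm_fa, params_fa)$loglik, f_id$loglik,
               tolerance = 1e-8)
})

test_that("the FA likelihood is invariant to orthogonal rotation of Lambda", {
  tt <- tiny_stage2(seed = 9, n_sc = 0, pi_structure = "fa", fa_order = 2)
  mm <- tt$mm
  M <- mm$M
  set.seed(1)
  Lam <- matrix(rnorm(M * 2, sd = 0.1), M, 2)
  params <- list(G = matrix(0.04), sigma2_l = 0.09,
                 pi = list(type = "fa", Lambda = Lam, phi = rep(0.01, M)))
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  params_rot <- params
  params_rot$pi$Lambda <- Lam %*% R
  expect_equal(stage2_at(mm, params)$loglik,
               stage2_at(mm, params_rot)$loglik, tolerance = 1e-8)
})

test_that("degenerate and misspecified inputs error clearly", {
  m1 <- mean_set("L1", c("g1", "g2", "g3"), c(3, 3.1, 3.2), rep(4, 3))
  expect_error(build_stage2(stack_means(list(m1)),
                            model_spec("identity", "identity")),
               "at least two locations")
  tt <- tiny_stage2(seed = 10, n_sc = 0)
  expect_error(build_stage2(tt$stk, model_spec("identity", "identity",
                                               n_sc = 1)),
               "SC")
  expect_error(build_stage2(tt$stk, model_spec("kinship", "identity")),
               "A matrix")
})

test_that("FA order path selects by AIC with warm starts and small-K ties", {
  tt <- tiny_stage2(seed = 11, n_sc = 0, pi_structure = "fa", fa_order = 1)
  best <- fit_fa_order_path(tt$mm, orders = 1:2)
  ap <- attr(best, "aic_path")
  expect_equal(nrow(ap), 2)
  expect_equal(best$aic, min(ap$aic))
  # Sigma from the FA fit is PSD with rank(Lambda Lambda') <= K
  Sig <- tcrossprod(best$params$pi$Lambda) + diag(best$params$pi$phi)
  expect_gte(min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_lte(qr(tcrossprod(best$params$pi$Lambda))$rank,
             best$spec$fa_order)
})
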
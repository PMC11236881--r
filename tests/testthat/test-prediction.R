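# New-location prediction, MSEPD and rank-correlation scoring.

pset <- function(location, genotypes, z) {
  structure(list(location = location, genotypes = genotypes, z = z,
                 mode = "main_effect"), class = "prediction_set")
}

test_that("predicted differences follow the definition on a worked fixture", {
  fit <- structure(list(
    spec = model_spec("identity", "identity", n_sc = 1),
    fixef = c(mu = 3.0, beta_SC1 = 0.2),
    blup = list(a = c(g1 = 0.1, g2 = -0.1),
                b = matrix(c(0.05, -0.05), 2, dimnames = list(c("g1", "g2"),
                                                              "SC1")),
                l = c(L1 = 0, L2 = 0),
                s = matrix(0, 2, 2, dimnames = list(c("g1", "g2"),
                                                    c("L1", "L2")))),
    genotypes = c("g1", "g2"), locations = c("L1", "L2")),
    class = "stage2_fit")
  p <- predict_new_location(fit, sc_new = 2)
  # z1 - z2 = (a1 - a2) + t * (b1 - b2) = 0.2 + 2 * 0.1 = 0.4
  expect_equal(p$z[1] - p$z[2], 0.4, tolerance = 1e-12)
  # with all interaction BLUPs zero both prediction modes coincide
  p2 <- predict_new_location(fit, sc_new = 2,
                             mode = "main_plus_avg_interaction")
  expect_equal(p2$z, p$z, tolerance = 1e-12)
  # without SCs predictions are constant per genotype across locations
  fit0 <- fit
  fit0$spec <- model_spec("identity", "identity", n_sc = 0)
  fit0$fixef <- c(mu = 3.0)
  expect_equal(diff(predict_new_location(fit0)$z), -0.2, tolerance = 1e-12)
  fit0$blup$s <- NULL
  expect_error(predict_new_location(fit0, mode = "main_plus_avg_interaction"),
               "interaction BLUPs")
})

test_that("MSEPD matches hand values, vanishes at equality, ignores shifts", {
  gen <- c("g1", "g2")
  obs <- list(mean_set("L1", gen, c(3.0, 2.0), c(1, 1)))
  prd <- list(pset("L1", gen, c(2.7, 2.3)))
  # observed diff 1.0, predicted 0.4 -> both ordered pairs give 0.36
  expect_equal(msepd(obs, prd), 0.36, tolerance = 1e-12)
  expect_equal(msepd(obs, list(pset("L1", gen, c(3.0, 2.0)))), 0)
  # per-location constant shifts leave MSEPD unchanged
  inst <- random_msepd_instance(M = 3, I = 6, seed = 2)
  base <- msepd(inst$obs, inst$prd)
  shifted <- inst$prd
  for (m in 1:3) shifted[[m]]$z <- shifted[[m]]$z + m * 1.7
  expect_equal(msepd(inst$obs, shifted), base, tolerance = 1e-10)
  expect_gt(base, 0)
  bad <- inst$prd
  bad[[1]]$genotypes <- rev(bad[[1]]$genotypes)
  expect_error(msepd(inst$obs, bad), "genotype sets differ")
})

test_that("MSEPD equals the brute-force ordered-pair oracle on random instances", {
  for (s in 1:12) {
    set.seed(s)
    inst <- random_msepd_instance(M = sample(1:4, 1), I = sample(2:10, 1),
                                  seed = s)
    expect_equal(msepd(inst$obs, inst$prd), msepd_brute(inst$obs, inst$prd),
                 tolerance = 1e-12)
  }
})

test_that("Spearman scoring averages per-location correlations with tie handling", {
  gen <- sprintf("g%d", 1:5)
  obs <- list(mean_set("L1", gen, c(1, 2, 3, 4, 5), rep(1, 5)),
              mean_set("L2", gen, c(2, 1, 4, 3, 5), rep(1, 5)))
  prd_same <- list(pset("L1", gen, c(10, 20, 30, 40, 50)),
                   pset("L2", gen, c(0.2, 0.1, 0.4, 0.3, 0.5)))
  sp <- spearman_by_location(obs, prd_same)
  expect_equal(unname(sp$per_location), c(1, 1))
  expect_equal(sp$mean, 1)
  prd_rev <- list(pset("L1", gen, c(5, 4, 3, 2, 1)),
                  pset("L2", gen, c(4, 5, 2, 3, 1)))
  expect_equal(spearman_by_location(obs, prd_rev)$mean, -1)
  # one tie: average-rank formula, cross-checked against cor() on ranks
  obs_t <- list(mean_set("L1", gen, c(1, 2, 2, 4, 5), rep(1, 5)))
  prd_t <- list(pset("L1", gen, c(1.1, 2.0, 2.5, 3.9, 5.2)))
  manual <- cor(rank(c(1, 2, 2, 4, 5)), rank(c(1.1, 2.0, 2.5, 3.9, 5.2)))
  expect_equal(spearman_by_location(obs_t, prd_t)$per_location[["L1"]],
               manual, tolerance = 1e-12)
  # constant predictions: NA with warning, excluded from the mean
  prd_c <- list(pset("L1", gen, c(10, 20, 30, 40, 50)),
                pset("L2", gen, rep(1, 5)))
  expect_warning(sp <- spearman_by_location(obs, prd_c), "undefined")
  expect_equal(sp$mean, 1)
})

test_that("leave-one-location-out trains without the held-out location", {
  sim <- sim_scenario("tiny", seed = 14)
  spec <- model_spec("identity", "identity", n_sc = 1)
  cv1 <- leave_one_location_out(sim$means, spec, ec = sim$ec)
  # corrupting the held-out location's means must not change its fold's
  # prediction (no leakage through PLS standardization or the REML fit)
  means2 <- sim$means
  means2[[1]] <- mean_set(means2[[1]]$location, means2[[1]]$genotypes,
                          means2[[1]]$means + 5, means2[[1]]$weights)
  cv2 <- leave_one_location_out(means2, spec, ec = sim$ec)
  expect_equal(cv1$predictions[[1]]$z, cv2$predictions[[1]]$z,
               tolerance = 1e-10)
  # other folds see different training data, so the CV score moves
  expect_false(isTRUE(all.equal(cv1$msepd_all_folds, cv2$msepd_all_folds)))
})

test_that("CV recovers near-perfect ranking when interaction is absent", {
  set.seed(15)
  gen <- sprintf("g%03d", 1:100)
  locs <- sprintf("L%d", 1:4)
  truth <- default_truth(0)
  truth$sigma2_s <- 1e-6
  gxl <- simulate_gxl(gen, locs, truth, seed = 15)
  means <- simulate_means(gxl$g, weight = 2000, seed = 15)
  cv <- leave_one_location_out(means, model_spec("identity", "identity"))
  expect_gte(cv$mean_rho, 0.9)
})
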
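## Simulators with known ground truth: pedigrees, environmental covariates and
## multi-environment trial phenotypes generated from the same structures the
## Stage I / Stage II models assume.
##
## All generators are pure functions of (parameters, seed). A single scenario
## seed expands into fixed per-component substreams so that, e.g., changing
## the plot-error draw does not perturb the pedigree.

sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 7L * as.integer(k)
}

#' Simulate a breeding pedigree
#'
#' Starts from unrelated founders and performs `crosses_per_gen` matings per
#' generation, drawing both parents from the previous generations; with
#' probability `selfing_prob` a mating is a selfing (both parents equal).
#'
#' @param n_founders number of founders (>= 2)
#' @param n_generations number of crossing generations
#' @param crosses_per_gen offspring produced per generation
#' @param selfing_prob probability a mating is a selfing
#' @param seed RNG seed
#' @return a `pedigree_table`; attribute `"final_generation"` lists the last
#'   generation's genotypes
#' @export
simulate_pedigree <- function(n_founders, n_generations = 2,
                              crosses_per_gen = n_founders,
                              selfing_prob = 0.1, seed = 1) {
  stopifnot(n_founders >= 2)
  set.seed(sub_seed(seed, 1))
  gid <- function(g, k) sprintf("G%d_%03d", g, k)
  genotype <- sprintf("F_%03d", seq_len(n_founders))
  p1 <- p2 <- rep(NA_character_, n_founders)
  pool <- genotype
  last <- genotype
  for (g in seq_len(n_generations)) {
    kids <- character(crosses_per_gen)
    for (k in seq_len(crosses_per_gen)) {
      pa <- sample(pool, 1)
      pb <- if (stats::runif(1) < selfing_prob) pa else sample(pool, 1)
      kids[k] <- gid(g, k)
      genotype <- c(genotype, kids[k])
      p1 <- c(p1, pa); p2 <- c(p2, pb)
    }
    pool <- c(pool, kids)
    last <- kids
  }
  ped <- pedigree_table(genotype, p1, p2)
  attr(ped, "final_generation") <- last
  ped
}

#' Simulate correlated environmental covariates
#'
#' Generates `EC = L F' + noise` from `latent_dim` latent location factors,
#' emulating the blockwise-correlated soil/weather panels of real
#' envirotyping tables, then shifts/scales columns to covariate-specific
#' units. The first latent factor (standardized) is returned as attribute
#' `"env_index"`; it is the environmental driver the PLS step should recover.
#'
#' @param M number of locations
#' @param P number of covariates
#' @param latent_dim number of latent factors
#' @param noise_sd residual noise standard deviation (latent scale)
#' @param seed RNG seed
#' @return an `ec_table`; attributes `"latent"` (M x latent_dim) and
#'   `"env_index"` (standardized first factor, named by location)
#' @export
simulate_ecs <- function(M = 6, P = 65, latent_dim = 3, noise_sd = 0.3,
                         seed = 1) {
  set.seed(sub_seed(seed, 2))
  locs <- sprintf("LOC%02d", seq_len(M))
  L <- matrix(stats::rnorm(M * latent_dim), M, latent_dim)
  Fm <- matrix(stats::rnorm(P * latent_dim), P, latent_dim)
  raw <- tcrossprod(L, Fm) + matrix(stats::rnorm(M * P, sd = noise_sd), M, P)
  mu <- stats::runif(P, -5, 50)
  scl <- stats::runif(P, 0.5, 20)
  vals <- sweep(sweep(raw, 2, scl, "*"), 2, mu, "+")
  colnames(vals) <- sprintf("ec%03d", seq_len(P))
  ec <- ec_table(locs, vals)
  lat <- L[match(ec$locations, locs), , drop = FALSE]
  rownames(lat) <- ec$locations
  attr(ec, "latent") <- lat
  ei <- (lat[, 1] - mean(lat[, 1])) / stats::sd(lat[, 1])
  attr(ec, "env_index") <- ei
  ec
}

#' Default variance components of the full-scale scenario
#'
#' Stage I components in (t/ha)^2 for a 2-replicate 25 x 4 row-column trial;
#' Stage II genotype/location/interaction variances and the SC regression
#' (fixed slope `beta`, random-slope variance `sigma2_b`) on a
#' unit-variance environmental index.
#'
#' @param n_sc number of true synthetic-covariate effects (0 or 1)
#' @return list of true parameters
#' @export
default_truth <- function(n_sc = 1) {
  list(mu = 3.0,
       stage1 = c(sigma2_h = 0.05, sigma2_r = 0.02, sigma2_c = 0.02,
                  sigma2_e = 0.10),
       sigma2_a = 0.04, sigma2_l = 0.09, sigma2_s = 0.02,
       beta = if (n_sc > 0) 0.15 else 0,
       sigma2_b = if (n_sc > 0) 0.02 else 0,
       n_sc = n_sc)
}

# Lower Cholesky of an interaction structure matrix Pi (M x M).
pi_chol <- function(truth_pi, M) {
  Pi <- if (is.matrix(truth_pi)) truth_pi else diag(truth_pi, M)
  ev <- min(eigen(Pi, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) stop("interaction structure matrix is not PSD")
  t(chol(Pi + diag(1e-10, M)))
}

#' Simulate genotype-by-location true values
#'
#' Draws genotype main effects (kinship-correlated when `A` is given),
#' location effects, SC regression effects and interaction effects with
#' covariance `Gamma (x) Pi`, and returns the I x M matrix of true
#' genotype-by-location means (t/ha).
#'
#' @param genotypes genotype identifiers
#' @param locations location identifiers
#' @param truth list as from [default_truth()]; element `pi` may be an M x M
#'   structure matrix (e.g. `Lambda Lambda' + diag(phi)`), otherwise
#'   `sigma2_s * I` is used
#' @param A optional `a_matrix` for kinship-correlated effects
#' @param env_index named length-M vector, the true environmental covariate
#'   driving the SC effects (required if `truth$n_sc > 0`)
#' @param seed RNG seed
#' @return list with `g` (I x M true means), `a`, `b`, `l`, `s`, `beta`
#' @export
simulate_gxl <- function(genotypes, locations, truth, A = NULL,
                         env_index = NULL, seed = 1) {
  set.seed(sub_seed(seed, 3))
  genotypes <- canonical_ids(genotypes)
  locations <- canonical_ids(locations)
  I <- length(genotypes); M <- length(locations)
  LG <- if (is.null(A)) diag(I) else
    t(chol(submatrix(A, genotypes)$values + diag(1e-8, I)))
  a <- sqrt(truth$sigma2_a) * drop(LG %*% stats::rnorm(I))
  l <- stats::rnorm(M, sd = sqrt(truth$sigma2_l))
  LP <- pi_chol(if (!is.null(truth$pi)) truth$pi else truth$sigma2_s, M)
  s <- LG %*% matrix(stats::rnorm(I * M), I, M) %*% t(LP)
  g <- outer(a, l, "+") + truth$mu + s
  b <- NULL
  if (truth$n_sc > 0) {
    if (is.null(env_index)) stop("truth has an SC effect; supply env_index")
    t_m <- env_index[locations]
    b <- sqrt(truth$sigma2_b) * drop(LG %*% stats::rnorm(I))
    g <- g + outer(rep(1, I), t_m) * truth$beta + outer(b, t_m)
  }
  dimnames(g) <- list(genotypes, locations)
  dimnames(s) <- list(genotypes, locations)
  list(g = g, a = stats::setNames(a, genotypes), b = b,
       l = stats::setNames(l, locations), s = s, beta = truth$beta)
}

#' Simulate plot-level row-column trials around true cell means
#'
#' Lays out `n_reps` resolvable replicates of `rows x cols` plots per
#' location, randomizes genotypes to plots within replicate, and adds
#' replicate, row-within-replicate, column-within-replicate and plot-error
#' effects with the Stage I variance components. Yields are written in kg/ha.
#'
#' @param g I x M matrix of true genotype-by-location means (t/ha) with
#'   dimnames
#' @param stage1 named Stage I variance components in (t/ha)^2
#'   (`sigma2_h`, `sigma2_r`, `sigma2_c`, `sigma2_e`)
#' @param rows,cols,n_reps field layout per replicate
#' @param seed RNG seed
#' @return named list of `trial_dataset` objects (kg/ha)
#' @export
simulate_trials <- function(g, stage1, rows = 25, cols = 4, n_reps = 2,
                            seed = 1) {
  set.seed(sub_seed(seed, 4))
  genotypes <- rownames(g); locations <- colnames(g)
  I <- length(genotypes)
  if (rows * cols < I) stop("layout too small for ", I, " genotypes")
  out <- list()
  for (m in seq_along(locations)) {
    rec <- NULL
    h <- stats::rnorm(n_reps, sd = sqrt(stage1["sigma2_h"]))
    for (j in seq_len(n_reps)) {
      cells <- expand.grid(row = seq_len(rows), col = seq_len(cols))
      cells <- cells[sample(nrow(cells), I), , drop = FALSE]
      r_eff <- stats::rnorm(rows, sd = sqrt(stage1["sigma2_r"]))
      c_eff <- stats::rnorm(cols, sd = sqrt(stage1["sigma2_c"]))
      e <- stats::rnorm(I, sd = sqrt(stage1["sigma2_e"]))
      y_t <- g[, m] + h[j] + r_eff[cells$row] + c_eff[cells$col] + e
      rec <- rbind(rec, data.frame(genotype = genotypes, replicate = j,
                                   row = cells$row, column = cells$col,
                                   yield = 1000 * y_t))
    }
    out[[locations[m]]] <- trial_dataset(locations[m], rec$genotype,
                                         rec$replicate, rec$row, rec$column,
                                         rec$yield, yield_unit = "kg/ha")
  }
  out
}

#' Simulate Stage II adjusted means directly
#'
#' Skips the plot level: adds independent mean errors with variance
#' `1/weight` to the true cell means, emulating forwarded Stage I output.
#'
#' @param g I x M matrix of true genotype-by-location means (t/ha)
#' @param weight precision weight of every mean (error variance `1/weight`)
#' @param seed RNG seed
#' @return list of [mean_set()] objects
#' @export
simulate_means <- function(g, weight = 100, seed = 1) {
  set.seed(sub_seed(seed, 5))
  lapply(seq_len(ncol(g)), function(m)
    mean_set(colnames(g)[m], rownames(g),
             g[, m] + stats::rnorm(nrow(g), sd = sqrt(1 / weight)),
             rep(weight, nrow(g))))
}

#' Generate a complete simulated study
#'
#' `"fullscale"`: 6 locations, 100 genotypes from a 3-generation pedigree,
#' 2 replicates of a 25 x 4 row-column layout, 65 ECs. `"tiny"`: 4 locations,
#' 12 genotypes, 20 ECs, direct Stage II means - for fast checks.
#'
#' @param scenario `"fullscale"` or `"tiny"`
#' @param seed scenario seed (expanded into per-component substreams)
#' @param n_sc number of true SC effects (0 or 1)
#' @return list with `pedigree`, `A`, `ec`, `truth`, `gxl` (true effects),
#'   and either `trials` (plot level, fullscale) or `means` (tiny)
#' @export
sim_scenario <- function(scenario = c("fullscale", "tiny"), seed = 1,
                         n_sc = 1) {
  scenario <- match.arg(scenario)
  truth <- default_truth(n_sc)
  if (scenario == "fullscale") {
    ped <- simulate_pedigree(n_founders = 20, n_generations = 3,
                             crosses_per_gen = 100,
                             selfing_prob = 0.1, seed = seed)
    gen <- attr(ped, "final_generation")
    ec <- simulate_ecs(M = 6, P = 65, latent_dim = 3, noise_sd = 0.3,
                       seed = seed)
    A <- numerator_relationship(ped)
    gxl <- simulate_gxl(gen, ec$locations, truth, A = A,
                        env_index = attr(ec, "env_index"), seed = seed)
    trials <- simulate_trials(gxl$g, truth$stage1, rows = 25, cols = 4,
                              n_reps = 2, seed = seed)
    list(pedigree = ped, A = A, ec = ec, truth = truth, gxl = gxl,
         trials = trials)
  } else {
    ped <- simulate_pedigree(n_founders = 6, n_generations = 1,
                             crosses_per_gen = 12, selfing_prob = 0.1,
                             seed = seed)
    gen <- attr(ped, "final_generation")
    ec <- simulate_ecs(M = 4, P = 20, latent_dim = 2, noise_sd = 0.2,
                       seed = seed)
    A <- numerator_relationship(ped)
    truth$sigma2_s <- 0.005
    gxl <- simulate_gxl(gen, ec$locations, truth, A = A,
                        env_index = attr(ec, "env_index"), seed = seed)
    means <- simulate_means(gxl$g, weight = 100, seed = seed)
    list(pedigree = ped, A = A, ec = ec, truth = truth, gxl = gxl,
         means = means)
  }
}
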
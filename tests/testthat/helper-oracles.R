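# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route than the package (brute force, dense linear
# algebra, Monte Carlo) so agreement is informative.

# Gene-dropping estimate of the numerator relationship matrix: founders get
# unique allele pairs, offspring inherit one random allele from each parent;
# A_ij = 2 * P(random allele of i IBD to random allele of j), vectorized over
# n_rep independent drops.
gene_drop_A <- function(ped, n_rep = 2e5, seed = 1) {
  set.seed(seed)
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  al1 <- al2 <- vector("list", n)
  names(al1) <- names(al2) <- ped$genotype
  next_allele <- 0L
  for (i in seq_len(n)) {
    p1 <- ped$parent1[i]; p2 <- ped$parent2[i]
    draw <- function(p) {
      if (is.na(p)) {
        next_allele <<- next_allele + 1L
        rep(next_allele, n_rep)
      } else {
        pick <- stats::runif(n_rep) < 0.5
        ifelse(pick, al1[[p]], al2[[p]])
      }
    }
    al1[[i]] <- draw(p1)
    al2[[i]] <- draw(p2)
  }
  A <- matrix(0, n, n, dimnames = list(ped$genotype, ped$genotype))
  for (i in seq_len(n)) for (j in i:n) {
    f <- 0.25 * (mean(al1[[i]] == al1[[j]]) + mean(al1[[i]] == al2[[j]]) +
                 mean(al2[[i]] == al1[[j]]) + mean(al2[[i]] == al2[[j]]))
    A[i, j] <- A[j, i] <- 2 * f
  }
  ord <- canonical_ids(ped$genotype)
  A[ord, ord]
}

# Dense GLS oracle for the Stage I row-column model: forms V explicitly from
# the design and given variance components and computes GLS means and their
# covariance (X' V^-1 X)^-1.
gls_oracle <- function(trial, vc) {
  gen <- canonical_ids(trial$genotype)
  X <- outer(trial$genotype, gen, "==") * 1
  Zh <- outer(trial$replicate, sort(unique(trial$replicate)), "==") * 1
  rid <- paste(trial$replicate, trial$row)
  cid <- paste(trial$replicate, trial$column)
  Zr <- outer(rid, sort(unique(rid)), "==") * 1
  Zc <- outer(cid, sort(unique(cid)), "==") * 1
  V <- vc["sigma2_h"] * tcrossprod(Zh) + vc["sigma2_r"] * tcrossprod(Zr) +
    vc["sigma2_c"] * tcrossprod(Zc) + vc["sigma2_e"] * diag(length(trial$yield))
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  omega <- solve(XtViX)
  means <- drop(omega %*% crossprod(X, Vi %*% trial$yield))
  list(genotypes = gen, means = means, omega = omega)
}

# Dense Henderson mixed-model-equations oracle for Stage II BLUPs at frozen
# variance parameters.
mme_oracle <- function(mm, params) {
  I <- mm$I; M <- mm$M; n <- I * M
  Q <- mm$spec$n_sc
  Za <- kronecker(rep(1, M), diag(I))
  Zb <- if (Q > 0)
    do.call(cbind, lapply(seq_len(Q), function(q)
      kronecker(mm$T[, 1 + q], diag(I))))
  Zl <- kronecker(diag(M), rep(1, I))
  Zs <- diag(n)
  Z <- cbind(Za, Zb, Zl, Zs)
  Pi <- metstage:::pi_matrix(params$pi, M)
  Gab <- kronecker(params$G, mm$Gamma)
  Gl <- diag(params$sigma2_l, M)
  Gs <- kronecker(Pi, mm$Gamma)          # s in location-major data order
  Gall <- matrix(0, ncol(Z), ncol(Z))
  i1 <- seq_len((1 + Q) * I)
  i2 <- max(i1) + seq_len(M)
  i3 <- max(i2) + seq_len(n)
  Gall[i1, i1] <- Gab; Gall[i2, i2] <- Gl; Gall[i3, i3] <- Gs
  Ri <- diag(1 / mm$d)
  X <- mm$X; y <- mm$y
  C <- rbind(cbind(crossprod(X, Ri %*% X), crossprod(X, Ri %*% Z)),
             cbind(crossprod(Z, Ri %*% X),
                   crossprod(Z, Ri %*% Z) + solve(Gall)))
  rhs <- c(crossprod(X, Ri %*% y), crossprod(Z, Ri %*% y))
  sol <- solve(C, rhs)
  p <- ncol(X)
  u <- sol[-seq_len(p)]
  list(beta = sol[seq_len(p)],
       a = u[seq_len(I)],
       b = if (Q > 0) matrix(u[I + seq_len(Q * I)], I) else NULL,
       l = u[(1 + Q) * I + seq_len(M)],
       s = matrix(u[(1 + Q) * I + M + seq_len(n)], I, M))
}

# Eigen-based PLS2 oracle: the k-th weight vector maximizes cov(Xw, Yq) and
# is the dominant eigenvector of X'YY'X on the deflated matrices; scores,
# loadings and deflation follow in closed form. Independent of the package's
# power-iteration route.
pls_eigen_oracle <- function(X, Y, K) {
  X <- as.matrix(X); Y <- sweep(as.matrix(Y), 2, colMeans(Y))
  M <- nrow(X)
  W <- matrix(0, ncol(X), K); Tm <- matrix(0, M, K)
  Pl <- matrix(0, ncol(X), K); Q <- matrix(0, ncol(Y), K)
  for (k in seq_len(K)) {
    S <- crossprod(X, Y)                     # P x I
    eg <- eigen(tcrossprod(S), symmetric = TRUE)
    w <- eg$vectors[, 1]
    tk <- drop(X %*% w)
    q <- drop(crossprod(Y, tk)) / sum(tk^2)
    p <- drop(crossprod(X, tk)) / sum(tk^2)
    W[, k] <- w; Tm[, k] <- tk; Pl[, k] <- p; Q[, k] <- q
    X <- X - tcrossprod(tk, p)
    Y <- Y - tcrossprod(tk, q)
  }
  list(W = W, T = Tm, P = Pl, Q = Q)
}

# Brute-force triple-loop MSEPD (ordered pairs), as defined.
msepd_brute <- function(observed, predicted) {
  M <- length(observed); I <- length(observed[[1]]$genotypes)
  tot <- 0
  for (m in seq_len(M)) {
    o <- observed[[m]]$means; z <- predicted[[m]]$z
    for (i in seq_len(I)) for (ip in seq_len(I)) if (ip != i)
      tot <- tot + ((o[i] - o[ip]) - (z[i] - z[ip]))^2
  }
  tot / (M * I * (I - 1))
}

# Random mean/prediction instance generator for MSEPD property checks.
random_msepd_instance <- function(M, I, seed) {
  set.seed(seed)
  gen <- sprintf("g%02d", seq_len(I))
  obs <- lapply(seq_len(M), function(m)
    mean_set(sprintf("L%02d", m), gen, rnorm(I, 3), rep(1, I)))
  prd <- lapply(seq_len(M), function(m)
    structure(list(location = sprintf("L%02d", m), genotypes = gen,
                   z = rnorm(I, 3), mode = "main_effect"),
              class = "prediction_set"))
  list(obs = obs, prd = prd)
}

# Small deterministic tiny-study builder shared by Stage II tests.
tiny_stage2 <- function(seed = 3, n_sc = 1, gamma = "identity",
                        pi_structure = "identity", fa_order = 1) {
  sim <- sim_scenario("tiny", seed = seed)
  stk <- stack_means(sim$means)
  sc <- if (n_sc > 0) extract_sc(sim$ec, sim$means, n_sc = n_sc)$sc
  spec <- model_spec(gamma, pi_structure, fa_order = fa_order, n_sc = n_sc)
  mm <- build_stage2(stk, spec, A = sim$A, sc = sc)
  list(sim = sim, stk = stk, sc = sc, spec = spec, mm = mm)
}
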
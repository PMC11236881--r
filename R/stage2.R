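## Stage II: weighted REML across locations with the residual covariance fixed
## at the forwarded diagonal Omega^(d).
##
## Model (location-major stacking, genotype within location):
##   y = 1 mu + t beta + Z1 a + Z2 l + Z3 s + Z4 b + f
## with a (and SC slopes b_q) ~ N(0, G (x) Gamma), l ~ N(0, I_M sigma_l^2),
## s ~ N(0, Gamma (x) Pi) (genotype-major; equals Pi (x) Gamma in the
## location-major data order), var(f) = Omega^(d) fixed. Gamma is I or the
## pedigree A matrix; Pi is I sigma_s^2, a diagonal Phi, or the
## factor-analytic Sigma = Lambda Lambda' + Phi.
##
## Collapsing the (a, b) random-coefficient block gives the marginal
## covariance
##   V = (T G T' + Pi) (x) Gamma + sigma_l^2 (I_M (x) J_I) + D
## where T = [1 | t_1 .. t_Q] (M x (1+Q)) and D = diag(1/weights). The REML
## log-likelihood and its analytic gradient are evaluated densely; problem
## sizes here (I ~ 100, M ~ 6) make that the simplest reliable route.

MODEL_GRID <- list(
  M1  = list(gamma = "identity", pi = "identity", sc = FALSE),
  M2  = list(gamma = "kinship",  pi = "identity", sc = FALSE),
  M3  = list(gamma = "identity", pi = "identity", sc = TRUE),
  M4  = list(gamma = "kinship",  pi = "identity", sc = TRUE),
  M5  = list(gamma = "identity", pi = "diagonal", sc = FALSE),
  M6  = list(gamma = "kinship",  pi = "diagonal", sc = FALSE),
  M7  = list(gamma = "identity", pi = "diagonal", sc = TRUE),
  M8  = list(gamma = "kinship",  pi = "diagonal", sc = TRUE),
  M9  = list(gamma = "identity", pi = "fa",       sc = FALSE),
  M10 = list(gamma = "kinship",  pi = "fa",       sc = FALSE),
  M11 = list(gamma = "identity", pi = "fa",       sc = TRUE),
  M12 = list(gamma = "kinship",  pi = "fa",       sc = TRUE))

#' Specify a Stage II model
#'
#' @param gamma covariance of the genotype dimension: `"identity"` or
#'   `"kinship"` (pedigree A matrix)
#' @param pi_structure genotype-by-location interaction structure:
#'   `"identity"` (one variance), `"diagonal"` (per-location variances) or
#'   `"fa"` (factor-analytic, Lambda Lambda' + Phi)
#' @param fa_order number of factor-analytic components K (1-3)
#' @param n_sc number of synthetic covariates entering as fixed slope plus
#'   per-genotype random slopes (0, 1 or 2)
#' @param prediction_mode `"main_effect"` or `"main_plus_avg_interaction"`
#'   (genotype main effect plus the average of its interaction BLUPs)
#' @return object of class `model_spec`
#' @export
model_spec <- function(gamma = c("identity", "kinship"),
                       pi_structure = c("identity", "diagonal", "fa"),
                       fa_order = 2, n_sc = 0,
                       prediction_mode = c("main_effect",
                                           "main_plus_avg_interaction")) {
  gamma <- match.arg(gamma)
  pi_structure <- match.arg(pi_structure)
  prediction_mode <- match.arg(prediction_mode)
  stopifnot(fa_order %in% 1:3, n_sc %in% 0:2)
  structure(list(gamma = gamma, pi_structure = pi_structure,
                 fa_order = as.integer(fa_order), n_sc = as.integer(n_sc),
                 prediction_mode = prediction_mode),
            class = "model_spec")
}

#' Model specification for one of the standard grid models M1-M12
#'
#' M1-M4 use the identity interaction structure, M5-M8 the diagonal and
#' M9-M12 the factor-analytic; within each block the models are without
#' SC/pedigree, with pedigree, with SC, and with SC plus pedigree.
#'
#' @param model_id one of `"M1"` ... `"M12"`
#' @param n_sc number of SCs for SC models (ignored for non-SC models)
#' @param fa_order factor-analytic order for M9-M12
#' @param prediction_mode see [model_spec()]
#' @return a `model_spec`
#' @export
grid_model <- function(model_id, n_sc = 1, fa_order = 2,
                       prediction_mode = "main_effect") {
  g <- MODEL_GRID[[model_id]]
  if (is.null(g)) stop("unknown model id: ", model_id)
  model_spec(gamma = g$gamma, pi_structure = g$pi,
             fa_order = fa_order, n_sc = if (g$sc) n_sc else 0,
             prediction_mode = prediction_mode)
}

#' Assemble Stage II model matrices
#'
#' @param stacked a `stacked_means` object
#' @param spec a `model_spec`
#' @param A an `a_matrix` (required when `spec$gamma == "kinship"`); its
#'   genotype set must cover the stacked genotypes
#' @param sc numeric matrix of SC scores, locations x n_sc, rownames covering
#'   the stacked locations (required when `spec$n_sc > 0`)
#' @return internal `stage2_model` list (response, fixed design, Gamma, T,
#'   fixed residual diagonal, dimensions)
#' @export
build_stage2 <- function(stacked, spec, A = NULL, sc = NULL) {
  stopifnot(inherits(stacked, "stacked_means"), inherits(spec, "model_spec"))
  gen <- stacked$genotypes; locs <- stacked$locations
  I <- length(gen); M <- length(locs)
  if (M < 2) stop("Stage II needs at least two locations (location variance ",
                  "inestimable with one)")
  if (spec$gamma == "kinship") {
    if (is.null(A)) stop("kinship model requires an A matrix")
    A <- regularize_amatrix(submatrix(A, gen))
    Gamma <- A$values
  } else {
    Gamma <- diag(I)
    dimnames(Gamma) <- list(gen, gen)
  }
  Q <- spec$n_sc
  if (Q > 0) {
    if (is.null(sc)) stop("spec requires ", Q, " SC(s) but none supplied")
    sc <- as.matrix(sc)
    miss <- setdiff(locs, rownames(sc))
    if (length(miss)) stop("missing SC for location(s): ",
                           paste(miss, collapse = ", "))
    if (ncol(sc) < Q) stop("sc has ", ncol(sc), " column(s), spec needs ", Q)
    Tm <- cbind(1, sc[locs, seq_len(Q), drop = FALSE])
  } else {
    Tm <- matrix(1, M, 1)
  }
  rownames(Tm) <- locs
  X <- Tm[rep(seq_len(M), each = I), , drop = FALSE]  # (1, t_m) per cell
  colnames(X) <- c("mu", if (Q > 0) paste0("beta_SC", seq_len(Q)))
  if (length(stacked$y) <= n_varpar(spec, M))
    stop("ill-posed model: ", n_varpar(spec, M), " variance parameters for ",
         length(stacked$y), " observations")
  structure(list(y = stacked$y, X = X, Gamma = Gamma, T = Tm,
                 d = stacked$omega_diag, genotypes = gen, locations = locs,
                 I = I, M = M, spec = spec),
            class = "stage2_model")
}

## Parameter bookkeeping -----------------------------------------------------
## params: list(G = (1+Q)x(1+Q) covariance of (intercept, slopes),
##              sigma2_l, pi = list(type, sigma2_s | phi, Lambda))
## theta: unconstrained vector (Cholesky of G with log diagonal, log sd for
## variances, free Lambda with zero upper triangle).

n_varpar <- function(spec, M) {
  q1 <- spec$n_sc + 1L
  ng <- q1 * (q1 + 1L) / 2L
  npi <- switch(spec$pi_structure,
                identity = 1L,
                diagonal = M,
                fa = M * spec$fa_order - spec$fa_order * (spec$fa_order - 1L) / 2L + M)
  ng + 1L + npi
}

fa_free_idx <- function(M, K) which(row(matrix(0, M, K)) >= col(matrix(0, M, K)))

params_to_theta <- function(params, spec, M) {
  L <- t(chol(params$G))
  diag(L) <- log(diag(L))
  th <- c(L[lower.tri(L, diag = TRUE)], 0.5 * log(params$sigma2_l))
  th <- c(th, switch(spec$pi_structure,
    identity = 0.5 * log(params$pi$sigma2_s),
    diagonal = 0.5 * log(params$pi$phi),
    fa = c(params$pi$Lambda[fa_free_idx(M, spec$fa_order)],
           0.5 * log(params$pi$phi))))
  th
}

theta_to_params <- function(theta, spec, M) {
  q1 <- spec$n_sc + 1L
  ng <- q1 * (q1 + 1L) / 2L
  L <- matrix(0, q1, q1)
  L[lower.tri(L, diag = TRUE)] <- theta[seq_len(ng)]
  diag(L) <- exp(diag(L))
  G <- tcrossprod(L)
  sigma2_l <- exp(2 * theta[ng + 1L])
  rest <- theta[-seq_len(ng + 1L)]
  pi <- switch(spec$pi_structure,
    identity = list(type = "identity", sigma2_s = exp(2 * rest[1])),
    diagonal = list(type = "diagonal", phi = exp(2 * rest)),
    fa = {
      K <- spec$fa_order
      idx <- fa_free_idx(M, K)
      Lam <- matrix(0, M, K)
      Lam[idx] <- rest[seq_along(idx)]
      list(type = "fa", Lambda = Lam, phi = exp(2 * rest[-seq_along(idx)]))
    })
  list(G = G, L = L, sigma2_l = sigma2_l, pi = pi)
}

pi_matrix <- function(pi, M) {
  switch(pi$type,
         identity = diag(pi$sigma2_s, M),
         diagonal = diag(pi$phi, M),
         fa = tcrossprod(pi$Lambda) + diag(pi$phi, M))
}

## Core likelihood machinery -------------------------------------------------

# Builds V, factors it, and returns everything needed for the REML
# log-likelihood, GLS fixed effects, and (optionally) the gradient.
stage2_eval <- function(mm, params, want_gradient = FALSE) {
  I <- mm$I; M <- mm$M; n <- I * M
  Tm <- mm$T
  H <- Tm %*% params$G %*% t(Tm) + pi_matrix(params$pi, M)
  V <- kronecker(H, mm$Gamma)
  for (m in seq_len(M)) {
    ix <- ((m - 1L) * I + 1L):(m * I)
    V[ix, ix] <- V[ix, ix] + params$sigma2_l
  }
  diag(V) <- diag(V) + mm$d
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  X <- mm$X; y <- mm$y; p <- ncol(X)
  ViX <- backsolve(cV, forwardsolve(t(cV), X))
  Viy <- backsolve(cV, forwardsolve(t(cV), y))
  XtViX <- crossprod(X, ViX)
  cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXtViX)) return(NULL)
  beta <- backsolve(cXtViX, forwardsolve(t(cXtViX), crossprod(X, Viy)))
  r <- Viy - ViX %*% beta               # r = P y = V^-1 (y - X beta_hat)
  quad <- sum(y * r)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXtViX))) +
                quad + (n - p) * log(2 * pi))
  out <- list(ll = ll, beta = drop(beta), r = drop(r), H = H, cV = cV)
  if (want_gradient) {
    Vi <- chol2inv(cV)
    B <- backsolve(cXtViX, t(ViX), transpose = TRUE)  # solve(t(C), t(ViX))
    Pmat <- Vi - crossprod(B)                          # REML projection
    out$Pmat <- Pmat
  }
  out
}

# Analytic gradient of the REML log-likelihood w.r.t. the unconstrained theta.
stage2_gradient <- function(mm, params, ev) {
  I <- mm$I; M <- mm$M
  Pmat <- ev$Pmat; r <- ev$r
  Gamma <- mm$Gamma; Tm <- mm$T
  # W[m,m'] = tr(P_{mm'} Gamma) - r_m' Gamma r_{m'}
  Rm <- matrix(r, I, M)
  GR <- Gamma %*% Rm
  S <- crossprod(Rm, GR)
  Qm <- matrix(0, M, M)
  blk <- function(m) ((m - 1L) * I + 1L):(m * I)
  for (a in seq_len(M)) for (b in a:M) {
    v <- sum(Pmat[blk(a), blk(b)] * Gamma)
    Qm[a, b] <- v; Qm[b, a] <- v
  }
  W <- Qm - S
  # location-variance term
  trP <- sum(vapply(seq_len(M), function(m) sum(Pmat[blk(m), blk(m)]), 0))
  rsum2 <- sum(colSums(Rm)^2)
  g_l <- -params$sigma2_l * (trP - rsum2)
  # G (Cholesky) block: dll/dL_uv = -(T' W A)[u,v], A = T L
  L <- params$L
  Am <- Tm %*% L
  M1 <- crossprod(Tm, W %*% Am)
  gL <- -M1
  diag(gL) <- diag(gL) * diag(L)        # chain rule for log-diagonal
  g_G <- gL[lower.tri(gL, diag = TRUE)]
  g_pi <- switch(params$pi$type,
    identity = -params$pi$sigma2_s * sum(diag(W)),
    diagonal = -params$pi$phi * diag(W),
    fa = {
      Lam <- params$pi$Lambda
      gLam <- -(W %*% Lam)
      c(gLam[fa_free_idx(M, ncol(Lam))], -params$pi$phi * diag(W))
    })
  c(g_G, g_l, g_pi)
}

## Starting values -----------------------------------------------------------

stage2_start <- function(mm) {
  spec <- mm$spec; I <- mm$I; M <- mm$M
  Ym <- matrix(mm$y, I, M)
  vy <- stats::var(mm$y)
  va <- vy / 3; vl <- vy / 3; vs <- vy / 3
  q1 <- spec$n_sc + 1L
  G <- diag(c(va, rep(0.05 * va, spec$n_sc)), q1)
  pi <- switch(spec$pi_structure,
    identity = list(type = "identity", sigma2_s = vs),
    diagonal = list(type = "diagonal", phi = rep(vs, M)),
    fa = {
      Cl <- stats::cov(Ym)                   # location x location covariance
      e1 <- eigen(Cl, symmetric = TRUE)
      K <- spec$fa_order
      Lam <- matrix(0.01 * sqrt(vs), M, K)
      Lam[, 1] <- e1$vectors[, 1] * sqrt(max(0.5 * e1$values[1], 0.05 * vs))
      Lam[upper.tri(Lam)] <- 0
      list(type = "fa", Lambda = Lam, phi = rep(0.5 * vs, M))
    })
  list(G = G, sigma2_l = vl, pi = pi)
}

## Fitting -------------------------------------------------------------------

#' Fit a Stage II model by REML
#'
#' Maximizes the REML log-likelihood over the variance parameters with the
#' residual covariance held fixed at the forwarded diagonal (no extra residual
#' scale parameter; the fully efficient stage-wise convention). Optimization
#' uses `nlminb` with the analytic gradient on an unconstrained
#' parameterization; specific variances are bounded below at
#' `1e-8 * var(y)` so factor-analytic fits cannot collapse (Heywood cases are
#' floored and flagged). BLUPs of all random effects are returned.
#'
#' @param mm a `stage2_model` from [build_stage2()]
#' @param start optional parameter list (warm start)
#' @param control list: `iter.max`, `rel.tol`, `restarts` (random restarts
#'   after a failed fit), `seed` (for restart jitter)
#' @return object of class `stage2_fit`
#' @export
reml_fit <- function(mm, start = NULL, control = list()) {
  stopifnot(inherits(mm, "stage2_model"))
  spec <- mm$spec; M <- mm$M
  ctl <- utils::modifyList(list(iter.max = 500, rel.tol = 1e-10,
                                restarts = 2, seed = 1L), control)
  if (is.null(start)) start <- stage2_start(mm)
  theta0 <- params_to_theta(start, spec, M)
  vy <- stats::var(mm$y)
  lower <- rep(-Inf, length(theta0))
  upper <- rep(Inf, length(theta0))
  # bound log-sd parameters of Phi / sigma_s / sigma_l away from 0 and Inf
  bnd_lo <- 0.5 * log(1e-8 * vy); bnd_hi <- 0.5 * log(1e6 * vy)
  q1 <- spec$n_sc + 1L; ng <- q1 * (q1 + 1L) / 2L
  phi_pos <- switch(spec$pi_structure,
    identity = ng + 2L,
    diagonal = ng + 1L + seq_len(M),
    fa = {
      nlam <- M * spec$fa_order - spec$fa_order * (spec$fa_order - 1L) / 2L
      ng + 1L + nlam + seq_len(M)
    })
  lower[c(ng + 1L, phi_pos)] <- bnd_lo
  upper[c(ng + 1L, phi_pos)] <- bnd_hi
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta, want_gradient = FALSE) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (!identical(cache$key, key) || (want_gradient && is.null(cache$ev$Pmat))) {
      pars <- theta_to_params(theta, spec, M)
      cache$pars <- pars
      cache$ev <- stage2_eval(mm, pars, want_gradient = want_gradient)
      cache$key <- key
    }
    cache
  }
  objective <- function(theta) {
    cc <- evaluate(theta)
    if (is.null(cc$ev)) return(1e10)
    -cc$ev$ll
  }
  gradient <- function(theta) {
    cc <- evaluate(theta, want_gradient = TRUE)
    if (is.null(cc$ev)) return(rep(0, length(theta)))
    -stage2_gradient(mm, cc$pars, cc$ev)
  }
  run_one <- function(th0) {
    stats::nlminb(th0, objective, gradient = gradient,
                  lower = lower, upper = upper,
                  control = list(iter.max = ctl$iter.max,
                                 eval.max = 4 * ctl$iter.max,
                                 rel.tol = ctl$rel.tol))
  }
  opt <- run_one(theta0)
  tries <- 0
  while ((!is.finite(opt$objective) || opt$objective >= 1e9) &&
         tries < ctl$restarts) {
    tries <- tries + 1
    set.seed(ctl$seed + tries)
    opt2 <- run_one(theta0 + stats::rnorm(length(theta0), sd = 0.3))
    if (opt2$objective < opt$objective) opt <- opt2
  }
  pars <- theta_to_params(opt$par, spec, M)
  ev <- stage2_eval(mm, pars, want_gradient = FALSE)
  if (is.null(ev)) stop("Stage II REML failed: covariance not factorizable ",
                        "at the returned parameters")
  # nlminb codes like "singular convergence" can flag ridge optima that are
  # perfectly good stationary points; accept them if the projected (KKT)
  # gradient of the objective is numerically zero.
  kkt_ok <- opt$convergence == 0
  if (!kkt_ok) {
    og <- gradient(opt$par)            # gradient of the NEGATIVE loglik
    at_lo <- opt$par <= lower + 1e-8
    at_hi <- opt$par >= upper - 1e-8
    viol <- abs(og)
    viol[at_lo] <- pmax(0, -og[at_lo])   # may not push further down
    viol[at_hi] <- pmax(0, og[at_hi])
    kkt_ok <- max(viol) < 1e-3
  }
  heywood <- switch(spec$pi_structure,
                    identity = FALSE,
                    any(pars$pi$phi <= 1.05e-8 * vy))
  fit <- structure(list(
    spec = spec, params = pars, loglik = ev$ll,
    aic = -2 * ev$ll + 2 * n_varpar(spec, M),
    fixef = stats::setNames(ev$beta, colnames(mm$X)),
    converged = kkt_ok && is.finite(ev$ll),
    n_iter = opt$iterations, message = opt$message,
    heywood = heywood,
    genotypes = mm$genotypes, locations = mm$locations,
    T = mm$T, Gamma = mm$Gamma, I = mm$I, M = mm$M),
    class = "stage2_fit")
  fit$blup <- stage2_blup(mm, pars, ev$r)
  fit
}

# BLUPs from u_hat = Cov(u, y) V^-1 (y - X beta_hat) = Cov(u, y) %*% Py.
stage2_blup <- function(mm, params, r) {
  I <- mm$I; M <- mm$M
  Rm <- matrix(r, I, M)
  B <- mm$Gamma %*% Rm                           # I x M
  TG <- mm$T %*% params$G                        # M x (1+Q)
  ab <- B %*% TG                                 # I x (1+Q): col 1 = a, rest b
  Pi <- pi_matrix(params$pi, M)
  s <- B %*% Pi                                  # I x M interaction BLUPs
  dimnames(s) <- list(mm$genotypes, mm$locations)
  l <- params$sigma2_l * colSums(Rm)
  list(a = stats::setNames(ab[, 1], mm$genotypes),
       b = if (ncol(ab) > 1)
         matrix(ab[, -1, drop = FALSE], nrow = I,
                dimnames = list(mm$genotypes,
                                paste0("SC", seq_len(ncol(ab) - 1L))))
       else NULL,
       l = stats::setNames(l, mm$locations),
       s = s)
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat("<stage2_fit>", x$spec$gamma, "genotype cov /", x$spec$pi_structure,
      "interaction", if (x$spec$pi_structure == "fa")
        paste0("(K=", x$spec$fa_order, ")") else "",
      if (x$spec$n_sc > 0) paste0("+ ", x$spec$n_sc, " SC") else "", "\n")
  cat("  REML loglik", round(x$loglik, 4), " AIC", round(x$aic, 4),
      if (!x$converged) " [NOT CONVERGED]" else "",
      if (x$heywood) " [Heywood: specific variance at floor]" else "", "\n")
  invisible(x)
}

#' REML log-likelihood at fixed variance parameters
#'
#' Evaluates the Stage II REML log-likelihood (and GLS fixed effects/BLUPs)
#' at user-supplied variance parameters without optimizing. Used for frozen
#' -parameter checks and rotation-invariance diagnostics.
#'
#' @param mm a `stage2_model`
#' @param params list with `G` ((1+Q) x (1+Q)), `sigma2_l`, and `pi` (a list
#'   with `type` and `sigma2_s`/`phi`/`Lambda` as applicable)
#' @return list with `loglik`, `fixef`, `blup`
#' @export
stage2_at <- function(mm, params) {
  ev <- stage2_eval(mm, params, want_gradient = FALSE)
  if (is.null(ev)) stop("covariance matrix not positive definite")
  list(loglik = ev$ll, fixef = stats::setNames(ev$beta, colnames(mm$X)),
       blup = stage2_blup(mm, params, ev$r))
}

#' Fit factor-analytic orders and select by AIC
#'
#' Fits FA(K) for each requested order with warm starts (the order-K loadings
#' seed order K+1) and returns the AIC-minimal fit; ties break toward the
#' smaller order.
#'
#' @param mm a `stage2_model` with `pi_structure = "fa"` (its `fa_order` is
#'   ignored)
#' @param orders candidate orders
#' @param control passed to [reml_fit()]
#' @return the selected `stage2_fit`; attribute `"aic_path"` holds the
#'   per-order AIC table
#' @export
fit_fa_order_path <- function(mm, orders = 1:3, control = list()) {
  stopifnot(mm$spec$pi_structure == "fa")
  orders <- sort(orders)
  fits <- list(); warm <- NULL
  errors <- character(0)
  for (K in orders) {
    spec_k <- mm$spec; spec_k$fa_order <- as.integer(K)
    mm_k <- mm; mm_k$spec <- spec_k
    start <- NULL
    if (!is.null(warm)) {
      start <- warm$params
      Lam <- matrix(0.01 * sqrt(mean(warm$params$pi$phi)), mm$M, K)
      kprev <- ncol(warm$params$pi$Lambda)
      Lam[, seq_len(min(kprev, K))] <-
        warm$params$pi$Lambda[, seq_len(min(kprev, K))]
      Lam[upper.tri(Lam)] <- 0
      start$pi <- list(type = "fa", Lambda = Lam, phi = warm$params$pi$phi)
    }
    f <- tryCatch(reml_fit(mm_k, start = start, control = control),
                  error = function(e) e)
    if (inherits(f, "error")) {
      errors <- c(errors, paste0("FA(", K, "): ", conditionMessage(f)))
    } else {
      fits[[paste0("FA", K)]] <- f
      warm <- f
    }
  }
  if (!length(fits))
    stop("all factor-analytic orders failed:\n", paste(errors, collapse = "\n"))
  aics <- vapply(fits, function(f) f$aic, 0)
  best <- fits[[which.min(aics)]]   # which.min takes the first (smallest K) tie
  attr(best, "aic_path") <- data.frame(order = as.integer(sub("FA", "", names(aics))),
                                       aic = unname(aics))
  best
}
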
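## Synthetic covariates by multivariate PLS (NIPALS / orthogonal scores).
##
## X = standardized environmental covariates (locations x covariates),
## Y = genotype-by-location adjusted means with each genotype's response as a
## separate variate (locations x genotypes, column-centered). The component
## scores t characterize each location and are carried into Stage II as
## synthetic covariates (SCs).

#' Standardize environmental covariates to mean zero, unit variance
#'
#' Column means and sample (n-1) standard deviations are computed on the
#' `reference_locations` only; all rows are transformed with those statistics,
#' so held-out locations never influence the standardization.
#'
#' @param ec an `ec_table`
#' @param reference_locations locations defining the statistics (default all)
#' @return object of class `standardized_ecs` with `z` (all locations),
#'   `center`, `scale`, `reference_locations`
#' @export
standardize_ecs <- function(ec, reference_locations = ec$locations) {
  stopifnot(inherits(ec, "ec_table"))
  ref <- match(reference_locations, ec$locations)
  if (anyNA(ref)) stop("reference location(s) not in EC table: ",
                       paste(reference_locations[is.na(ref)], collapse = ", "))
  if (length(ref) < 2) stop("need at least two reference locations")
  xr <- ec$values[ref, , drop = FALSE]
  ctr <- colMeans(xr)
  scl <- apply(xr, 2, stats::sd)
  zero <- scl <= 0
  if (any(zero))
    stop("zero standard deviation over the reference locations for: ",
         paste(colnames(ec$values)[zero], collapse = ", "))
  z <- sweep(sweep(ec$values, 2, ctr), 2, scl, "/")
  rownames(z) <- ec$locations
  structure(list(z = z, center = ctr, scale = scl,
                 locations = ec$locations,
                 reference_locations = ec$locations[sort(ref)]),
            class = "standardized_ecs")
}

#' Multivariate PLS (NIPALS) of genotype responses on standardized ECs
#'
#' Orthogonal-scores PLS2. `x` rows and `y_matrix` rows must correspond to the
#' same training locations; `y_matrix` columns (one per genotype) are centered
#' internally and not scaled (all responses share the t/ha unit).
#'
#' @param x numeric matrix of standardized ECs for the training locations
#'   (M x P), e.g. the training rows of `standardize_ecs()$z`
#' @param y_matrix M x I matrix of adjusted genotype means (t/ha)
#' @param n_components number of latent components K, at most `min(M-1, P)`
#' @param tol NIPALS inner-loop convergence tolerance on the scores
#' @return object of class `pls_model` with x_weights (P x K), x_scores
#'   (M x K, the SC values), x_loadings, y_loadings, coefficients (P x I),
#'   x_variance_explained and y_variance_explained (percent per component)
#' @export
fit_pls <- function(x, y_matrix, n_components, tol = 1e-12) {
  x <- as.matrix(x); y_matrix <- as.matrix(y_matrix)
  M <- nrow(x); P <- ncol(x); I <- ncol(y_matrix)
  stopifnot(nrow(y_matrix) == M)
  if (n_components > min(M - 1, P))
    stop("n_components must be <= min(M-1, P) = ", min(M - 1, P))
  y_center <- colMeans(y_matrix)
  X <- x
  Y <- sweep(y_matrix, 2, y_center)
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  W <- matrix(0, P, n_components); Pl <- matrix(0, P, n_components)
  Tm <- matrix(0, M, n_components); Q <- matrix(0, I, n_components)
  xve <- yve <- numeric(n_components)
  for (k in seq_len(n_components)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, M)
    for (it in 1:500) {
      w <- drop(crossprod(X, u))
      w <- w / sqrt(sum(w^2))
      tk <- drop(X %*% w)
      q <- drop(crossprod(Y, tk)) / sum(tk^2)
      u <- drop(Y %*% q) / sum(q^2)
      if (sqrt(sum((tk - t_old)^2)) < tol * sqrt(sum(tk^2))) break
      t_old <- tk
    }
    p <- drop(crossprod(X, tk)) / sum(tk^2)
    W[, k] <- w; Tm[, k] <- tk; Pl[, k] <- p; Q[, k] <- q
    X <- X - tcrossprod(tk, p)
    Y <- Y - tcrossprod(tk, q)
    xve[k] <- 100 * sum(tk^2) * sum(p^2) / ssx0
    yve[k] <- 100 * sum(tk^2) * sum(q^2) / ssy0
  }
  # regression coefficients on the standardized EC scale: B = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(Pl, W), t(Q))
  dimnames(B) <- list(colnames(x), colnames(y_matrix))
  rownames(W) <- rownames(Pl) <- colnames(x)
  rownames(Tm) <- rownames(x)
  rownames(Q) <- colnames(y_matrix)
  structure(list(n_components = n_components,
                 x_weights = W, x_scores = Tm, x_loadings = Pl,
                 y_loadings = Q, coefficients = B, y_center = y_center,
                 x_variance_explained = xve, y_variance_explained = yve),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model>", x$n_components, "component(s); X-variance explained:",
      paste(sprintf("%.2f%%", x$x_variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Project a new location onto the fitted PLS components
#'
#' Applies the fitted weight/deflation sequence to a standardized EC row
#' (standardized with the training statistics). Projecting a training row
#' reproduces its stored scores.
#'
#' @param model a `pls_model`
#' @param z_row length-P standardized EC vector
#' @return length-K vector of synthetic-covariate scores
#' @export
project_location <- function(model, z_row) {
  z_row <- as.numeric(z_row)
  if (length(z_row) != nrow(model$x_weights))
    stop("z_row has length ", length(z_row), ", expected ",
         nrow(model$x_weights))
  scores <- numeric(model$n_components)
  for (k in seq_len(model$n_components)) {
    scores[k] <- sum(z_row * model$x_weights[, k])
    z_row <- z_row - scores[k] * model$x_loadings[, k]
  }
  scores
}

#' Rank environmental covariates by their PLS coefficient
#'
#' Reduces the P x I coefficient structure to one coefficient per covariate as
#' the first-component weight times the sum of the first-component response
#' loadings, and ranks by absolute value. This identifies the dominant
#' covariates in the first synthetic covariate.
#'
#' @param model a `pls_model`
#' @param top_n number of covariates to return (capped at P)
#' @return data frame with columns `rank`, `covariate`, `coefficient`
#' @export
coefficient_ranking <- function(model, top_n = 15) {
  coef1 <- model$x_weights[, 1] * sum(model$y_loadings[, 1])
  ord <- order(abs(coef1), decreasing = TRUE)
  n <- min(top_n, length(coef1))
  data.frame(rank = seq_len(n),
             covariate = rownames(model$x_weights)[ord[seq_len(n)]],
             coefficient = unname(coef1[ord[seq_len(n)]]),
             stringsAsFactors = FALSE)
}

#' Extract synthetic covariates for training and held-out locations
#'
#' Convenience wrapper used by the cross-validation driver: standardizes the
#' ECs on the training locations, fits the PLS on the training rows against
#' the genotype-by-location mean matrix, and returns SC scores for all
#' locations (training rows from the fit, others by projection). Scores are
#' scaled to unit sample standard deviation over the training locations, which
#' only reparameterizes the Stage II regression.
#'
#' @param ec an `ec_table` covering training and held-out locations
#' @param train_means list of [mean_set()] for the training locations
#' @param n_sc number of synthetic covariates (components)
#' @return list with `sc` (matrix locations x n_sc over all EC locations),
#'   `model` (the `pls_model`), `train_locations`
#' @export
extract_sc <- function(ec, train_means, n_sc) {
  stk <- stack_means(train_means, intersect = TRUE)
  train_locs <- stk$locations
  std <- standardize_ecs(ec, reference_locations = train_locs)
  Ym <- matrix(stk$y, nrow = length(train_locs), byrow = TRUE,
               dimnames = list(train_locs, stk$genotypes))
  model <- fit_pls(std$z[train_locs, , drop = FALSE], Ym, n_components = n_sc)
  sc <- t(apply(std$z, 1, function(zr) project_location(model, zr)))
  sc <- matrix(sc, ncol = n_sc,
               dimnames = list(std$locations, paste0("SC", seq_len(n_sc))))
  sds <- apply(sc[train_locs, , drop = FALSE], 2, stats::sd)
  sds[sds <= 0] <- 1
  sc <- sweep(sc, 2, sds, "/")
  list(sc = sc, model = model, train_locations = train_locs)
}
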
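## Prediction for untested locations and leave-one-location-out
## cross-validation scored by MSEPD and averaged Spearman rank correlation.

#' Predict genotype values for a new (untested) location
#'
#' `main_effect` mode: `z_i = mu + sum_q t_q (beta_q + b_iq) + a_i`; the BLUP
#' of the unseen location's main effect is 0. `main_plus_avg_interaction`
#' additionally adds the average over training locations of the genotype's
#' interaction BLUPs (used with covariance-carrying interaction structures,
#' where part of the genotype main effect is absorbed in the interactions).
#'
#' @param fit a `stage2_fit`
#' @param sc_new length-`n_sc` vector of SC scores for the new location
#'   (required iff the model has SCs)
#' @param mode prediction mode; defaults to the one in the fitted spec
#' @param location identifier recorded on the returned prediction set
#' @return object of class `prediction_set` with `genotypes` and `z` (t/ha)
#' @export
predict_new_location <- function(fit, sc_new = NULL,
                                 mode = fit$spec$prediction_mode,
                                 location = "new") {
  stopifnot(inherits(fit, "stage2_fit"))
  mode <- match.arg(mode, c("main_effect", "main_plus_avg_interaction"))
  Q <- fit$spec$n_sc
  z <- fit$fixef[["mu"]] + fit$blup$a
  if (Q > 0) {
    if (is.null(sc_new) || length(sc_new) < Q)
      stop("model has ", Q, " SC(s); supply sc_new of that length")
    sc_new <- as.numeric(sc_new)[seq_len(Q)]
    beta <- fit$fixef[-1]
    z <- z + sum(sc_new * beta) + drop(fit$blup$b %*% sc_new)
  }
  if (mode == "main_plus_avg_interaction") {
    if (is.null(fit$blup$s))
      stop("fit carries no interaction BLUPs; cannot average them")
    z <- z + rowMeans(fit$blup$s)
  }
  structure(list(location = location, genotypes = fit$genotypes,
                 z = unname(z), mode = mode),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set>", x$location, "-", length(x$z), "genotypes (",
      x$mode, ")\n")
  invisible(x)
}

#' Mean squared error of predicted differences
#'
#' For each location, compares every ordered pair of genotypes: the squared
#' discrepancy between the observed difference of adjusted means and the
#' predicted difference, summed over all ordered pairs `i != i'` and all
#' locations, divided by `M * I * (I - 1)`. Invariant to per-location additive
#' shifts of the predictions.
#'
#' @param observed list of [mean_set()] (the held-out adjusted means)
#' @param predicted list of `prediction_set`, same locations and genotypes
#' @return MSEPD in t^2/ha^2
#' @export
msepd <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  obs_locs <- vapply(observed, function(s) s$location, character(1))
  prd_locs <- vapply(predicted, function(p) p$location, character(1))
  predicted <- predicted[match(obs_locs, prd_locs)]
  if (anyNA(match(obs_locs, prd_locs)))
    stop("locations of observed and predicted sets do not match")
  num <- 0; M <- length(observed); I <- NULL
  for (m in seq_len(M)) {
    o <- observed[[m]]; p <- predicted[[m]]
    if (!identical(o$genotypes, p$genotypes))
      stop("genotype sets differ at location '", o$location, "'")
    if (is.null(I)) I <- length(o$genotypes)
    if (length(o$genotypes) != I)
      stop("genotype count differs across locations")
    d <- o$means - p$z
    # sum over ordered pairs of ((d_i - d_i')^2) = 2 I sum d^2 - 2 (sum d)^2
    num <- num + 2 * I * sum(d^2) - 2 * sum(d)^2
  }
  if (I < 2) stop("MSEPD needs at least two genotypes")
  num / (M * I * (I - 1))
}

#' Per-location Spearman rank correlation between observed and predicted
#'
#' Computed with average ranks for ties, per location, then averaged; the
#' standard error is the between-location standard deviation divided by
#' `sqrt(M)`. Locations with a constant observed or predicted vector give an
#' undefined correlation: recorded as `NA`, excluded from the mean with a
#' warning.
#'
#' @inheritParams msepd
#' @return list with `per_location` (named vector), `mean`, `se`
#' @export
spearman_by_location <- function(observed, predicted) {
  obs_locs <- vapply(observed, function(s) s$location, character(1))
  prd_locs <- vapply(predicted, function(p) p$location, character(1))
  predicted <- predicted[match(obs_locs, prd_locs)]
  rho <- vapply(seq_along(observed), function(m) {
    o <- observed[[m]]; p <- predicted[[m]]
    if (length(o$means) < 3) stop("need >= 3 genotypes per location")
    if (stats::sd(o$means) == 0 || stats::sd(p$z) == 0) return(NA_real_)
    stats::cor(o$means, p$z, method = "spearman")
  }, 0)
  names(rho) <- obs_locs
  if (anyNA(rho))
    warning("undefined Spearman correlation at: ",
            paste(obs_locs[is.na(rho)], collapse = ", "))
  ok <- rho[!is.na(rho)]
  list(per_location = rho, mean = mean(ok),
       se = stats::sd(ok) / sqrt(length(ok)))
}

#' Leave-one-location-out cross-validation of a Stage II model
#'
#' Each location in turn is removed; the synthetic covariates (if any) are
#' re-extracted on the training locations only (standardization and PLS refit
#' without the held-out location, whose SC comes from projection), the Stage
#' II model is refitted by REML on the training means, and the held-out
#' location is predicted. Folds are scored jointly by [msepd()] and
#' [spearman_by_location()] against the held-out Stage I adjusted means.
#'
#' @param means list of [mean_set()] over all locations (t/ha)
#' @param spec a `model_spec`
#' @param A an `a_matrix` for kinship models
#' @param ec an `ec_table` for SC models
#' @param control passed to [reml_fit()]
#' @param strict if `TRUE`, any non-converged fold gives `msepd = NA`
#' @return object of class `cv_result`
#' @export
leave_one_location_out <- function(means, spec, A = NULL, ec = NULL,
                                   control = list(), strict = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  M <- length(means)
  if (M < 3) stop("leave-one-location-out CV needs at least 3 locations")
  locs <- vapply(means, function(s) s$location, character(1))
  ord <- order(locs, method = "radix")
  means <- means[ord]; locs <- locs[ord]
  preds <- vector("list", M)
  observed <- vector("list", M)
  failed <- character(0)
  for (m in seq_len(M)) {
    train <- means[-m]
    if (spec$n_sc > 0) {
      if (is.null(ec)) stop("SC model requires an EC table")
      scx <- extract_sc(ec, train, n_sc = spec$n_sc)
      sc <- scx$sc
      sc_new <- sc[locs[m], ]
    } else {
      sc <- NULL; sc_new <- NULL
    }
    stacked <- stack_means(train, intersect = TRUE)
    mm <- build_stage2(stacked, spec, A = A, sc = sc)
    fit <- reml_fit(mm, control = control)
    if (!fit$converged) failed <- c(failed, locs[m])
    pred <- predict_new_location(fit, sc_new = sc_new, location = locs[m])
    # score on the genotypes the training fit could predict
    ho <- means[[m]]
    keep <- match(fit$genotypes, ho$genotypes)
    if (anyNA(keep))
      stop("held-out location '", locs[m], "' lacks means for trained genotypes")
    observed[[m]] <- mean_set(ho$location, ho$genotypes[keep],
                              ho$means[keep], ho$weights[keep])
    preds[[m]] <- pred
  }
  sp <- spearman_by_location(observed, preds)
  ms <- msepd(observed, preds)
  structure(list(model_id = NA_character_, spec = spec,
                 n_sc = spec$n_sc, prediction_mode = spec$prediction_mode,
                 msepd = if (strict && length(failed)) NA_real_ else ms,
                 msepd_all_folds = ms,
                 per_location = as.list(sp$per_location),
                 mean_rho = sp$mean, se_rho = sp$se,
                 predictions = preds, observed = observed,
                 failed_folds = failed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", if (!is.na(x$model_id)) x$model_id else "",
      sprintf("MSEPD = %.5f t^2/ha^2, mean Spearman rho = %.4f (SE %.3f)\n",
              x$msepd_all_folds, x$mean_rho, x$se_rho))
  if (length(x$failed_folds))
    cat("  non-converged folds:", paste(x$failed_folds, collapse = ", "), "\n")
  invisible(x)
}
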
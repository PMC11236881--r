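## Stage I: per-location row-column adjustment.
##
## Model for one trial: y = mu + genotype (fixed) + replicate + row-in-rep +
## column-in-rep (random, independent) + plot error. Fitted by REML in a
## cell-means parameterization (one fixed mean per genotype), so the adjusted
## means are the fixed-effect estimates and their variance-covariance matrix
## Omega_m is the corresponding block of the inverse coefficient matrix,
## (X' V^-1 X)^-1 at the REML variance estimates.

#' Fit the per-location row-column model and return adjusted means
#'
#' @param trial a `trial_dataset`
#' @return object of class `stage1_fit`: adjusted means (input units), the
#'   variance-covariance matrix `omega` of the means, REML variance components
#'   (`sigma2_h` replicates, `sigma2_r` rows within replicate, `sigma2_c`
#'   columns within replicate, `sigma2_e` residual), REML log-likelihood and
#'   boundary flags
#' @export
fit_rowcol_model <- function(trial) {
  stopifnot(inherits(trial, "trial_dataset"))
  d <- data.frame(genotype = factor(trial$genotype,
                                    levels = canonical_ids(trial$genotype)),
                  rep = factor(trial$replicate),
                  row = factor(paste(trial$replicate, trial$row, sep = ":")),
                  col = factor(paste(trial$replicate, trial$column, sep = ":")),
                  y = trial$yield)
  fit <- lme4::lmer(
    y ~ 0 + genotype + (1 | rep) + (1 | row) + (1 | col),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore",
                                calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  varcomps <- c(sigma2_h = getv("rep"), sigma2_r = getv("row"),
                sigma2_c = getv("col"), sigma2_e = getv("Residual"))
  means <- lme4::fixef(fit)
  omega <- as.matrix(stats::vcov(fit))
  gnames <- sub("^genotype", "", names(means))
  names(means) <- gnames
  dimnames(omega) <- list(gnames, gnames)
  structure(list(location = trial$location,
                 genotypes = gnames,
                 means = as.numeric(means),
                 omega = omega,
                 varcomps = varcomps,
                 boundary = varcomps[1:3] < 1e-10 * varcomps["sigma2_e"],
                 loglik = as.numeric(stats::logLik(fit)),
                 yield_unit = trial$yield_unit,
                 n_plots = nrow(d)),
            class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("<stage1_fit>", x$location, "-", length(x$genotypes), "genotype means (",
      x$yield_unit, ")\n  varcomps:",
      paste(names(x$varcomps), signif(x$varcomps, 4), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Forward a Stage I fit to Stage II: means in t/ha with diagonal weights
#'
#' The weights are the diagonal elements of the full inverse of `omega`
#' (not the reciprocal diagonal of `omega`). Means fitted in kg/ha are
#' converted to t/ha (and `omega` to (t/ha)^2) so that prediction errors are
#' reported in t^2/ha^2.
#'
#' @param fit a `stage1_fit`
#' @return a [mean_set()]
#' @export
stage2_weights <- function(fit) {
  stopifnot(inherits(fit, "stage1_fit"))
  scale <- if (identical(fit$yield_unit, "kg/ha")) 1000 else 1
  means <- fit$means / scale
  omega <- fit$omega / scale^2
  oi <- try(solve(omega), silent = TRUE)
  if (inherits(oi, "try-error"))
    stop("Omega_m singular at location '", fit$location,
         "'; drop means or regularize before forwarding to Stage II")
  mean_set(fit$location, fit$genotypes, means, diag(oi))
}

#' Run Stage I over all locations
#'
#' @param trials list of `trial_dataset` objects
#' @return list of [mean_set()] objects (means in t/ha)
#' @export
stage1_all <- function(trials) {
  lapply(trials, function(tr) stage2_weights(fit_rowcol_model(tr)))
}
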
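#' metstage: two-stage mixed-model prediction for untested locations
#'
#' Stage-wise analysis of multi-environment trials (MET): per-location
#' row-column adjustment (Stage I), weighted across-location mixed models with
#' pedigree kinship, identity/diagonal/factor-analytic genotype-by-location
#' covariance and PLS-derived synthetic environmental covariates (Stage II),
#' evaluated by leave-one-location-out cross-validation.
#'
#' @keywords internal
"_PACKAGE"

## Canonical orderings ------------------------------------------------------

#' Canonical (locale-independent lexicographic) ordering of identifiers
#'
#' All genotype and location indexing in the package runs off this single
#' ordering so that matrices built in different modules align.
#'
#' @param x character vector of identifiers
#' @return sorted unique identifiers
#' @export
canonical_ids <- function(x) {
  sort(unique(as.character(x)), method = "radix")
}

## MeanSet -------------------------------------------------------------------

#' Adjusted genotype means of one location with Stage II weights
#'
#' @param location location identifier
#' @param genotypes character vector of genotype identifiers
#' @param means adjusted means, t/ha
#' @param weights strictly positive weights, the diagonal elements of the
#'   inverse of the Stage I variance-covariance matrix of the means
#' @return object of class `mean_set`
#' @export
mean_set <- function(location, genotypes, means, weights) {
  genotypes <- as.character(genotypes)
  stopifnot(length(genotypes) == length(means),
            length(genotypes) == length(weights))
  if (anyDuplicated(genotypes))
    stop("duplicate genotype in means for location '", location, "'")
  if (any(!is.finite(means)))
    stop("non-finite adjusted mean for location '", location, "'")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be strictly positive for location '", location, "'")
  ord <- order(genotypes, method = "radix")
  structure(list(location = as.character(location),
                 genotypes = genotypes[ord],
                 means = as.numeric(means)[ord],
                 weights = as.numeric(weights)[ord]),
            class = "mean_set")
}

#' @export
print.mean_set <- function(x, ...) {
  cat("<mean_set> location", x$location, "-", length(x$genotypes),
      "genotypes, mean yield", round(mean(x$means), 3), "t/ha\n")
  invisible(x)
}

#' Stack per-location mean sets into the Stage II response
#'
#' Concatenates adjusted means location-major (genotype within location) and
#' builds the diagonal of the fixed residual covariance as the inverse of the
#' forwarded weights. Genotype sets must agree across locations unless
#' `intersect = TRUE`, in which case the common (canonically sorted) subset is
#' kept.
#'
#' @param sets list of [mean_set()] objects
#' @param intersect keep only genotypes present at every location
#' @return object of class `stacked_means` with elements `y` (length I*M),
#'   `omega_diag` (1/weights, same order), `genotypes`, `locations`
#' @export
stack_means <- function(sets, intersect = FALSE) {
  stopifnot(length(sets) >= 1)
  locs <- vapply(sets, function(s) s$location, character(1))
  if (anyDuplicated(locs)) stop("duplicate locations in mean sets")
  ord <- order(locs, method = "radix")
  sets <- sets[ord]
  locs <- locs[ord]
  glists <- lapply(sets, function(s) s$genotypes)
  common <- Reduce(base::intersect, glists)
  all_same <- all(vapply(glists, function(g) identical(g, glists[[1]]), logical(1)))
  if (!all_same && !intersect)
    stop("genotype sets differ across locations; use intersect = TRUE to keep ",
         length(common), " common genotypes")
  gen <- canonical_ids(common)
  if (length(gen) < 2) stop("fewer than two genotypes common to all locations")
  y <- numeric(0); w <- numeric(0)
  for (s in sets) {
    idx <- match(gen, s$genotypes)
    y <- c(y, s$means[idx])
    w <- c(w, s$weights[idx])
  }
  structure(list(y = y, omega_diag = 1 / w, weights = w,
                 genotypes = gen, locations = locs,
                 mean_sets = sets),
            class = "stacked_means")
}

#' @export
print.stacked_means <- function(x, ...) {
  cat("<stacked_means>", length(x$genotypes), "genotypes x",
      length(x$locations), "locations (", length(x$y), "means )\n")
  invisible(x)
}

#' Drop genotypes without pedigree entries from the Stage I means
#'
#' Genotypes that do not appear in the pedigree (typically checks) cannot carry
#' a kinship-based genotype effect and are removed between the stages; the
#' dropped identifiers are reported via a message and an attribute.
#'
#' @param sets list of [mean_set()] objects
#' @param pedigree a `pedigree_table`
#' @return the list with unpedigreed genotypes removed; attribute `"dropped"`
#'   lists them
#' @export
drop_unpedigreed <- function(sets, pedigree) {
  known <- pedigree$genotype
  dropped <- character(0)
  out <- lapply(sets, function(s) {
    keep <- s$genotypes %in% known
    dropped <<- union(dropped, s$genotypes[!keep])
    mean_set(s$location, s$genotypes[keep], s$means[keep], s$weights[keep])
  })
  if (length(dropped))
    message("dropped ", length(dropped), " genotype(s) without pedigree: ",
            paste(dropped, collapse = ", "))
  attr(out, "dropped") <- dropped
  out
}
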
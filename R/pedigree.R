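## Numerator relationship matrix from pedigree records (tabular method).

#' Numerator relationship matrix A from a pedigree
#'
#' Tabular (recursive) construction over the topologically sorted pedigree:
#' `A[i,i] = d + 0.5 * A[p1,p2]` and `A[i,j] = 0.5 * (A[j,p1] + A[j,p2])` for
#' earlier `j`, with unknown-parent terms contributing 0. `d = 1` for
#' non-inbred founders; with `founders_inbred = TRUE` founder diagonals are set
#' to 2 (fully inbred lines) and the same recursion applies. Selfing
#' (`parent1 == parent2`) is supported.
#'
#' The result is returned in canonical genotype order.
#'
#' @param ped a `pedigree_table`
#' @param founders_inbred treat founders as fully inbred (diagonal 2)
#' @return object of class `a_matrix`: list with `genotypes` and symmetric
#'   matrix `values`
#' @export
numerator_relationship <- function(ped, founders_inbred = FALSE) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$genotype, ped$genotype))
  idx <- stats::setNames(seq_len(n), ped$genotype)
  for (i in seq_len(n)) {
    p1 <- ped$parent1[i]; p2 <- ped$parent2[i]
    i1 <- if (is.na(p1)) 0L else idx[[p1]]
    i2 <- if (is.na(p2)) 0L else idx[[p2]]
    if (i > 1) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (i1) A[j, i1] else 0) + (if (i2) A[j, i2] else 0))
      A[j, i] <- aj
      A[i, j] <- aj
    }
    base <- if (i1 == 0L && i2 == 0L && founders_inbred) 2 else 1
    A[i, i] <- base + if (i1 && i2) 0.5 * A[i1, i2] else 0
  }
  ord <- canonical_ids(ped$genotype)
  structure(list(genotypes = ord, values = A[ord, ord, drop = FALSE]),
            class = "a_matrix")
}

#' @export
print.a_matrix <- function(x, ...) {
  cat("<a_matrix>", length(x$genotypes), "genotypes, mean diagonal",
      round(mean(diag(x$values)), 3), "\n")
  invisible(x)
}

#' Principal submatrix of an A matrix
#'
#' @param A an `a_matrix`
#' @param genotypes identifiers to keep; returned in canonical order
#' @return an `a_matrix` over the requested genotypes
#' @export
submatrix <- function(A, genotypes) {
  genotypes <- as.character(genotypes)
  unknown <- setdiff(genotypes, A$genotypes)
  if (length(unknown))
    stop("genotype(s) not in A matrix: ", paste(unknown, collapse = ", "))
  keep <- canonical_ids(genotypes)
  structure(list(genotypes = keep,
                 values = A$values[keep, keep, drop = FALSE]),
            class = "a_matrix")
}

#' Ensure an A matrix admits a Cholesky factorization
#'
#' Adds a ridge to the diagonal if `chol()` fails (near-singular pedigrees),
#' with a message.
#'
#' @param A an `a_matrix`
#' @param ridge diagonal inflation used when needed
#' @return an `a_matrix` guaranteed to be positive definite in `chol()`
#' @export
regularize_amatrix <- function(A, ridge = 1e-6) {
  ok <- !inherits(try(chol(A$values), silent = TRUE), "try-error")
  if (!ok) {
    message("A matrix numerically singular; adding ridge ", ridge,
            " to the diagonal")
    A$values <- A$values + diag(ridge, nrow(A$values))
  }
  A
}

#' Export an A matrix as sparse 3-column CSV
#'
#' Writes upper-triangle (including diagonal) non-zero entries as
#' `genotype1,genotype2,value`.
#'
#' @param A an `a_matrix`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_amatrix <- function(A, path) {
  V <- A$values
  ut <- which(upper.tri(V, diag = TRUE) & V != 0, arr.ind = TRUE)
  df <- data.frame(genotype1 = A$genotypes[ut[, 1]],
                   genotype2 = A$genotypes[ut[, 2]],
                   value = V[ut], stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
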
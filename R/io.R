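## CSV readers/writers for the exchange formats. Comma-separated, UTF-8,
## '.' decimal, mandatory header throughout.

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

num_or_stop <- function(x, what, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & trimws(x) != "" & toupper(trimws(x)) != "NA")
  if (length(bad))
    stop("non-numeric ", what, " in ", path, " at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  v
}

#' Read plot-level trial data
#'
#' Expects columns `location,genotype,replicate,row,column,yield`. Yields are
#' kept in the input unit (default kg/ha). Rows with a missing yield are
#' dropped with a message.
#'
#' @param path CSV file path
#' @param yield_unit unit of the yield column, `"kg/ha"` or `"t/ha"`
#' @return named list of `trial_dataset` objects, one per location
#' @export
read_plot_data <- function(path, yield_unit = c("kg/ha", "t/ha")) {
  yield_unit <- match.arg(yield_unit)
  df <- read_csv_strict(path, c("location", "genotype", "replicate",
                                "row", "column", "yield"))
  df$replicate <- num_or_stop(df$replicate, "replicate", path)
  df$row <- num_or_stop(df$row, "row", path)
  df$column <- num_or_stop(df$column, "column", path)
  df$yield <- num_or_stop(df$yield, "yield", path)
  if (any(df$replicate < 1 | df$row < 1 | df$column < 1, na.rm = TRUE))
    stop("replicate/row/column indices must be positive in ", path)
  miss <- is.na(df$yield)
  if (any(miss)) {
    message("dropping ", sum(miss), " plot(s) with missing yield")
    df <- df[!miss, , drop = FALSE]
  }
  out <- lapply(split(df, df$location), function(d) {
    trial_dataset(location = d$location[1], genotype = d$genotype,
                  replicate = d$replicate, row = d$row, column = d$column,
                  yield = d$yield, yield_unit = yield_unit)
  })
  out[canonical_ids(names(out))]
}

#' One location's row-column trial
#'
#' @param location location identifier
#' @param genotype,replicate,row,column,yield parallel plot-level vectors
#' @param yield_unit unit of `yield`
#' @return object of class `trial_dataset`
#' @export
trial_dataset <- function(location, genotype, replicate, row, column, yield,
                          yield_unit = "kg/ha") {
  n <- length(yield)
  stopifnot(length(genotype) == n, length(replicate) == n,
            length(row) == n, length(column) == n)
  cell <- paste(replicate, row, column, sep = ":")
  dup <- cell[duplicated(cell)]
  if (length(dup))
    stop("duplicate (replicate,row,column) cell(s) at location '", location,
         "': ", paste(unique(dup), collapse = ", "))
  structure(list(location = as.character(location),
                 genotype = as.character(genotype),
                 replicate = as.integer(replicate),
                 row = as.integer(row), column = as.integer(column),
                 yield = as.numeric(yield), yield_unit = yield_unit,
                 layout = c(rows = max(row), cols = max(column),
                            reps = length(unique(replicate)))),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset>", x$location, "-", length(x$yield), "plots,",
      length(unique(x$genotype)), "genotypes,", x$layout["reps"], "reps of",
      x$layout["rows"], "x", x$layout["cols"], "(", x$yield_unit, ")\n")
  invisible(x)
}

#' Read pedigree records
#'
#' Columns `genotype,parent1,parent2`; empty, `NA` or `0` mark an unknown
#' parent. Parents that never appear as a genotype are appended as founders.
#' Cycles are an error.
#'
#' @param path CSV file path
#' @return a `pedigree_table` (data frame with class attribute), topologically
#'   sorted so parents precede offspring
#' @export
read_pedigree <- function(path) {
  df <- read_csv_strict(path, c("genotype", "parent1", "parent2"))
  pedigree_table(df$genotype, df$parent1, df$parent2)
}

#' Build and validate a pedigree table
#'
#' @param genotype,parent1,parent2 character vectors; unknown parents as `NA`,
#'   `""` or `"0"`
#' @return topologically sorted `pedigree_table`
#' @export
pedigree_table <- function(genotype, parent1, parent2) {
  norm <- function(p) {
    p <- as.character(p)
    p[is.na(p) | trimws(p) == "" | trimws(p) == "0" |
        toupper(trimws(p)) == "NA"] <- NA_character_
    p
  }
  genotype <- as.character(genotype)
  if (anyDuplicated(genotype))
    stop("duplicate genotype entries in pedigree: ",
         paste(unique(genotype[duplicated(genotype)]), collapse = ", "))
  p1 <- norm(parent1); p2 <- norm(parent2)
  parents <- setdiff(stats::na.omit(unique(c(p1, p2))), genotype)
  if (length(parents)) {            # complete: unseen parents become founders
    genotype <- c(parents, genotype)
    p1 <- c(rep(NA_character_, length(parents)), p1)
    p2 <- c(rep(NA_character_, length(parents)), p2)
  }
  df <- data.frame(genotype = genotype, parent1 = p1, parent2 = p2,
                   stringsAsFactors = FALSE)
  df <- sort_pedigree(df)
  class(df) <- c("pedigree_table", "data.frame")
  df
}

#' Topologically sort a pedigree so parents precede offspring
#'
#' @param ped data frame with columns genotype, parent1, parent2
#' @return the same rows reordered; error (listing the cycle members) if the
#'   pedigree is cyclic
#' @export
sort_pedigree <- function(ped) {
  n <- nrow(ped)
  placed <- logical(n)
  names(placed) <- ped$genotype
  order_idx <- integer(0)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      p1 <- ped$parent1[i]; p2 <- ped$parent2[i]
      (is.na(p1) || isTRUE(placed[[p1]])) && (is.na(p2) || isTRUE(placed[[p2]]))
    }, logical(1))]
    if (!length(ready)) {
      if (!length(remaining)) break
      stop("pedigree contains a cycle involving: ",
           paste(ped$genotype[remaining], collapse = ", "))
    }
    order_idx <- c(order_idx, ready)
    placed[ped$genotype[ready]] <- TRUE
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  out <- ped[order_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an environmental-covariate table
#'
#' First column `location`, remaining columns one numeric covariate each.
#' Missing cells are an error (no imputation); constant-valued covariates are
#' dropped with a warning since they cannot be standardized.
#'
#' @param path CSV file path
#' @return an `ec_table`: list with `locations` and numeric matrix `values`
#'   (locations x covariates)
#' @export
read_ec_table <- function(path) {
  df <- read_csv_strict(path, "location")
  covs <- setdiff(names(df), "location")
  if (!length(covs)) stop("EC table ", path, " has no covariate columns")
  vals <- sapply(covs, function(cn) num_or_stop(df[[cn]], cn, path))
  vals <- matrix(as.numeric(vals), nrow = nrow(df),
                 dimnames = list(NULL, covs))
  if (anyNA(vals)) {
    bad <- covs[colSums(is.na(vals)) > 0]
    stop("EC table ", path, " has missing cells in: ",
         paste(bad, collapse = ", "))
  }
  ec_table(df$location, vals)
}

#' Construct an EC table
#'
#' @param locations location identifiers (rows)
#' @param values numeric matrix, locations x covariates, with column names
#' @return object of class `ec_table`
#' @export
ec_table <- function(locations, values) {
  locations <- as.character(locations)
  stopifnot(is.matrix(values), nrow(values) == length(locations),
            !is.null(colnames(values)))
  if (anyDuplicated(locations)) stop("duplicate locations in EC table")
  const <- apply(values, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning("dropping constant EC column(s): ",
            paste(colnames(values)[const], collapse = ", "))
    values <- values[, !const, drop = FALSE]
  }
  if (!ncol(values)) stop("no non-constant EC columns left")
  ord <- order(locations, method = "radix")
  structure(list(locations = locations[ord],
                 values = values[ord, , drop = FALSE]),
            class = "ec_table")
}

#' @export
print.ec_table <- function(x, ...) {
  cat("<ec_table>", length(x$locations), "locations x", ncol(x$values),
      "covariates\n")
  invisible(x)
}

#' Read per-location adjusted means for Stage II
#'
#' Columns `location,genotype,mean_t_ha` and optionally `weight`; absent
#' weights default to 1 with a warning.
#'
#' @param path CSV file path
#' @return list of [mean_set()] objects
#' @export
read_means <- function(path) {
  df <- read_csv_strict(path, c("location", "genotype", "mean_t_ha"))
  df$mean_t_ha <- num_or_stop(df$mean_t_ha, "mean_t_ha", path)
  if ("weight" %in% names(df)) {
    df$weight <- num_or_stop(df$weight, "weight", path)
  } else {
    warning("no 'weight' column in ", path, "; using unit weights")
    df$weight <- 1
  }
  out <- lapply(split(df, df$location), function(d)
    mean_set(d$location[1], d$genotype, d$mean_t_ha, d$weight))
  out[canonical_ids(names(out))]
}

#' Write adjusted means with weights
#'
#' @param sets list of [mean_set()] objects
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_means <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(location = s$location, genotype = s$genotypes,
               mean_t_ha = s$means, weight = s$weights,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an EC table
#'
#' @param ec an `ec_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ec_table <- function(ec, path) {
  df <- data.frame(location = ec$locations, ec$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cross-validation report as JSON
#'
#' @param cv a `cv_result` (or list of them)
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_cv_report <- function(cv, path) {
  as_rep <- function(r) list(
    model = r$model_id,
    n_sc = r$n_sc,
    prediction_mode = r$prediction_mode,
    msepd_t2ha2 = r$msepd,
    mean_spearman = r$mean_rho,
    se_spearman = r$se_rho,
    per_location = r$per_location,
    non_converged_folds = r$failed_folds)
  rep <- if (inherits(cv, "cv_result")) as_rep(cv) else lapply(cv, as_rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
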
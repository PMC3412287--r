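#' Declare an individuals-by-variables table with missing entries
#'
#' Tags a rectangular table with the variable roles used throughout the
#' package: the analysis outcome, the analysis covariates, auxiliary
#' variables (used only to impute), and the fully observed predictors of
#' the missingness (weighting) model. Roles may overlap. Missing entries
#' are represented by `NA` — an explicit mask, never a numeric sentinel.
#'
#' @param data A data frame. All role variables must be numeric; categorical
#'   variables are expected to arrive already expanded to 0/1 codes.
#' @param outcome Name of the analysis-model outcome variable.
#' @param covariates Character vector of analysis-model covariate names.
#' @param auxiliary Character vector of auxiliary variable names (may be
#'   empty). Auxiliaries can appear in imputation models but not in the
#'   analysis model.
#' @param weight_predictors Character vector of variables available to
#'   missingness (weighting) models. These must be fully observed: weights
#'   are defined through a model for inclusion given observed data.
#' @param id Optional name of an identifier column, carried through
#'   unchanged. Row order is the identity key; an id column is never
#'   required.
#'
#' @return A tibble of class `incomplete_df` carrying the role metadata.
#' @examples
#' d <- tibble::tibble(Y = c(1, NA, 3), X1 = c(0, 1, 1), X2 = c(0.2, NA, 1))
#' inc <- incomplete_data(d, outcome = "Y", covariates = "X2",
#'                        weight_predictors = "X1")
#' missing_pattern(inc)
#' @export
incomplete_data <- function(data, outcome, covariates,
                            auxiliary = character(),
                            weight_predictors = character(),
                            id = NULL) {
  data <- tibble::as_tibble(data)
  roles <- list(
    outcome = outcome, covariates = covariates,
    auxiliary = auxiliary, weight_predictors = weight_predictors
  )
  vars <- unique(unlist(roles))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("Role variables not found in `data`: ",
                 paste(missing_vars, collapse = ", ")))
  }
  for (v in vars) {
    if (!is.numeric(data[[v]])) {
      abort(paste0("Variable `", v, "` must be numeric (0/1-code categoricals first)."))
    }
  }
  for (v in weight_predictors) {
    if (anyNA(data[[v]])) {
      abort(paste0("Weight predictor `", v, "` contains missing values; ",
                   "missingness-model predictors must be fully observed."))
    }
  }
  if (!is.null(id) && !id %in% names(data)) {
    abort(paste0("Id column `", id, "` not found in `data`."))
  }
  structure(data,
    class = c("incomplete_df", class(tibble::tibble())),
    roles = roles, id_col = id
  )
}

#' Roles attached to an `incomplete_df`
#' @param data An `incomplete_df`.
#' @return Named list with elements `outcome`, `covariates`, `auxiliary`,
#'   `weight_predictors`.
#' @export
variable_roles <- function(data) {
  r <- attr(data, "roles")
  if (is.null(r)) abort("`data` carries no role metadata; see `incomplete_data()`.")
  r
}

#' Missingness pattern matrix
#'
#' Per-individual logical missingness indicators over the role variables:
#' `TRUE` where a value is missing. The pattern is a function of the mask
#' only, never of the values.
#'
#' @param data An `incomplete_df` (or any data frame; then all columns are
#'   used).
#' @return A logical matrix, individuals in rows.
#' @export
missing_pattern <- function(data) {
  vars <- if (inherits(data, "incomplete_df")) {
    unique(unlist(variable_roles(data)))
  } else {
    names(data)
  }
  m <- vapply(vars, function(v) is.na(data[[v]]), logical(nrow(data)))
  m <- matrix(m, nrow = nrow(data), dimnames = list(NULL, vars))
  m
}

#' Read an incomplete dataset from CSV
#'
#' Reads an RFC-4180-style CSV with a header row, converts the declared
#' missing-value code to `NA`, and attaches variable roles. A non-numeric,
#' non-missing cell in a role column is a parse error naming the offending
#' row and column; a missing value in a weight-predictor column is a
#' role-violation error.
#'
#' @param path Path to a CSV file.
#' @param outcome,covariates,auxiliary,weight_predictors,id Roles, as in
#'   [incomplete_data()].
#' @param missing_code Token marking a missing entry (default `"NA"`; the
#'   empty cell is always treated as missing).
#' @return An `incomplete_df`.
#' @export
read_incomplete_csv <- function(path, outcome, covariates,
                                auxiliary = character(),
                                weight_predictors = character(),
                                id = NULL, missing_code = "NA") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  role_vars <- unique(c(outcome, covariates, auxiliary, weight_predictors))
  out <- tibble::as_tibble(raw)
  for (v in intersect(names(out), role_vars)) {
    cell <- out[[v]]
    is_mis <- cell == missing_code | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_mis & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0("Cannot parse cell at row ", i, ", column `", v,
                   "`: \"", cell[i], "\" is neither numeric nor the missing code."))
    }
    num[is_mis] <- NA_real_
    out[[v]] <- num
  }
  incomplete_data(out, outcome = outcome, covariates = covariates,
                  auxiliary = auxiliary, weight_predictors = weight_predictors,
                  id = id)
}

#' Write an incomplete dataset to CSV
#'
#' Inverse of [read_incomplete_csv()]: `NA` cells are written as
#' `missing_code`. A write/read round trip reproduces values, masks and
#' roles exactly.
#'
#' @param data An `incomplete_df`.
#' @param path Output path.
#' @param missing_code Token to write for missing entries.
#' @return `path`, invisibly.
#' @export
write_incomplete_csv <- function(data, path, missing_code = "NA") {
  df <- as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, na = missing_code)
  invisible(path)
}

#' @export
print.incomplete_df <- function(x, ...) {
  r <- attr(x, "roles")
  cat("<incomplete_df> ", nrow(x), " individuals\n", sep = "")
  cat("  outcome:           ", paste(r$outcome, collapse = ", "), "\n", sep = "")
  cat("  covariates:        ", paste(r$covariates, collapse = ", "), "\n", sep = "")
  if (length(r$auxiliary))
    cat("  auxiliary:         ", paste(r$auxiliary, collapse = ", "), "\n", sep = "")
  if (length(r$weight_predictors))
    cat("  weight predictors: ", paste(r$weight_predictors, collapse = ", "), "\n", sep = "")
  NextMethod()
}
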
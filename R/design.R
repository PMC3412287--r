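#' Analysis-model specification
#'
#' A lightweight model specification: an outcome name plus a term list.
#' Terms are variable names or colon-separated products (`"X2:X3"` means
#' the rowwise product of `X2` and `X3`). Duplicate terms are rejected.
#'
#' @param outcome Outcome variable name.
#' @param terms Character vector of terms (main effects and products).
#' @param intercept Include an intercept column? Default `TRUE`.
#' @return An object of class `ipwmi_model_spec`.
#' @examples
#' model_spec("Y", c("X2", "X3", "X2:X3"))
#' @export
model_spec <- function(outcome, terms, intercept = TRUE) {
  stopifnot(is.character(outcome), length(outcome) == 1L)
  terms <- as.character(terms)
  if (anyDuplicated(terms)) {
    abort(paste0("Duplicate terms in model specification: ",
                 paste(unique(terms[duplicated(terms)]), collapse = ", ")))
  }
  structure(list(outcome = outcome, terms = terms, intercept = isTRUE(intercept)),
            class = "ipwmi_model_spec")
}

#' @export
print.ipwmi_model_spec <- function(x, ...) {
  rhs <- c(if (x$intercept) "1", x$terms)
  cat("<model_spec> ", x$outcome, " ~ ", paste(rhs, collapse = " + "), "\n", sep = "")
  invisible(x)
}

term_variables <- function(terms) {
  unique(unlist(strsplit(terms, ":", fixed = TRUE)))
}

## evaluate one term (possibly a product) over the rows of a data frame
eval_term <- function(data, term) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  out <- data[[vars[1]]]
  for (v in vars[-1]) out <- out * data[[v]]
  out
}

#' Build a design matrix and outcome vector
#'
#' Expands a [model_spec()] over the requested rows of a dataset. Columns
#' are ordered intercept first, then terms in specification order; product
#' terms are computed rowwise. Every term variable must be observed on
#' every requested row.
#'
#' @param data A data frame or `incomplete_df`.
#' @param spec A [model_spec()] (or a spec-like list with `terms` and
#'   `intercept`; the outcome is only extracted when present and observed).
#' @param rows Integer row indices to use; default all rows. An empty set
#'   yields a 0-row matrix.
#' @param require_outcome Require the outcome observed on all rows?
#'   Default `TRUE`; with `FALSE`, `y` may contain `NA`.
#' @return A list with elements `x` (numeric matrix) and `y` (numeric
#'   vector, `NULL` if the spec has no outcome).
#' @export
build_design <- function(data, spec, rows = NULL, require_outcome = TRUE) {
  if (is.null(rows)) rows <- seq_len(nrow(data))
  rows <- as.integer(rows)
  vars <- term_variables(spec$terms)
  unknown <- setdiff(c(vars, spec$outcome), names(data))
  if (length(unknown) > 0) {
    abort(paste0("Model specification references unknown variable(s): ",
                 paste(unknown, collapse = ", ")))
  }
  d <- data[rows, , drop = FALSE]
  for (v in vars) {
    if (anyNA(d[[v]])) {
      bad <- rows[is.na(d[[v]])]
      abort(paste0("Variable `", v, "` is missing on requested row(s): ",
                   paste(head(bad, 5L), collapse = ", "),
                   if (length(bad) > 5L) ", ..." else ""))
    }
  }
  cols <- lapply(spec$terms, function(tm) eval_term(d, tm))
  x <- do.call(cbind, c(
    if (spec$intercept) list(`(Intercept)` = rep(1, length(rows))),
    setNames(cols, spec$terms)
  ))
  if (length(rows) == 0L) {
    p <- length(spec$terms) + as.integer(spec$intercept)
    x <- matrix(numeric(0), nrow = 0, ncol = p,
                dimnames = list(NULL, c(if (spec$intercept) "(Intercept)", spec$terms)))
  }
  y <- NULL
  if (!is.null(spec$outcome)) {
    y <- d[[spec$outcome]]
    if (require_outcome && anyNA(y)) {
      bad <- rows[is.na(y)]
      abort(paste0("Outcome `", spec$outcome, "` is missing on requested row(s): ",
                   paste(head(bad, 5L), collapse = ", "),
                   if (length(bad) > 5L) ", ..." else ""))
    }
  }
  list(x = x, y = y)
}
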
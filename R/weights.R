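#' Inclusion rules over missingness patterns
#'
#' An inclusion rule is a deterministic predicate over the per-individual
#' missingness pattern (never over the values) deciding who enters the
#' weighted analysis. `rule_block_complete()` is the default rule: an
#' individual is included iff a designated block of variables is fully
#' observed. `rule_observed()` includes individuals with a single variable
#' observed (the usual stage-2 rule for a missing outcome).
#'
#' @param vars Variables whose joint observedness defines inclusion.
#' @return An object of class `inclusion_rule`.
#' @examples
#' rule_block_complete(c("X2", "X3", "X4", "X5"))
#' @export
rule_block_complete <- function(vars) {
  stopifnot(is.character(vars), length(vars) >= 1L)
  structure(
    list(vars = vars,
         label = paste0("block complete: ", paste(vars, collapse = ", "))),
    class = "inclusion_rule"
  )
}

#' @rdname rule_block_complete
#' @param var Single variable name.
#' @export
rule_observed <- function(var) {
  stopifnot(is.character(var), length(var) == 1L)
  structure(list(vars = var, label = paste0("observed: ", var)),
            class = "inclusion_rule")
}

#' @export
print.inclusion_rule <- function(x, ...) {
  cat("<inclusion_rule> included iff ", x$label, "\n", sep = "")
  invisible(x)
}

#' Evaluate an inclusion rule
#' @param rule An `inclusion_rule`.
#' @param data A data frame with the rule's variables.
#' @return Logical vector, `TRUE` for included individuals.
#' @export
is_included <- function(rule, data) {
  stopifnot(inherits(rule, "inclusion_rule"))
  missing_vars <- setdiff(rule$vars, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("Inclusion rule references unknown variable(s): ",
                 paste(missing_vars, collapse = ", ")))
  }
  stats::complete.cases(data[, rule$vars, drop = FALSE])
}

#' Missingness-model specification
#'
#' Declares the model for the probability of inclusion given fully
#' observed predictors. Two links are supported: `"saturated"` fits one
#' inclusion probability per cross-classified stratum of discrete
#' predictors (the maximum-likelihood fit for any identity- or logit-link
#' model saturated in those predictors), and `"logistic"` fits a logistic
#' regression on the predictor terms (products allowed, `"X2:X4"`).
#'
#' @param predictors Character vector of predictor terms. The underlying
#'   variables must be observed wherever the model is fitted.
#' @param link `"saturated"` or `"logistic"`.
#' @return An object of class `weight_model_spec`.
#' @export
weight_model_spec <- function(predictors, link = c("saturated", "logistic")) {
  link <- match.arg(link)
  structure(list(predictors = as.character(predictors), link = link),
            class = "weight_model_spec")
}

new_weight_set <- function(tbl, link, alpha, known_weights, floor,
                           score_info = NULL) {
  structure(tbl,
    class = c("weight_set", class(tibble::tibble())),
    link = link, alpha = alpha, known_weights = known_weights,
    floor = floor, score_info = score_info
  )
}

check_floor <- function(pi_inc, floor, truncate, where) {
  if (any(pi_inc < floor)) {
    if (truncate) return(pmax(pi_inc, floor))
    abort(paste0("Fitted inclusion probabilities below the positivity floor ",
                 format(floor), " in ", where, "; weights would be unbounded. ",
                 "Set `truncate = TRUE` only if you accept the changed estimand."))
  }
  pi_inc
}

#' Fit the missingness model and derive inverse-probability weights
#'
#' Fits the inclusion indicator defined by `rule` on the model's
#' predictors by maximum likelihood over *all* individuals in `rows`
#' (included and excluded), and returns weights `W = 1/pi_hat` for the
#' included individuals. Excluded individuals keep `pi_hat` but have
#' weight `NA`.
#'
#' @param data A data frame or `incomplete_df`.
#' @param rule An [rule_block_complete()]-style inclusion rule.
#' @param spec A [weight_model_spec()].
#' @param rows Rows over which the model is fitted (default: all). Used
#'   for stage-2 models that are only defined among individuals retained
#'   at stage 1.
#' @param floor Positivity floor for fitted probabilities (default 1e-6).
#'   Probabilities below it raise an error unless `truncate = TRUE`.
#' @param truncate Truncate at the floor instead of erroring? Default
#'   `FALSE`: truncation silently changes the estimand.
#' @return A `weight_set` tibble with columns `.row`, `included`,
#'   `pi_hat`, `weight`, with the fitted parameters in attributes and
#'   `known_weights = FALSE`.
#' @examples
#' d <- tibble::tibble(Z = rep(c(0, 1), each = 5),
#'                     X = c(1, 2, 3, 4, NA, 1, NA, NA, NA, 2))
#' fit_missingness_model(d, rule_block_complete("X"),
#'                       weight_model_spec("Z", "saturated"))
#' @export
fit_missingness_model <- function(data, rule, spec, rows = NULL,
                                  floor = 1e-6, truncate = FALSE) {
  stopifnot(inherits(spec, "weight_model_spec"))
  if (is.null(rows)) rows <- seq_len(nrow(data))
  rows <- as.integer(rows)
  d <- data[rows, , drop = FALSE]
  g <- as.numeric(is_included(rule, d))
  if (all(g == 1) || all(g == 0)) {
    if (all(g == 0)) abort("No included individuals; cannot fit a missingness model.")
    ## degenerate but valid: everyone included, all weights 1
    tbl <- tibble::tibble(.row = rows, included = TRUE, pi_hat = 1, weight = 1)
    return(new_weight_set(tbl, spec$link, alpha = NULL, known_weights = FALSE,
                          floor = floor,
                          score_info = list(type = "degenerate", rows = rows, g = g)))
  }
  pvars <- term_variables(spec$predictors)
  for (v in pvars) {
    if (!v %in% names(d)) abort(paste0("Weight-model predictor `", v, "` not found."))
    if (anyNA(d[[v]])) {
      abort(paste0("Weight-model predictor `", v, "` is missing on fitted rows; ",
                   "missingness-model predictors must be fully observed."))
    }
  }

  if (spec$link == "saturated") {
    strata <- interaction(d[, pvars, drop = FALSE], drop = TRUE, lex.order = TRUE)
    n_k <- tapply(g, strata, length)
    pi_k <- tapply(g, strata, mean)
    if (any(pi_k == 0)) {
      abort(paste0("Stratum with zero included individuals (",
                   paste(names(pi_k)[pi_k == 0], collapse = ", "),
                   "); positivity fails for the saturated link."))
    }
    pi_hat <- as.numeric(pi_k[as.character(strata)])
    alpha <- as.numeric(pi_k)
    names(alpha) <- names(pi_k)
    score_info <- list(type = "saturated", stratum = as.integer(strata),
                       n_strata = nlevels(strata), rows = rows, g = g)
  } else {
    des <- build_design(d, list(outcome = NULL, terms = spec$predictors,
                                intercept = TRUE), require_outcome = FALSE)
    fit <- suppressWarnings(
      stats::glm.fit(des$x, g, family = stats::binomial())
    )
    eta <- drop(des$x %*% fit$coefficients)
    if (!fit$converged || any(abs(eta) > 30)) {
      abort(paste0("Logistic missingness model failed to converge (possible ",
                   "separation); max |linear predictor| = ",
                   format(max(abs(eta)), digits = 3), "."))
    }
    pi_hat <- plogis(eta)
    alpha <- fit$coefficients
    score_info <- list(type = "logistic", z = des$x, rows = rows, g = g)
  }

  inc <- g == 1
  pi_hat[inc] <- check_floor(pi_hat[inc], floor, truncate, "fit_missingness_model")
  tbl <- tibble::tibble(
    .row = rows, included = inc, pi_hat = pi_hat,
    weight = ifelse(inc, 1 / pi_hat, NA_real_)
  )
  new_weight_set(tbl, spec$link, alpha, known_weights = FALSE, floor = floor,
                 score_info = score_info)
}

#' Supply known inverse-probability weights
#'
#' For analyses where the inclusion probabilities are known (true design
#' weights, or the generator's true probabilities in simulation),
#' bypasses model fitting. `pi_hat = 1/weight` is stored and
#' `known_weights = TRUE`, which marks the weight-estimation sandwich
#' adjustment as inapplicable.
#'
#' @param data A data frame.
#' @param rule Inclusion rule.
#' @param weights Positive finite weights: either one per included
#'   individual (in row order) or one per row of `data`.
#' @return A `weight_set` with `known_weights = TRUE`.
#' @export
set_known_weights <- function(data, rule, weights) {
  g <- is_included(rule, data)
  n <- nrow(data)
  if (length(weights) == n) {
    w_inc <- weights[g]
  } else if (length(weights) == sum(g)) {
    w_inc <- weights
  } else {
    abort(paste0("`weights` must have length ", n, " (all rows) or ", sum(g),
                 " (included rows); got ", length(weights), "."))
  }
  if (anyNA(w_inc) || any(!is.finite(w_inc)) || any(w_inc <= 0)) {
    abort("All weights for included individuals must be positive and finite.")
  }
  w <- rep(NA_real_, n)
  w[g] <- w_inc
  tbl <- tibble::tibble(.row = seq_len(n), included = g,
                        pi_hat = ifelse(g, 1 / w, NA_real_), weight = w)
  new_weight_set(tbl, link = "known", alpha = NULL, known_weights = TRUE,
                 floor = 0)
}

#' Compose two-stage weights
#'
#' For two-stage exclusion the probability of being retained is the
#' product of the per-stage probabilities; the composed weight is the
#' reciprocal of that product. The stage-2 inclusion set must be a subset
#' of the stage-1 inclusion set.
#'
#' @param stage1,stage2 `weight_set` objects. `stage2` is typically fitted
#'   over the stage-1 included rows only.
#' @return A `weight_set` over the rows of `stage1`, included where both
#'   stages include.
#' @export
product_weights <- function(stage1, stage2) {
  stopifnot(inherits(stage1, "weight_set"), inherits(stage2, "weight_set"))
  rows1 <- stage1$.row
  rows2 <- stage2$.row
  inc2_rows <- rows2[stage2$included]
  if (!all(rows2 %in% rows1[stage1$included])) {
    abort("Stage-2 weight set must be fitted within the stage-1 included set.")
  }
  pi <- stage1$pi_hat
  inc <- rep(FALSE, length(rows1))
  idx2 <- match(rows2, rows1)
  pi[idx2] <- pi[idx2] * stage2$pi_hat
  inc[match(inc2_rows, rows1)] <- TRUE
  tbl <- tibble::tibble(
    .row = rows1, included = inc, pi_hat = pi,
    weight = ifelse(inc, 1 / pi, NA_real_)
  )
  new_weight_set(tbl, link = paste0(attr(stage1, "link"), "*", attr(stage2, "link")),
                 alpha = list(stage1 = attr(stage1, "alpha"),
                              stage2 = attr(stage2, "alpha")),
                 known_weights = attr(stage1, "known_weights") &&
                   attr(stage2, "known_weights"),
                 floor = max(attr(stage1, "floor"), attr(stage2, "floor")))
}

## weights aligned to arbitrary data rows (NA where excluded / absent)
weight_for_rows <- function(wset, rows) {
  wset$weight[match(rows, wset$.row)]
}

included_rows <- function(wset) wset$.row[wset$included]
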
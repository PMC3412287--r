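#' Imputation-model specifications
#'
#' `regression_imputer()` declares a normal linear-regression imputation
#' model for a single variable; predictors may include auxiliary
#' variables, the weight column `W`, and products. `mvn_imputer()`
#' declares a joint multivariate-normal model for a block of variables
#' that is missing all-or-nothing per individual, with optional follow-on
#' conditional regressions (each a `regression_imputer`) imputed from the
#' drawn block values.
#'
#' @param outcome Variable to impute.
#' @param terms Predictor terms (names and `:`-products; `"W"` denotes the
#'   inverse-probability weight, materialised at imputation time).
#' @param intercept Include an intercept? Default `TRUE`.
#' @return A `regression_imputer` / `mvn_imputer` object.
#' @examples
#' regression_imputer("Y", c("X1", "X2", "X3", "X2:X3"))
#' mvn_imputer(c("X2", "X3", "X4"),
#'             conditionals = list(regression_imputer("X5", c("X2", "X3", "X2:X3"))))
#' @export
regression_imputer <- function(outcome, terms, intercept = TRUE) {
  spec <- model_spec(outcome, terms, intercept)
  structure(list(outcome = spec$outcome, terms = spec$terms,
                 intercept = spec$intercept, weight_terms = FALSE),
            class = c("regression_imputer", "ipwmi_model_spec"))
}

#' @rdname regression_imputer
#' @param block Character vector of jointly normal block variables.
#' @param conditionals List of `regression_imputer` specs for variables
#'   imputed conditionally on the block (e.g. a variable whose mean is a
#'   product of two block variables).
#' @export
mvn_imputer <- function(block, conditionals = list()) {
  stopifnot(is.character(block), length(block) >= 2L)
  for (cs in conditionals) stopifnot(inherits(cs, "regression_imputer"))
  structure(list(block = block, conditionals = conditionals),
            class = "mvn_imputer")
}

#' Add weight main effect and weight-by-covariate products to an imputer
#'
#' Augments a regression imputation model with the weight `W` (when the
#' model has an intercept) and the pairwise products of `W` with every
#' existing term. Required for the pooled variance to be unbiased when
#' imputing the outcome of a weighted linear analysis: without these terms
#' the imputer assumes the outcome model is identical across weight
#' strata, an assumption the weighted analyst does not make. Idempotent.
#'
#' @param spec A [regression_imputer()].
#' @param weights Optional `weight_set`, checked to cover all included
#'   rows when supplied.
#' @return The augmented spec with `weight_terms = TRUE`.
#' @examples
#' attach_weight_terms(regression_imputer("Y", c("X2", "X3")))
#' @export
attach_weight_terms <- function(spec, weights = NULL) {
  stopifnot(inherits(spec, "regression_imputer"))
  if (isTRUE(spec$weight_terms)) return(spec)
  if (!is.null(weights) && anyNA(weights$weight[weights$included])) {
    abort("Weights must be available for every included individual.")
  }
  extra <- c(if (spec$intercept) "W", paste0("W:", spec$terms))
  out <- regression_imputer(spec$outcome, c(spec$terms, extra), spec$intercept)
  out$weight_terms <- TRUE
  out
}

new_imputed_stack <- function(imputations, rows, draws, seed) {
  M <- length(imputations)
  structure(list(imputations = imputations, rows = rows, draws = draws,
                 M = M, seed = seed),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("<imputed_stack> M = ", x$M, " completed copies of ",
      length(x$rows), " individuals\n", sep = "")
  invisible(x)
}

## posterior draw for a normal linear regression under the improper
## prior p(beta, sigma_eps) ~ 1/sigma_eps^2:
##   sigma2* = RSS / chisq_{n-p},  beta* ~ N(beta_hat, sigma2* (X'X)^-1)
draw_regression_posterior <- function(x, y, label = "imputation model") {
  n <- nrow(x); p <- ncol(x)
  if (n <= p) {
    abort(paste0("Too few observed rows to fit the ", label, ": n = ", n,
                 " with p = ", p, " predictors."))
  }
  qr_x <- qr(x)
  if (qr_x$rank < p) {
    dep <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):p]]
    abort(paste0("Collinear design in the ", label, "; dependent column(s): ",
                 paste(dep, collapse = ", ")))
  }
  beta_hat <- qr.coef(qr_x, y)
  res <- y - drop(x %*% beta_hat)
  rss <- sum(res^2)
  xtx_inv <- chol2inv(qr.R(qr_x))
  sigma2 <- rss / rchisq(1L, df = n - p)
  L <- chol(xtx_inv)
  beta <- beta_hat + sqrt(sigma2) * drop(t(L) %*% rnorm(p))
  list(beta = beta, sigma2 = sigma2, beta_hat = beta_hat, rss = rss, df = n - p)
}

## materialise the weight column W onto a data frame when the spec uses it
with_weight_column <- function(d, spec, weights, rows) {
  uses_w <- "W" %in% term_variables(spec$terms)
  if (!uses_w) return(d)
  if (is.null(weights)) abort("Imputer references `W` but no weights were supplied.")
  d$W <- weight_for_rows(weights, rows)
  if (anyNA(d$W)) abort("Imputer references `W` but weights are unavailable for some rows.")
  d
}

#' Proper regression imputation of a missing outcome
#'
#' Multiply imputes a variable by Bayesian normal linear regression: the
#' model is fitted by unweighted least squares to the included rows with
#' the variable observed; per imputation, the error variance is drawn as
#' `RSS/chisq(n-p)`, coefficients from their normal posterior given that
#' draw, and missing values as the drawn linear predictor plus drawn
#' noise. Observed cells are never touched. Weights never act as fitting
#' weights — they enter only as covariates (see [attach_weight_terms()]).
#'
#' @param data A data frame or `incomplete_df`.
#' @param weights A `weight_set`, or `NULL` to use all rows of `data`.
#' @param spec A [regression_imputer()].
#' @param M Number of imputations (>= 1; pooling requires >= 2).
#' @param seed Optional integer seed for reproducible draws.
#' @return An `imputed_stack`: `M` completed tibbles of the included
#'   rows plus the parameter draws that produced them.
#' @export
impute_regression <- function(data, weights, spec, M, seed = NULL) {
  stopifnot(inherits(spec, "regression_imputer"), M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rows <- if (is.null(weights)) seq_len(nrow(data)) else included_rows(weights)
  d <- tibble::as_tibble(data)[rows, , drop = FALSE]
  d <- with_weight_column(d, spec, weights, rows)
  pvars <- term_variables(spec$terms)
  for (v in pvars) {
    if (anyNA(d[[v]])) {
      abort(paste0("Imputer predictor `", v, "` is missing on included rows; ",
                   "impute it first or exclude those rows."))
    }
  }
  y_all <- d[[spec$outcome]]
  mis <- is.na(y_all)
  if (!any(mis)) {
    return(new_imputed_stack(rep(list(d), M), rows,
                             draws = tibble::tibble(m = integer(), sigma2 = numeric()),
                             seed = seed))
  }
  obs <- !mis
  des <- build_design(d, list(outcome = NULL, terms = spec$terms,
                              intercept = spec$intercept),
                      rows = which(obs), require_outcome = FALSE)
  des_mis <- build_design(d, list(outcome = NULL, terms = spec$terms,
                                  intercept = spec$intercept),
                          rows = which(mis), require_outcome = FALSE)
  imputations <- vector("list", M)
  draws <- vector("list", M)
  for (m in seq_len(M)) {
    dr <- draw_regression_posterior(des$x, y_all[obs], label = "regression imputer")
    y_new <- y_all
    y_new[mis] <- drop(des_mis$x %*% dr$beta) + sqrt(dr$sigma2) * rnorm(sum(mis))
    dm <- d
    dm[[spec$outcome]] <- y_new
    imputations[[m]] <- dm
    draws[[m]] <- tibble::tibble(m = m, sigma2 = dr$sigma2,
                                 beta = list(dr$beta))
  }
  new_imputed_stack(imputations, rows, dplyr::bind_rows(draws), seed)
}

## one inverse-Wishart draw, IW(df, scale S): Sigma = (Wishart(df, S^-1))^-1
draw_inv_wishart <- function(df, S, retries = 10L) {
  S_inv <- chol2inv(chol(S))
  for (r in seq_len(retries)) {
    W <- stats::rWishart(1L, df, S_inv)[, , 1L]
    Sig <- try(chol2inv(chol(W)), silent = TRUE)
    if (!inherits(Sig, "try-error")) return(Sig)
  }
  abort("Posterior covariance draw failed to be positive definite after retries.")
}

#' Proper multivariate-normal imputation of a missing block
#'
#' Multiply imputes a block of variables that is missing all-or-nothing
#' per individual, assuming the block is jointly normal. The posterior
#' under the standard noninformative (Jeffreys-limit) normal–inverse-
#' Wishart prior is conjugate: `Sigma | data ~ InvWishart(n - 1, S)` with
#' `S` the centred scatter of the block-complete rows, and
#' `mu | Sigma ~ N(xbar, Sigma/n)`. Per imputation the whole missing
#' block is drawn jointly from the drawn normal, then any follow-on
#' conditional regressions are imputed by the [impute_regression()]
#' mechanics using the drawn block values.
#'
#' @inheritParams impute_regression
#' @param spec An [mvn_imputer()].
#' @return An `imputed_stack` over the included rows.
#' @export
impute_mvn_block <- function(data, weights, spec, M, seed = NULL) {
  stopifnot(inherits(spec, "mvn_imputer"), M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rows <- if (is.null(weights)) seq_len(nrow(data)) else included_rows(weights)
  d <- tibble::as_tibble(data)[rows, , drop = FALSE]
  blk <- as.matrix(d[, spec$block, drop = FALSE])
  n_mis_var <- rowSums(is.na(blk))
  if (any(n_mis_var > 0 & n_mis_var < ncol(blk))) {
    abort("Block variables must be all observed or all missing per individual.")
  }
  mis <- n_mis_var == ncol(blk)
  cond_targets <- vapply(spec$conditionals, function(cs) cs$outcome, character(1))

  if (!any(mis)) {
    cond_missing <- any(vapply(cond_targets, function(v) anyNA(d[[v]]), logical(1)))
    if (!cond_missing) {
      return(new_imputed_stack(rep(list(d), M), rows,
                               draws = tibble::tibble(m = integer()), seed = seed))
    }
  }
  obs_idx <- which(!mis)
  dcomp <- blk[obs_idx, , drop = FALSE]
  n <- nrow(dcomp); p <- ncol(dcomp)
  total_p <- p + sum(vapply(spec$conditionals,
                            function(cs) length(cs$terms) + cs$intercept, numeric(1)))
  if (n <= total_p) {
    abort(paste0("Too few block-complete rows (", n, ") for the joint model (",
                 total_p, " parameters)."))
  }
  xbar <- colMeans(dcomp)
  S <- crossprod(sweep(dcomp, 2L, xbar))

  imputations <- vector("list", M)
  draws <- vector("list", M)
  n_mis <- sum(mis)
  for (m in seq_len(M)) {
    Sig <- draw_inv_wishart(n - 1L, S)
    mu <- xbar + drop(t(chol(Sig / n)) %*% rnorm(p))
    dm <- d
    if (n_mis > 0) {
      Z <- matrix(rnorm(n_mis * p), n_mis, p) %*% chol(Sig)
      imp <- sweep(Z, 2L, mu, "+")
      for (j in seq_len(p)) dm[[spec$block[j]]][mis] <- imp[, j]
    }
    ## follow-on conditional regressions, fitted on block-complete rows,
    ## imputed where the target is missing using drawn/imputed block values
    for (cs in spec$conditionals) {
      yv <- d[[cs$outcome]]
      fit_rows <- which(!mis & !is.na(yv))
      des <- build_design(d, list(outcome = NULL, terms = cs$terms,
                                  intercept = cs$intercept),
                          rows = fit_rows, require_outcome = FALSE)
      dr <- draw_regression_posterior(des$x, yv[fit_rows],
                                      label = paste0("conditional imputer for ", cs$outcome))
      tgt <- which(is.na(yv))
      if (length(tgt) > 0) {
        des_t <- build_design(dm, list(outcome = NULL, terms = cs$terms,
                                       intercept = cs$intercept),
                              rows = tgt, require_outcome = FALSE)
        dm[[cs$outcome]][tgt] <- drop(des_t$x %*% dr$beta) +
          sqrt(dr$sigma2) * rnorm(length(tgt))
      }
    }
    imputations[[m]] <- dm
    draws[[m]] <- tibble::tibble(m = m, mu = list(mu), Sigma = list(Sig))
  }
  new_imputed_stack(imputations, rows, dplyr::bind_rows(draws), seed)
}
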
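SUPPORTED_PAIRS <- c("CC/CC", "CC/IPW", "CC/MI", "IPW/CC", "IPW/IPW",
                     "IPW/MI", "MI/MI")

#' Specify a two-stage missing-data strategy
#'
#' A strategy pairs a choice for stage 1 (missingness in the covariate
#' block) with a choice for stage 2 (missingness in the outcome): `CC`
#' excludes without weighting, `IPW` excludes and weights by the inverse
#' modeled inclusion probability, `MI` imputes. The supported pairs are
#' CC/CC, CC/IPW, CC/MI, IPW/CC, IPW/IPW, IPW/MI and MI/MI; MI/CC and
#' MI/IPW (impute a large block, then throw imputed individuals away) are
#' rejected. Misspecified-imputation variants are expressed by passing
#' alternative imputer specs.
#'
#' @param stage1,stage2 One of `"CC"`, `"IPW"`, `"MI"`.
#' @param imputer1 An [mvn_imputer()] for the stage-1 block (required when
#'   `stage1 = "MI"`).
#' @param imputer2 A [regression_imputer()] for the outcome (required when
#'   `stage2 = "MI"`).
#' @param weight_model1,weight_model2 [weight_model_spec()]s for the
#'   stage-1 / stage-2 missingness models (required for `IPW` stages).
#' @param M Number of imputations when any stage imputes (default 10).
#' @param label Display label; defaults to `"stage1/stage2"`.
#' @return A `strategy_spec`.
#' @export
strategy_spec <- function(stage1, stage2, imputer1 = NULL, imputer2 = NULL,
                          weight_model1 = NULL, weight_model2 = NULL,
                          M = 10L, label = NULL) {
  stage1 <- match.arg(stage1, c("CC", "IPW", "MI"))
  stage2 <- match.arg(stage2, c("CC", "IPW", "MI"))
  pair <- paste0(stage1, "/", stage2)
  if (!pair %in% SUPPORTED_PAIRS) {
    abort(paste0("Strategy ", pair, " is not supported (imputing a block and ",
                 "then excluding wastes the imputations); supported: ",
                 paste(SUPPORTED_PAIRS, collapse = ", "), "."))
  }
  if (stage1 == "MI" && is.null(imputer1)) abort("stage1 = \"MI\" needs `imputer1`.")
  if (stage2 == "MI" && is.null(imputer2)) abort("stage2 = \"MI\" needs `imputer2`.")
  if (stage1 == "IPW" && is.null(weight_model1)) abort("stage1 = \"IPW\" needs `weight_model1`.")
  if (stage2 == "IPW" && is.null(weight_model2)) abort("stage2 = \"IPW\" needs `weight_model2`.")
  structure(list(stage1 = stage1, stage2 = stage2,
                 imputer1 = imputer1, imputer2 = imputer2,
                 weight_model1 = weight_model1, weight_model2 = weight_model2,
                 M = as.integer(M), label = label %||% pair),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat("<strategy_spec> ", x$label, " (", x$stage1, "/", x$stage2,
      if (x$stage1 == "MI" || x$stage2 == "MI") paste0(", M = ", x$M),
      ")\n", sep = "")
  invisible(x)
}

## deterministic small hash of a label -> RNG substream offset
hash_label <- function(label) {
  v <- utf8ToInt(label)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 1048573
  as.integer(h)
}

fit_family <- function(y, x, w, rows, family) {
  if (family == "linear") wls_fit(y, x, w, rows = rows)
  else weighted_logistic_fit(y, x, w, rows = rows)
}

#' Run a two-stage strategy and return a pooled fit
#'
#' Composes exclusion, weighting and imputation at the two missingness
#' stages and fits the analysis model: stage-1 `CC`/`IPW` drops
#' individuals with an incomplete block (weighting or not), stage-1 `MI`
#' imputes the block in all individuals; stage-2 `CC`/`IPW` drops the
#' remaining individuals with a missing outcome (composing weights via
#' [product_weights()] for `IPW`), stage-2 `MI` imputes the outcome by
#' proper regression imputation. Each completed dataset is fitted with
#' [wls_fit()] (or [weighted_logistic_fit()]) and the fits pooled by
#' Rubin's rules; strategies with no imputation return a single-fit
#' `pooled_fit` with `M = 1` and a zero between component.
#'
#' @param data An `incomplete_df`.
#' @param spec A [strategy_spec()].
#' @param analysis A [model_spec()] for the analysis model.
#' @param block Character vector naming the stage-1 variable block;
#'   must be disjoint from the analysis outcome.
#' @param family `"linear"` (weighted least squares) or `"logistic"`.
#' @param seed Optional integer seed.
#' @return A `pooled_fit`.
#' @export
run_strategy <- function(data, spec, analysis, block,
                         family = c("linear", "logistic"), seed = NULL) {
  stopifnot(inherits(spec, "strategy_spec"), inherits(analysis, "ipwmi_model_spec"))
  family <- match.arg(family)
  if (analysis$outcome %in% block) {
    abort("The stage-1 block and the analysis outcome must be disjoint.")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- tibble::as_tibble(data)
  n <- nrow(d)
  rule1 <- rule_block_complete(block)
  rule2 <- rule_observed(analysis$outcome)

  ## ---- stage 1 -------------------------------------------------------
  if (spec$stage1 %in% c("CC", "IPW")) {
    if (spec$stage1 == "CC") {
      inc1 <- which(is_included(rule1, d))
      w1 <- rep(1, length(inc1))
      wset1 <- NULL
    } else {
      wset1 <- fit_missingness_model(d, rule1, spec$weight_model1)
      inc1 <- included_rows(wset1)
      w1 <- weight_for_rows(wset1, inc1)
    }
    if (length(inc1) == 0L) abort("No individuals left after stage-1 exclusion.")
    base <- d[inc1, , drop = FALSE]

    ## ---- stage 2 on the single stage-1 dataset ----
    if (spec$stage2 %in% c("CC", "IPW")) {
      obs_y <- !is.na(base[[analysis$outcome]])
      keep <- inc1[obs_y]
      if (length(keep) == 0L) abort("No individuals left after stage-2 exclusion.")
      w <- w1[obs_y]
      if (spec$stage2 == "IPW") {
        wset2 <- fit_missingness_model(d, rule2, spec$weight_model2, rows = inc1)
        w <- w * weight_for_rows(wset2, keep)
      }
      des <- build_design(d, analysis, rows = keep)
      return(pooled_single(fit_family(des$y, des$x, w, keep, family)))
    }

    ## stage 2 = MI: proper regression imputation of the outcome
    if (spec$M < 2L) abort("Imputation stages need M >= 2 for pooling.")
    wset_for_imp <- wset1 %||% set_known_weights(d, rule1, rep(1, length(inc1)))
    stack <- impute_regression(d, wset_for_imp, spec$imputer2, M = spec$M)
    fits <- lapply(stack$imputations, function(di) {
      des <- build_design(di, analysis)
      fit_family(des$y, des$x, w1, inc1, family)
    })
    return(pool(fits))
  }

  ## ---- stage 1 = MI (pair is MI/MI) ----------------------------------
  if (spec$M < 2L) abort("Imputation stages need M >= 2 for pooling.")
  stack1 <- impute_mvn_block(d, NULL, spec$imputer1, M = spec$M)
  fits <- lapply(stack1$imputations, function(di) {
    ## outcome imputer: fitted on outcome-observed rows of this completed
    ## copy, missing outcomes drawn conditional on this copy's covariates
    st <- impute_regression(di, NULL, spec$imputer2, M = 1L)
    dii <- st$imputations[[1]]
    des <- build_design(dii, analysis)
    fit_family(des$y, des$x, rep(1, nrow(dii)), seq_len(nrow(dii)), family)
  })
  pool(fits)
}

#' Check a strategy against the conditions for valid weighted imputation
#'
#' Advisory checks, never errors: warns when an IPW stage is combined
#' with an imputation model that contains neither the weight `W` nor all
#' the weight-model predictors (the imputed-data distribution is then
#' estimated giving too much weight to high-inclusion individuals), and
#' warns when a linear-outcome imputer for a weighted analysis lacks the
#' weight-by-covariate product terms needed for an unbiased pooled
#' variance (see [attach_weight_terms()]).
#'
#' @param spec A [strategy_spec()].
#' @param analysis The analysis [model_spec()].
#' @return A tibble of advisory messages (zero rows when clean),
#'   invisibly; each message is also raised as a warning.
#' @export
validate_conditions <- function(spec, analysis) {
  stopifnot(inherits(spec, "strategy_spec"))
  msgs <- character()
  has_ipw <- spec$stage1 == "IPW" || spec$stage2 == "IPW"
  if (has_ipw && spec$stage2 == "MI" && !is.null(spec$imputer2)) {
    vars <- term_variables(spec$imputer2$terms)
    zvars <- if (!is.null(spec$weight_model1)) {
      term_variables(spec$weight_model1$predictors)
    } else character()
    has_w <- "W" %in% vars
    has_all_z <- length(zvars) > 0 && all(zvars %in% vars)
    if (!has_w && !has_all_z) {
      msgs <- c(msgs, paste0(
        "Imputation model for `", spec$imputer2$outcome, "` contains neither the ",
        "weight W nor all weight-model predictors; imputation fitted to the ",
        "included subsample may be biased toward low-weight individuals. ",
        "Include W (or the weight predictors) in the imputer."))
    }
    wx <- paste0("W:", analysis$terms)
    if (!isTRUE(spec$imputer2$weight_terms) && !all(wx %in% spec$imputer2$terms) &&
        !has_all_z) {
      msgs <- c(msgs, paste0(
        "Imputer for the weighted linear analysis lacks the weight-by-covariate ",
        "products (", paste(wx, collapse = ", "), "); the pooled variance may be ",
        "overestimated. See attach_weight_terms()."))
    }
  }
  for (m in msgs) warn(m)
  invisible(tibble::tibble(message = msgs))
}
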
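complete_fixture <- function(n = 200, seed = 41) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rnorm(n); x3 <- rnorm(n); x4 <- rnorm(n)
  x5 <- rnorm(n, x2 * x3)
  y <- -3 + x4 + 0.5 * x5 + x1 * x2 + x1 * x3 + 0.5 * x2 * x3 + rnorm(n)
  incomplete_data(
    tibble::tibble(X1 = as.numeric(x1), X2 = x2, X3 = x3, X4 = x4, X5 = x5,
                   Y = y),
    outcome = "Y", covariates = c("X2", "X3"), auxiliary = c("X4", "X5"),
    weight_predictors = "X1")
}

test_that("unsupported stage pairs are rejected, supported ones accepted", {
  expect_error(strategy_spec("MI", "CC"), "not supported")
  expect_error(strategy_spec("MI", "IPW"), "not supported")
  expect_silent(strategy_spec("CC", "CC"))
  expect_error(strategy_spec("IPW", "CC"), "weight_model1")
  expect_error(strategy_spec("CC", "MI"), "imputer2")
})

test_that("with no missing data every strategy returns the same estimate", {
  d <- complete_fixture()
  analysis <- model_spec("Y", c("X2", "X3", "X2:X3"))
  block <- c("X2", "X3", "X4", "X5")
  thetas <- lapply(study_strategies(M = 4), function(sp) {
    run_strategy(d, sp, analysis, block = block, seed = 5)$theta
  })
  base <- thetas[[1]]
  for (th in thetas) expect_equal(th, base, tolerance = 1e-10)
})

test_that("complete-case equals IPW when inclusion probabilities are constant", {
  ## missingness independent of X1: both weight models fit ~constant
  ## probabilities; CC/CC and IPW/IPW then agree exactly up to weighting
  ## by a constant, which wls is invariant to
  set.seed(43)
  d0 <- complete_fixture(n = 300, seed = 43)
  d <- tibble::as_tibble(d0)
  drop_block <- runif(300) < 0.3
  for (v in c("X2", "X3", "X4", "X5")) d[[v]][drop_block] <- NA
  d$Y[drop_block] <- NA
  dd <- incomplete_data(d, outcome = "Y", covariates = c("X2", "X3"),
                        auxiliary = c("X4", "X5"), weight_predictors = "X1")
  analysis <- model_spec("Y", c("X2", "X3", "X2:X3"))
  block <- c("X2", "X3", "X4", "X5")
  cc <- run_strategy(dd, strategy_spec("CC", "CC"), analysis, block = block)
  ## constant known weights at both stages
  w1 <- set_known_weights(dd, rule_block_complete(block),
                          rep(2, sum(!drop_block)))
  keep <- w1$.row[w1$included]
  ipw_fit <- wls_fit(
    build_design(dd, analysis, rows = keep)$y,
    build_design(dd, analysis, rows = keep)$x,
    w1$weight[w1$included]
  )
  expect_equal(ipw_fit$theta, cc$theta, tolerance = 1e-12)
  expect_equal(ipw_fit$vcov, cc$Wbar, tolerance = 1e-12)
})

test_that("single-fit strategies return an M = 1 pooled fit with zero between", {
  d <- generate_twostage(twostage_config(N = 400), seed = 44)
  pf <- run_strategy(d, strategy_spec("CC", "CC"),
                     model_spec("Y", c("X2", "X3", "X2:X3")),
                     block = c("X2", "X3", "X4", "X5"))
  expect_equal(pf$M, 1L)
  expect_equal(max(abs(pf$B)), 0)
  expect_equal(pf$Sigma, pf$Wbar)
})

test_that("imputing the outcome with the analysis covariates approximates exclusion", {
  ## with constant weights and the imputer using exactly the analysis
  ## covariates, exclusion (IPW/CC-style) and imputation (IPW/MI-style)
  ## agree as M grows
  set.seed(45)
  d0 <- complete_fixture(n = 500, seed = 45)
  d <- tibble::as_tibble(d0)
  d$Y[runif(500) < 0.35] <- NA
  dd <- incomplete_data(d, outcome = "Y", covariates = c("X2", "X3"),
                        auxiliary = c("X4", "X5"), weight_predictors = "X1")
  analysis <- model_spec("Y", c("X2", "X3", "X2:X3"))
  block <- c("X2", "X3", "X4", "X5")
  ex <- run_strategy(dd, strategy_spec("CC", "CC"), analysis, block = block)
  im <- run_strategy(dd,
    strategy_spec("CC", "MI",
                  imputer2 = regression_imputer("Y", c("X2", "X3", "X2:X3")),
                  M = 400),
    analysis, block = block, seed = 46)
  ## pooled estimate converges to the excluded-fit estimate at rate 1/sqrt(M)
  expect_equal(im$theta, ex$theta, tolerance = 0.02)
})

test_that("strategy runs are reproducible from the seed", {
  d <- generate_twostage(twostage_config(N = 400), seed = 47)
  sp <- study_strategies(M = 4)[["IPW/MI"]]
  analysis <- model_spec("Y", c("X2", "X3", "X2:X3"))
  a <- run_strategy(d, sp, analysis, block = c("X2", "X3", "X4", "X5"), seed = 9)
  b <- run_strategy(d, sp, analysis, block = c("X2", "X3", "X4", "X5"), seed = 9)
  expect_identical(a$theta, b$theta)
  expect_identical(a$Sigma, b$Sigma)
})

test_that("condition checks warn when the imputer ignores the weights", {
  w1 <- weight_model_spec("X1", "saturated")
  bad <- strategy_spec("IPW", "MI", weight_model1 = w1,
                       imputer2 = regression_imputer("Y", c("X2", "X3")))
  analysis <- model_spec("Y", c("X2", "X3", "X2:X3"))
  w <- capture_warnings(validate_conditions(bad, analysis))
  expect_match(w, "neither the weight W", all = FALSE)

  ## imputer containing all weight-model predictors passes silently
  good <- study_strategies(M = 4)[["IPW/MI"]]
  expect_silent(validate_conditions(good, analysis))

  ## strategies without IPW have no weight-related conditions
  mimi <- study_strategies(M = 4)[["MI/MI"]]
  expect_silent(validate_conditions(mimi, analysis))
})
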
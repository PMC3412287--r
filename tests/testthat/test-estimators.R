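test_that("weighted least squares reproduces closed-form special cases", {
  ## intercept-only weighted mean: (1*1 + 3*2) / 4 = 1.75
  fit <- wls_fit(c(1, 2), cbind(`(Intercept)` = c(1, 1)), w = c(1, 3))
  expect_equal(unname(fit$theta), 1.75)

  ## exact linear data: theta recovered, sandwich exactly zero
  x <- cbind(1, c(1, 2, 3, 4))
  y <- drop(x %*% c(2, -1))
  fit2 <- wls_fit(y, x)
  expect_equal(unname(fit2$theta), c(2, -1))
  expect_equal(max(abs(fit2$vcov)), 0, tolerance = 1e-20)
})

test_that("wls point estimate and sandwich match a brute-force oracle", {
  fx <- make_regression_fixture(n = 8)
  fit <- wls_fit(fx$y, fx$x, fx$w)
  orc <- oracle_wls(fx$y, fx$x, fx$w)
  expect_equal(unname(fit$theta), orc$theta, tolerance = 1e-10)
  expect_equal(unname(fit$vcov), unname(orc$vcov), tolerance = 1e-8)
})

test_that("unit-weight wls equals OLS with the HC0 robust variance", {
  fx <- make_regression_fixture(n = 30, seed = 55)
  fit <- wls_fit(fx$y, fx$x)
  lmfit <- lm(fx$y ~ fx$x - 1)
  expect_equal(unname(fit$theta), unname(coef(lmfit)), tolerance = 1e-12)
  skip_if_not_installed("sandwich")
  expect_equal(unname(fit$vcov),
               unname(sandwich::vcovHC(lmfit, type = "HC0")),
               tolerance = 1e-10)
})

test_that("weights are scale-equivariant and equal to row replication", {
  fx <- make_regression_fixture(n = 12, seed = 77)
  f1 <- wls_fit(fx$y, fx$x, fx$w)
  f2 <- wls_fit(fx$y, fx$x, 10 * fx$w)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-12)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-12)

  ## integer weight 2 = physically duplicated row (point estimates)
  y <- c(1, 3, 7); x <- cbind(1, c(0, 1, 2))
  fa <- wls_fit(y, x, c(1, 2, 1))
  fb <- wls_fit(c(y, 3), rbind(x, x[2, ]))
  expect_equal(fa$theta, fb$theta, tolerance = 1e-12)
})

test_that("weighted logistic matches ML and closed forms", {
  set.seed(31)
  n <- 50
  x <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, plogis(drop(x %*% c(-0.5, 1))))
  fit <- weighted_logistic_fit(y, x)
  ref <- glm(y ~ x - 1, family = binomial())
  expect_equal(unname(fit$theta), unname(coef(ref)), tolerance = 1e-8)

  ## intercept-only with mean 0.25: logit(0.25) = log(1/3)
  y2 <- c(1, 0, 0, 0)
  f2 <- weighted_logistic_fit(y2, cbind(rep(1, 4)))
  expect_equal(unname(f2$theta), log(1 / 3), tolerance = 1e-9)

  ## weight 2 equals duplication
  y3 <- c(0, 1, 1, 0, 1); x3 <- cbind(1, c(-1, 0, 1, 2, 0.5))
  fa <- weighted_logistic_fit(y3, x3, c(1, 2, 1, 1, 1))
  fb <- weighted_logistic_fit(c(y3, 1), rbind(x3, x3[2, ]))
  expect_equal(fa$theta, fb$theta, tolerance = 1e-9)
})

test_that("separation and rank deficiency are reported as errors", {
  y <- c(0, 0, 1, 1)
  x <- cbind(1, c(-2, -1, 1, 2))
  expect_error(weighted_logistic_fit(y, x), "separat|converge")
  xx <- cbind(a = c(1, 1, 1), b = c(2, 2, 2))
  expect_error(wls_fit(c(1, 2, 3), xx), "rank deficient")
  expect_error(wls_fit(c(1, 2), cbind(1, 1:2), w = c(1, -1)), "positive")
})

test_that("adjusted sandwich equals the finite-difference stacked oracle (saturated)", {
  d <- make_weighted_fixture(n = 60, seed = 7)
  rule <- rule_block_complete(c("X2", "Y"))
  ws <- fit_missingness_model(d, rule, weight_model_spec("Z", "saturated"))
  keep <- ws$.row[ws$included]
  des <- build_design(d, model_spec("Y", "X2"), rows = keep)
  fit <- wls_fit(des$y, des$x, ws$weight[ws$included], rows = keep)
  adj <- adjusted_sandwich(fit, ws)
  info <- attr(ws, "score_info")
  orc <- oracle_stacked_sandwich(
    des$y, des$x, g = info$g, zinfo = info$stratum, link = "saturated",
    alpha = attr(ws, "alpha"), theta = fit$theta,
    fit_pos = match(keep, info$rows)
  )
  expect_equal(unname(adj$vcov), unname(orc), tolerance = 1e-6)
  ## accounting for weight estimation must not inflate the intercept variance
  expect_lte(adj$vcov[1, 1], fit$vcov[1, 1] + 1e-12)
})

test_that("adjusted sandwich equals the finite-difference stacked oracle (logistic)", {
  set.seed(17)
  n <- 80
  d <- tibble::tibble(Z = rnorm(n))
  obs <- runif(n) < plogis(1 - 0.8 * d$Z)
  d$X2 <- ifelse(obs, rnorm(n), NA)
  d$Y <- ifelse(obs, 1 + 0.5 * d$X2 + rnorm(n), NA)
  ws <- fit_missingness_model(d, rule_block_complete(c("X2", "Y")),
                              weight_model_spec("Z", "logistic"))
  keep <- ws$.row[ws$included]
  des <- build_design(d, model_spec("Y", "X2"), rows = keep)
  fit <- wls_fit(des$y, des$x, ws$weight[ws$included], rows = keep)
  adj <- adjusted_sandwich(fit, ws)
  info <- attr(ws, "score_info")
  orc <- oracle_stacked_sandwich(
    des$y, des$x, g = info$g, zinfo = info$z, link = "logistic",
    alpha = attr(ws, "alpha"), theta = fit$theta,
    fit_pos = match(keep, info$rows)
  )
  expect_equal(unname(adj$vcov), unname(orc), tolerance = 1e-6)
})

test_that("adjusted sandwich refuses known weights", {
  d <- tibble::tibble(X2 = c(1, 2, 3), Y = c(1, 2, 4))
  ws <- set_known_weights(d, rule_block_complete("X2"), rep(1, 3))
  des <- build_design(d, model_spec("Y", "X2"))
  fit <- wls_fit(des$y, des$x, rows = 1:3)
  expect_error(adjusted_sandwich(fit, ws), "known")
})
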
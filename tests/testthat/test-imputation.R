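test_that("observed cells are preserved exactly across all imputations", {
  d <- make_weighted_fixture()
  rule <- rule_block_complete(c("X2", "Y"))
  ## impute Y among rows with X2 observed
  ws <- fit_missingness_model(d, rule_block_complete("X2"),
                              weight_model_spec("Z", "saturated"))
  st <- impute_regression(d, ws, regression_imputer("Y", c("Z", "X2", "Z:X2")),
                          M = 5, seed = 1)
  obs <- !is.na(d$Y[st$rows])
  for (m in 1:5) {
    expect_identical(st$imputations[[m]]$Y[obs], d$Y[st$rows][obs])
    expect_identical(st$imputations[[m]]$X2, d$X2[st$rows])
  }
  expect_false(anyNA(st$imputations[[1]]$Y))
})

test_that("a fully observed outcome yields M identical copies", {
  d <- tibble::tibble(Z = c(0, 1, 0, 1), X2 = c(1, 2, 3, 4), Y = c(1, 3, 2, 5))
  st <- impute_regression(d, NULL, regression_imputer("Y", "X2"), M = 3, seed = 2)
  expect_identical(st$imputations[[1]], st$imputations[[3]])
  expect_equal(st$imputations[[2]]$Y, d$Y)
})

test_that("identical seed and inputs give bit-identical imputation stacks", {
  d <- make_weighted_fixture()
  ws <- fit_missingness_model(d, rule_block_complete("X2"),
                              weight_model_spec("Z", "saturated"))
  spec <- regression_imputer("Y", c("Z", "X2"))
  a <- impute_regression(d, ws, spec, M = 4, seed = 77)
  b <- impute_regression(d, ws, spec, M = 4, seed = 77)
  expect_identical(a$imputations, b$imputations)
})

test_that("error-variance draws follow the scaled inverse chi-square law", {
  ## freeze a fixture; the sigma2 draws must be RSS / chisq_{n-p}
  set.seed(5)
  n <- 40
  d <- tibble::tibble(X2 = rnorm(n), Y = 1 + 0.5 * rnorm(n) + rnorm(n))
  d$Y[1:10] <- NA
  obs <- !is.na(d$Y)
  fit <- lm(Y ~ X2, data = d[obs, ])
  rss <- sum(residuals(fit)^2)
  df <- sum(obs) - 2
  st <- impute_regression(d, NULL, regression_imputer("Y", "X2"),
                          M = 2000, seed = 6)
  sig2 <- st$draws$sigma2
  ## transform: rss/sig2 ~ chisq_df
  ks <- suppressWarnings(ks.test(rss / sig2, "pchisq", df = df))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean of imputed values matches the least-squares prediction", {
  set.seed(8)
  n <- 20000
  x <- rnorm(n)
  y <- 2 + 1.5 * x + rnorm(n)
  mis <- seq_len(n) %% 5 == 0
  d <- tibble::tibble(X2 = x, Y = replace(y, mis, NA))
  obs <- !mis
  bh <- coef(lm(Y ~ X2, data = d[obs, ]))
  pred <- bh[1] + bh[2] * x[mis]
  st <- impute_regression(d, NULL, regression_imputer("Y", "X2"),
                          M = 200, seed = 9)
  imp_mean <- rowMeans(sapply(st$imputations, function(di) di$Y[mis]))
  ## each imputed value is conditional mean + noise of sd ~ 1, averaged
  ## over M = 200 draws; the overall mean discrepancy has SE ~ 1/sqrt(M n)
  se <- 1 / sqrt(200 * sum(mis))
  expect_lt(abs(mean(imp_mean - pred)), 3 * se)
  expect_lt(sd(imp_mean - pred), 2 / sqrt(200))
})

test_that("attach_weight_terms augments with W and W-by-term products, idempotently", {
  spec <- regression_imputer("Y", c("X2", "X3"))
  aug <- attach_weight_terms(spec)
  expect_identical(aug$terms, c("X2", "X3", "W", "W:X2", "W:X3"))
  expect_true(aug$weight_terms)
  expect_identical(attach_weight_terms(aug), aug)

  ## constant weights make the augmentation collinear; the imputer must say so
  d <- tibble::tibble(X2 = rnorm(12), X3 = rnorm(12),
                      Y = c(rnorm(10), NA, NA))
  ws <- set_known_weights(d, rule_block_complete("X2"), rep(2, 12))
  expect_error(impute_regression(d, ws, aug, M = 2, seed = 1), "[Cc]ollinear")
})

test_that("degenerate regression imputation inputs raise informative errors", {
  d <- tibble::tibble(X2 = rnorm(3), Y = c(1, NA, NA))
  expect_error(impute_regression(d, NULL, regression_imputer("Y", "X2"), M = 2),
               "Too few observed rows")
  d2 <- tibble::tibble(X2 = c(1, 2, NA), Y = c(1, 2, NA))
  expect_error(impute_regression(d2, NULL, regression_imputer("Y", "X2"), M = 2),
               "predictor")
})

test_that("mvn block posterior concentrates at the sample moments", {
  set.seed(11)
  n <- 20000
  mu <- c(1, -2, 0.5)
  L <- chol(matrix(c(1, .3, .1, .3, 1, -.2, .1, -.2, 1), 3))
  xx <- matrix(rnorm(n * 3), n, 3) %*% L
  xx <- sweep(xx, 2, mu, "+")
  d <- tibble::tibble(X2 = xx[, 1], X3 = xx[, 2], X4 = xx[, 3])
  mis <- seq_len(n) %% 4 == 0
  for (v in c("X2", "X3", "X4")) d[[v]][mis] <- NA
  st <- impute_mvn_block(d, NULL, mvn_imputer(c("X2", "X3", "X4")),
                         M = 40, seed = 12)
  mus <- do.call(rbind, st$draws$mu)
  xbar <- colMeans(xx[!mis, ])
  se <- sqrt(diag(cov(xx[!mis, ])) / sum(!mis))
  expect_true(all(abs(colMeans(mus) - xbar) < 3 * se))
  ## observed block rows identical across imputations
  expect_identical(st$imputations[[1]]$X2[!mis], d$X2[!mis])
})

test_that("a joint-normal imputer destroys a product mean structure", {
  ## X5 = X2*X3 + noise has zero covariance with (X2, X3, X4), so a
  ## 4-variable joint-normal fit is approximately diagonal and imputed X5
  ## is uncorrelated with X2*X3
  cfg <- twostage_config(N = 1e5)
  d <- generate_twostage(cfg, seed = 13)
  st <- impute_mvn_block(d, NULL, mvn_imputer(c("X2", "X3", "X4", "X5")),
                         M = 1, seed = 14)
  Sig <- st$draws$Sigma[[1]]
  off <- Sig[upper.tri(Sig)] / sqrt(diag(Sig)[1] * diag(Sig)[2])
  expect_true(all(abs(off) < 0.03))
  di <- st$imputations[[1]]
  mis <- is.na(d$X2)
  r <- cor(di$X5[mis], di$X2[mis] * di$X3[mis])
  expect_lt(abs(r), 0.02)
})

test_that("block rows must be missing all-or-nothing", {
  d <- tibble::tibble(X2 = c(1, NA, 3), X3 = c(1, 2, 3))
  expect_error(impute_mvn_block(d, NULL, mvn_imputer(c("X2", "X3")), M = 2),
               "all observed or all missing")
})

test_that("a fully observed block yields M identical copies", {
  d <- tibble::tibble(X2 = rnorm(10), X3 = rnorm(10), X4 = rnorm(10))
  st <- impute_mvn_block(d, NULL, mvn_imputer(c("X2", "X3", "X4")), M = 3,
                         seed = 15)
  expect_identical(st$imputations[[1]], st$imputations[[3]])
  expect_equal(st$imputations[[2]]$X2, d$X2)
})
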
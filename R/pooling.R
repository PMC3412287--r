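new_pooled_fit <- function(theta, Wbar, B, Sigma, df, M) {
  structure(list(theta = theta, Wbar = Wbar, B = B, Sigma = Sigma,
                 df = df, M = M),
            class = "pooled_fit")
}

#' Combine per-imputation fits by Rubin's rules
#'
#' Pools `M >= 2` per-imputation estimates and variances: the pooled
#' estimate is the mean of the per-imputation estimates; the total
#' variance is the mean within-imputation variance plus `(1 + 1/M)` times
#' the between-imputation sample covariance of the estimates. Per-
#' coefficient degrees of freedom follow the classical large-sample
#' formula `(M - 1) (1 + Wbar_jj / ((1 + 1/M) B_jj))^2` (infinite when
#' the between component vanishes).
#'
#' @param fits List of `quasi_fit` objects sharing coefficient order.
#' @return A `pooled_fit` with elements `theta`, `Wbar`, `B`, `Sigma`,
#'   `df`, `M`.
#' @examples
#' f1 <- wls_fit(c(0.9, 2.1), cbind(`(Intercept)` = c(1, 1)))
#' f2 <- wls_fit(c(1.1, 2.9), cbind(`(Intercept)` = c(1, 1)))
#' pool(list(f1, f2))
#' @export
pool <- function(fits) {
  M <- length(fits)
  if (M < 2L) abort("Rubin's rules require M >= 2 per-imputation fits.")
  for (f in fits) stopifnot(inherits(f, "quasi_fit"))
  p <- length(fits[[1]]$theta)
  nm <- names(fits[[1]]$theta)
  for (f in fits) {
    if (length(f$theta) != p || !identical(names(f$theta), nm)) {
      abort("All fits must share coefficient dimension and ordering.")
    }
  }
  thetas <- do.call(rbind, lapply(fits, function(f) f$theta))
  theta_bar <- colMeans(thetas)
  Wbar <- Reduce(`+`, lapply(fits, function(f) f$vcov)) / M
  B <- cov(thetas)                       # (M-1)^-1 sum (th_m - bar)(...)'
  Sigma <- Wbar + (1 + 1 / M) * B
  dimnames(Wbar) <- dimnames(B) <- dimnames(Sigma) <- list(nm, nm)
  bjj <- diag(B)
  df <- ifelse(bjj > 0,
               (M - 1) * (1 + diag(Wbar) / ((1 + 1 / M) * bjj))^2,
               Inf)
  new_pooled_fit(setNames(theta_bar, nm), Wbar, B, Sigma, setNames(df, nm), M)
}

## single-fit wrapper: M = 1, B = 0 convention for interface uniformity
pooled_single <- function(fit) {
  p <- length(fit$theta)
  zero <- matrix(0, p, p, dimnames = dimnames(fit$vcov))
  df <- rep(max(fit$n - p, 1L), p)
  new_pooled_fit(fit$theta, fit$vcov, zero, fit$vcov,
                 setNames(df, names(fit$theta)), 1L)
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("<pooled_fit> M = ", x$M, " imputations\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.pooled_fit <- function(x, ...) {
  se <- unname(sqrt(diag(x$Sigma)))
  tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std.error = se,
    statistic = unname(x$theta) / se,
    df = unname(x$df)
  )
}

#' @export
glance.pooled_fit <- function(x, ...) {
  tibble::tibble(
    M = x$M,
    within.trace = sum(diag(x$Wbar)),
    between.trace = sum(diag(x$B))
  )
}
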
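new_quasi_fit <- function(theta, vcov, kind, n, x = NULL, y = NULL, w = NULL,
                          rows = NULL, weight_uncertainty = FALSE) {
  structure(list(theta = theta, vcov = vcov, kind = kind, n = n,
                 x = x, y = y, w = w, rows = rows,
                 weight_uncertainty = weight_uncertainty),
            class = "quasi_fit")
}

#' @export
print.quasi_fit <- function(x, ...) {
  cat("<quasi_fit> ", x$kind, ", n = ", x$n,
      if (x$weight_uncertainty) ", weight-adjusted variance", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

check_design_rank <- function(x, tol = 1e-8) {
  qr_x <- qr(x, tol = tol)
  if (qr_x$rank < ncol(x)) {
    dep <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    abort(paste0("Design matrix is rank deficient; dependent column(s): ",
                 paste(dep, collapse = ", ")))
  }
  qr_x
}

#' Weighted least squares with sandwich variance
#'
#' Solves the weighted estimating equations
#' `sum_i W_i x_i (y_i - x_i' theta) = 0`, i.e.
#' `theta = (X'diag(W)X)^-1 X'diag(W)y`, via a QR decomposition of the
#' `sqrt(W)`-scaled design. The variance is the robust sandwich
#' `A^-1 B A^-1` with `A = sum W_i x_i x_i'` and
#' `B = sum W_i^2 e_i^2 x_i x_i'` (HC0 form; with unit weights this is
#' OLS with the HC0 heteroscedasticity-robust variance).
#'
#' @param y Numeric outcome vector.
#' @param x Design matrix (use [build_design()]); must be full column rank.
#' @param w Positive weights (default all 1).
#' @param rows Optional original row indices of the fitted individuals,
#'   carried for [adjusted_sandwich()].
#' @return A `quasi_fit` with elements `theta` and `vcov`.
#' @examples
#' fit <- wls_fit(c(1, 2), cbind(1, 0:1), w = c(1, 3))
#' tidy(fit)
#' @export
wls_fit <- function(y, x, w = rep(1, length(y)), rows = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(y) != nrow(x) || length(w) != nrow(x)) {
    abort("`y`, `w` and the rows of `x` must have equal length.")
  }
  if (anyNA(w) || any(w <= 0)) abort("Weights must be positive.")
  sw <- sqrt(w)
  qr_x <- check_design_rank(x * sw)
  theta <- qr.coef(qr_x, y * sw)
  e <- y - drop(x %*% theta)
  A <- crossprod(x, w * x)
  B <- crossprod(x, (w^2 * e^2) * x)
  A_inv <- chol2inv(chol(A))
  U <- A_inv %*% B %*% A_inv
  dimnames(U) <- list(colnames(x), colnames(x))
  new_quasi_fit(setNames(theta, colnames(x)), U, "wls", length(y),
                x = x, y = y, w = w, rows = rows)
}

#' Weighted logistic regression with sandwich variance
#'
#' Solves `sum_i W_i x_i (y_i - expit(x_i' theta)) = 0` by damped Newton
#' iteration (step-halving), with the sandwich variance `A^-1 B A^-1`,
#' `A = sum W_i v_i x_i x_i'` (`v_i` the fitted Bernoulli variance) and
#' `B = sum W_i^2 (y_i - p_i)^2 x_i x_i'`.
#'
#' @inheritParams wls_fit
#' @param y Binary 0/1 outcome.
#' @param max_iter,tol Newton controls: at most `max_iter` iterations,
#'   convergence when the largest score component is below `tol`.
#' @return A `quasi_fit` of kind `"weighted-logistic"`.
#' @export
weighted_logistic_fit <- function(y, x, w = rep(1, length(y)), rows = NULL,
                                  max_iter = 100L, tol = 1e-9) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!all(y %in% c(0, 1))) abort("`y` must be coded 0/1.")
  if (anyNA(w) || any(w <= 0)) abort("Weights must be positive.")
  check_design_rank(x)
  p_dim <- ncol(x)
  theta <- numeric(p_dim)
  score_at <- function(th) {
    pr <- plogis(drop(x %*% th))
    list(s = drop(crossprod(x, w * (y - pr))), p = pr)
  }
  cur <- score_at(theta)
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$s)) < tol) break
    v <- cur$p * (1 - cur$p)
    J <- crossprod(x, (w * v) * x)
    step <- tryCatch(solve(J, cur$s), error = function(e) {
      abort("Newton step failed (singular information); possible separation.")
    })
    lambda <- 1
    for (h in 0:30) {
      cand <- theta + lambda * step
      nxt <- score_at(cand)
      if (max(abs(nxt$s)) < max(abs(cur$s)) || max(abs(nxt$s)) < tol) break
      lambda <- lambda / 2
    }
    theta <- cand; cur <- nxt
  }
  if (max(abs(cur$s)) >= tol) {
    abort(paste0("Weighted logistic fit did not converge (max |score| = ",
                 format(max(abs(cur$s)), digits = 3),
                 "); possible separation."))
  }
  if (max(abs(drop(x %*% theta))) > 30) {
    abort("Fitted probabilities at machine boundary; data are separated.")
  }
  pr <- cur$p
  v <- pr * (1 - pr)
  A <- crossprod(x, (w * v) * x)
  B <- crossprod(x, (w^2 * (y - pr)^2) * x)
  A_inv <- chol2inv(chol(A))
  U <- A_inv %*% B %*% A_inv
  dimnames(U) <- list(colnames(x), colnames(x))
  new_quasi_fit(setNames(theta, colnames(x)), U, "weighted-logistic", length(y),
                x = x, y = y, w = w, rows = rows)
}

#' Sandwich variance accounting for estimated weights
#'
#' Replaces the variance of a weighted fit by the relevant block of the
#' stacked-estimating-equation sandwich: the missingness-model score
#' equations for the weight parameters are stacked above the weighted
#' analysis estimating equations, the joint bread is the block Jacobian
#' of the stacked system, the joint meat the outer products of the
#' stacked per-individual contributions, and the reported variance is the
#' analysis-parameter block. Treating estimated weights as known
#' typically overstates the variance, most visibly for the intercept.
#'
#' @param fit A `quasi_fit` from [wls_fit()] or [weighted_logistic_fit()]
#'   carrying `rows` (original row indices of the fitted individuals).
#' @param weightfit The `weight_set` whose weights entered `fit`; must
#'   have been estimated (`known_weights = FALSE`).
#' @return The `quasi_fit` with `vcov` replaced and
#'   `weight_uncertainty = TRUE`.
#' @export
adjusted_sandwich <- function(fit, weightfit) {
  stopifnot(inherits(fit, "quasi_fit"), inherits(weightfit, "weight_set"))
  if (attr(weightfit, "known_weights")) {
    abort("Weights are known; the weight-estimation adjustment does not apply.")
  }
  info <- attr(weightfit, "score_info")
  if (is.null(info) || info$type == "degenerate") {
    abort("Weight set carries no score information to stack.")
  }
  if (is.null(fit$rows)) {
    abort("`fit` must carry `rows` mapping fitted individuals to the weight model.")
  }
  g <- info$g
  N <- length(g)
  fit_pos <- match(fit$rows, info$rows)
  if (anyNA(fit_pos)) abort("`fit` rows are not a subset of the weight-model rows.")

  x <- fit$x; yv <- fit$y; w <- fit$w
  n_fit <- nrow(x); p_theta <- ncol(x)
  if (fit$kind == "wls") {
    mu <- drop(x %*% fit$theta); v <- rep(1, n_fit)
  } else {
    mu <- plogis(drop(x %*% fit$theta)); v <- mu * (1 - mu)
  }
  e <- yv - mu

  if (info$type == "logistic") {
    z <- info$z
    p_alpha <- ncol(z)
    pi_all <- plogis(drop(z %*% attr(weightfit, "alpha")))
    S <- z * (g - pi_all)                       # N x p_alpha score rows
    J_aa <- -crossprod(z, (pi_all * (1 - pi_all)) * z)
    ## dW/dalpha for fitted rows: -W(1-pi) z
    dW <- -(w * (1 - pi_all[fit_pos])) * z[fit_pos, , drop = FALSE]
  } else {                                      # saturated strata
    k <- info$stratum
    p_alpha <- info$n_strata
    alpha <- attr(weightfit, "alpha")
    pi_all <- alpha[k]
    S <- matrix(0, N, p_alpha)
    S[cbind(seq_len(N), k)] <- g - pi_all
    J_aa <- -diag(tabulate(k, p_alpha), p_alpha)
    dW <- matrix(0, n_fit, p_alpha)             # dW_i/dpi_s = -W^2 on own stratum
    dW[cbind(seq_len(n_fit), k[fit_pos])] <- -w^2
  }

  U <- matrix(0, N, p_theta)                    # analysis scores, all N rows
  U[fit_pos, ] <- (w * e) * x
  J_tt <- -crossprod(x, (w * v) * x)
  J_ta <- crossprod(x * e, dW)                  # d/dalpha sum W_i x_i e_i

  J <- rbind(cbind(J_aa, matrix(0, p_alpha, p_theta)),
             cbind(J_ta, J_tt))
  G <- cbind(S, U)
  meat <- crossprod(G)
  J_inv <- solve(J)
  V <- J_inv %*% meat %*% t(J_inv)
  idx <- p_alpha + seq_len(p_theta)
  vc <- V[idx, idx, drop = FALSE]
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- dimnames(fit$vcov)
  out <- fit
  out$vcov <- vc
  out$weight_uncertainty <- TRUE
  out
}

#' @export
tidy.quasi_fit <- function(x, ...) {
  se <- unname(sqrt(diag(x$vcov)))
  tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std.error = se,
    statistic = unname(x$theta) / se
  )
}

#' @export
glance.quasi_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, nobs = x$n,
                 weight_uncertainty = x$weight_uncertainty)
}
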
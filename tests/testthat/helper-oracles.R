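## Independent brute-force oracles used to validate the closed-form
## estimators. Each deliberately avoids the code path it checks.

## Solve weighted estimating equations sum w x (y - x'theta) = 0 by a
## generic Newton root-finder with finite-difference Jacobian, and build
## the sandwich A^-1 B A^-1 by explicit per-observation loops.
oracle_wls <- function(y, x, w) {
  p <- ncol(x)
  score <- function(th) {
    s <- numeric(p)
    for (i in seq_along(y)) s <- s + w[i] * x[i, ] * (y[i] - sum(x[i, ] * th))
    s
  }
  th <- numeric(p)
  for (it in 1:50) {
    s <- score(th)
    if (max(abs(s)) < 1e-12) break
    J <- matrix(0, p, p)
    h <- 1e-6
    for (j in seq_len(p)) {
      e <- numeric(p); e[j] <- h
      J[, j] <- (score(th + e) - score(th - e)) / (2 * h)
    }
    th <- th - solve(J, s)
  }
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (i in seq_along(y)) {
    xi <- x[i, ]
    ei <- y[i] - sum(xi * th)
    A <- A + w[i] * outer(xi, xi)
    B <- B + w[i]^2 * ei^2 * outer(xi, xi)
  }
  Ai <- solve(A)
  list(theta = th, vcov = Ai %*% B %*% Ai)
}

## Stacked (weight-model + analysis) sandwich by central finite
## differences of the summed stacked estimating equations.
## Parameters: alpha = stratum inclusion probabilities (saturated link)
## or logistic coefficients; theta = analysis coefficients.
oracle_stacked_sandwich <- function(y, x, g, zinfo, link, alpha, theta,
                                    fit_pos) {
  N <- length(g)
  p_a <- length(alpha); p_t <- length(theta)
  contrib <- function(par) {
    a <- par[seq_len(p_a)]; th <- par[p_a + seq_len(p_t)]
    if (link == "saturated") {
      pi_all <- a[zinfo]                      # zinfo = stratum index per row
      S <- matrix(0, N, p_a)
      S[cbind(seq_len(N), zinfo)] <- g - pi_all
    } else {
      pi_all <- plogis(drop(zinfo %*% a))     # zinfo = z design matrix
      S <- zinfo * (g - pi_all)
    }
    U <- matrix(0, N, p_t)
    w <- 1 / pi_all[fit_pos]
    U[fit_pos, ] <- (w * (y - drop(x %*% th))) * x
    cbind(S, U)
  }
  par <- c(alpha, theta)
  q <- p_a + p_t
  Gsum <- function(p_) colSums(contrib(p_))
  J <- matrix(0, q, q)
  h <- 1e-6
  for (j in seq_len(q)) {
    e <- numeric(q); e[j] <- h
    J[, j] <- (Gsum(par + e) - Gsum(par - e)) / (2 * h)
  }
  Gm <- contrib(par)
  meat <- crossprod(Gm)
  Ji <- solve(J)
  V <- Ji %*% meat %*% t(Ji)
  V[p_a + seq_len(p_t), p_a + seq_len(p_t), drop = FALSE]
}
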
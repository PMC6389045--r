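# Brute-force REML oracle: dense-matrix restricted likelihood over
# (sigma2_mu, sigma2_eps), maximized by Nelder-Mead from several starts.
# Deliberately independent of the package's profiled/whitened fitting path.

oracle_reml_loglik <- function(s2m, s2e, y, X, groups) {
  Z <- stats::model.matrix(~ factor(groups) - 1)
  n <- length(y)
  p <- qr(X)$rank
  S <- s2e * diag(n) + s2m * tcrossprod(Z)
  Si <- solve(S)
  XtSiX <- t(X) %*% Si %*% X
  b <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% b
  -0.5 * as.numeric(determinant(S)$modulus +
                      determinant(XtSiX)$modulus +
                      t(r) %*% Si %*% r + (n - p) * log(2 * pi))
}

oracle_reml_fit <- function(y, X, groups) {
  nll <- function(par) -oracle_reml_loglik(exp(par[1]), exp(par[2]),
                                           y, X, groups)
  v <- stats::var(y)
  starts <- list(log(c(v / 2, v / 2)), log(c(v / 10, v)), log(c(v, v / 10)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(loglik = -best$value, sigma2_mu = exp(best$par[1]),
       sigma2_eps = exp(best$par[2]))
}
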
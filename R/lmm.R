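# Random-intercept linear mixed model, y = X b + Z u + e with
# u_i ~ N(0, sigma2_mu), e ~ N(0, sigma2_eps), estimated by REML.
#
# The marginal covariance is sigma2_eps * V(lambda) with
# V = I + lambda Z Z', lambda = sigma2_mu / sigma2_eps. V is block diagonal
# per individual, so GLS reduces to OLS after a cheap per-group whitening:
# y_tilde = y - d_g * mean_g(y), d_g = 1 - 1/sqrt(1 + lambda * n_g), and
# log|V| = sum_g log(1 + lambda * n_g). The restricted likelihood is
# profiled over lambda (sigma2_eps has a closed form at each lambda) and
# maximized on log-lambda by a grid scan refined with Brent's method, with
# the lambda -> 0 boundary (plain OLS) checked explicitly.

whiten_groups <- function(x, group_idx, n_g, lambda) {
  d <- 1 - 1 / sqrt(1 + lambda * n_g)
  x <- as.matrix(x)
  gm <- rowsum(x, group_idx, reorder = TRUE) / n_g
  x - d[group_idx] * gm[group_idx, , drop = FALSE]
}

# profiled restricted log-likelihood at a given lambda; also returns the
# GLS pieces needed to finish the fit
reml_pieces <- function(lambda, y, X, group_idx, n_g) {
  yt <- whiten_groups(y, group_idx, n_g, lambda)
  Xt <- whiten_groups(X, group_idx, n_g, lambda)
  qrx <- qr(Xt)
  p <- qrx$rank
  n <- length(y)
  res <- qr.resid(qrx, yt)
  rss <- sum(res^2)
  s2 <- rss / (n - p)
  logdetV <- sum(log1p(lambda * n_g))
  R <- qr.R(qrx)[seq_len(p), seq_len(p), drop = FALSE]
  logdetXtX <- 2 * sum(log(abs(diag(R))))
  ll <- -0.5 * ((n - p) * log(s2) + logdetV + logdetXtX +
                  (n - p) + (n - p) * log(2 * pi))
  list(ll = ll, s2 = s2, qrx = qrx, yt = yt, logdetV = logdetV)
}

#' Restricted log-likelihood of the random-intercept model
#'
#' Evaluates the REML log-likelihood at given variance components
#' `(sigma2_mu, sigma2_eps)`; used internally by the fitter and exported so
#' the estimates can be compared against generic numerical optimizers.
#'
#' @param sigma2_mu,sigma2_eps variance components (>= 0, > 0).
#' @param y outcome vector.
#' @param X fixed-effects design matrix (with intercept).
#' @param groups grouping vector (one level per individual).
#' @return the restricted log-likelihood (a scalar).
#' @export
reml_loglik <- function(sigma2_mu, sigma2_eps, y, X, groups) {
  gi <- as.integer(factor(groups))
  n_g <- tabulate(gi)
  lambda <- sigma2_mu / sigma2_eps
  yt <- whiten_groups(y, gi, n_g, lambda)
  Xt <- whiten_groups(as.matrix(X), gi, n_g, lambda)
  qrx <- qr(Xt)
  p <- qrx$rank
  n <- length(y)
  rss <- sum(qr.resid(qrx, yt)^2)
  R <- qr.R(qrx)[seq_len(p), seq_len(p), drop = FALSE]
  logdetXtX <- 2 * sum(log(abs(diag(R))))
  logdetV <- sum(log1p(lambda * n_g))
  -0.5 * ((n - p) * log(sigma2_eps) + logdetV + logdetXtX +
            rss / sigma2_eps + (n - p) * log(2 * pi))
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Estimates the individual-level and residual variance components by
#' restricted maximum likelihood, profiling over the variance ratio
#' `lambda = sigma2_mu/sigma2_eps` on `log(lambda) in [-12, 12]` (grid scan
#' plus Brent refinement) with the `lambda -> 0` boundary (ordinary least
#' squares) compared explicitly. Fixed effects come from generalized least
#' squares at the optimum; their standard errors from the GLS covariance.
#' Aliased design columns are dropped and reported.
#'
#' @param y outcome vector.
#' @param X fixed-effects design matrix (with intercept column).
#' @param groups grouping vector, one level per individual; individuals
#'   contribute one or two observations in the two-visit designs, but any
#'   group size is supported.
#' @param method `"REML"` (default) or `"ML"`. ML replaces the restricted
#'   criterion by the full profile likelihood.
#' @return object of class `lmm_fit`: `coefficients` (data.frame with
#'   `estimate`, `se`), `sigma2_mu`, `sigma2_eps`, `loglik` (restricted),
#'   `converged`, `n_obs`, `n_groups`, `dropped` (aliased columns), and the
#'   model frame pieces needed for Satterthwaite p-values.
#' @seealso [lmm_pvalues()]
#' @export
fit_random_intercept_lmm <- function(y, X, groups, method = c("REML", "ML")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- !is.na(y) & !apply(is.na(X), 1L, any)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  groups <- factor(groups[ok])
  gi <- as.integer(groups)
  n_g <- tabulate(gi)
  n <- length(y)

  # drop aliased columns up front so every lambda sees the same design
  qr0 <- qr(X)
  dropped <- character(0)
  if (qr0$rank < ncol(X)) {
    keep <- qr0$pivot[seq_len(qr0$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    X <- X[, sort(keep), drop = FALSE]
  }
  p <- ncol(X)
  if (n < p + 2L) stop("too few observations to fit the model")

  crit <- function(loglam) {
    if (method == "REML")
      reml_pieces(exp(loglam), y, X, gi, n_g)$ll
    else ml_profile(exp(loglam), y, X, gi, n_g)
  }
  grid <- seq(-12, 12, length.out = 49L)
  vals <- vapply(grid, crit, numeric(1))
  best <- which.max(vals)
  lo <- grid[max(1L, best - 1L)]; hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(crit, c(lo, hi), maximum = TRUE, tol = 1e-10)
  # boundary check: sigma2_mu = 0
  ll0 <- if (method == "REML") reml_pieces(0, y, X, gi, n_g)$ll
         else ml_profile(0, y, X, gi, n_g)
  if (ll0 >= opt$objective) {
    lambda <- 0
    llmax <- ll0
  } else {
    lambda <- exp(opt$maximum)
    llmax <- opt$objective
  }
  converged <- !(lambda > 0 && abs(opt$maximum) > 11.99)

  pc <- reml_pieces(lambda, y, X, gi, n_g)
  s2_eps <- if (method == "REML") pc$s2 else {
    rss <- sum(qr.resid(pc$qrx, pc$yt)^2); rss / n
  }
  beta <- qr.coef(pc$qrx, pc$yt)
  R <- qr.R(pc$qrx)
  XtXinv <- chol2inv(R[seq_len(p), seq_len(p), drop = FALSE])
  piv <- pc$qrx$pivot
  vcov_b <- matrix(NA_real_, p, p)
  vcov_b[piv, piv] <- s2_eps * XtXinv
  se <- sqrt(diag(vcov_b))

  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              se = se, stringsAsFactors = FALSE),
    vcov = vcov_b,
    sigma2_mu = lambda * s2_eps,
    sigma2_eps = s2_eps,
    loglik = llmax,
    method = method,
    converged = converged,
    n_obs = n,
    n_groups = nlevels(groups),
    rank = p,
    dropped = dropped,
    model = list(y = y, X = X, groups = gi, n_g = n_g)),
    class = "lmm_fit")
}

# full profile log-likelihood (ML) at a given lambda
ml_profile <- function(lambda, y, X, gi, n_g) {
  yt <- whiten_groups(y, gi, n_g, lambda)
  Xt <- whiten_groups(X, gi, n_g, lambda)
  qrx <- qr(Xt)
  n <- length(y)
  rss <- sum(qr.resid(qrx, yt)^2)
  s2 <- rss / n
  -0.5 * (n * log(s2) + sum(log1p(lambda * n_g)) + n + n * log(2 * pi))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("random-intercept LMM (%s): %d obs, %d groups%s\n",
              x$method, x$n_obs, x$n_groups,
              if (x$converged) "" else " [not converged]"))
  cat(sprintf("  sigma2_mu = %.4g, sigma2_eps = %.4g, logLik = %.4f\n",
              x$sigma2_mu, x$sigma2_eps, x$loglik))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# variance of coefficient k as a function of theta = (sigma2_mu, sigma2_eps)
coef_var_at <- function(theta, k, model) {
  lambda <- theta[1] / theta[2]
  Xt <- whiten_groups(model$X, model$groups, model$n_g, lambda)
  XtXinv <- chol2inv(chol(crossprod(Xt)))
  theta[2] * XtXinv[k, k]
}

#' P-values for a fitted random-intercept model
#'
#' Two-sided p-values for each fixed effect from a t distribution with
#' Satterthwaite-approximated degrees of freedom: for coefficient k,
#' `df = 2 c_k^2 / (g' A g)` where `c_k` is the coefficient's variance,
#' `g` its gradient with respect to the variance components (finite
#' differences) and `A` the inverse of the negative Hessian of the
#' restricted log-likelihood at the estimates. At the `sigma2_mu = 0`
#' boundary the ordinary-least-squares residual df is used; non-positive or
#' undefined df fall back to the normal approximation with a warning.
#'
#' @param fit an `lmm_fit` from [fit_random_intercept_lmm()].
#' @param df_method `"satterthwaite"` (default) or `"normal"`.
#' @return data.frame `term`, `estimate`, `se`, `df`, `t`, `p`.
#' @export
lmm_pvalues <- function(fit, df_method = c("satterthwaite", "normal")) {
  df_method <- match.arg(df_method)
  est <- fit$coefficients$estimate
  se <- fit$coefficients$se
  tval <- est / se
  p <- fit$rank
  if (df_method == "normal") {
    df <- rep(Inf, length(est))
  } else if (fit$sigma2_mu <= 1e-10 * fit$sigma2_eps) {
    df <- rep(fit$n_obs - p, length(est))
  } else {
    df <- satterthwaite_df(fit)
  }
  pval <- 2 * stats::pt(-abs(tval), df)
  data.frame(term = fit$coefficients$term, estimate = est, se = se,
             df = df, t = tval, p = pval, stringsAsFactors = FALSE)
}

satterthwaite_df <- function(fit) {
  model <- fit$model
  theta <- c(fit$sigma2_mu, fit$sigma2_eps)
  ll <- function(th) reml_loglik(th[1], th[2], model$y, model$X,
                                 model$groups)
  h <- pmax(1e-7, 1e-4 * theta)
  H <- matrix(NA_real_, 2, 2)
  f0 <- ll(theta)
  for (i in 1:2) for (j in i:2) {
    ei <- ej <- c(0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (ll(theta + ei) - 2 * f0 + ll(pmax(theta - ei, 1e-12))) /
        h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (ll(theta + ei + ej) - ll(theta + ei - ej) -
           ll(theta - ei + ej) + ll(pmax(theta - ei - ej, 1e-12))) /
        (4 * h[i] * h[j])
    }
  }
  A <- tryCatch(solve(-H), error = function(e) NULL)
  n_coef <- nrow(fit$coefficients)
  df <- rep(NA_real_, n_coef)
  if (!is.null(A) && all(is.finite(A)) && all(diag(A) > 0)) {
    for (k in seq_len(n_coef)) {
      if (is.na(fit$coefficients$se[k])) next
      g <- numeric(2)
      for (i in 1:2) {
        e <- c(0, 0); e[i] <- h[i]
        g[i] <- (coef_var_at(theta + e, k, model) -
                   coef_var_at(pmax(theta - e, 1e-12), k, model)) / (2 * h[i])
      }
      ck <- coef_var_at(theta, k, model)
      denom <- drop(t(g) %*% A %*% g)
      if (denom > 0) df[k] <- 2 * ck^2 / denom
    }
  }
  bad <- !is.finite(df) | df <= 0
  if (any(bad)) {
    warning("Satterthwaite df unavailable for ", sum(bad),
            " coefficient(s); using the normal approximation")
    df[bad] <- Inf
  }
  df
}
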
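#' Beta-value to M-value transform
#'
#' Methylation beta-values (methylated / total signal, bounded in (0,1)) are
#' mapped to the unbounded M-value scale by the binary logit,
#' M = log2(beta / (1 - beta)). Regression models in this package operate on
#' M-values; beta-values are kept for the fine-scale change analyses.
#'
#' @param beta numeric vector or matrix with entries strictly in (0, 1);
#'   `NA`s pass through.
#' @return M-values of the same shape.
#' @seealso [m_to_beta()] for the inverse.
#' @export
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))   # -2, 0, 2
beta_to_m <- function(beta) {
  bad <- which(!is.na(beta) & (beta <= 0 | beta >= 1))
  if (length(bad))
    stop("beta values must lie strictly in (0, 1); offending entries at ",
         "positions: ", paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ...")
  log2(beta / (1 - beta))
}

#' M-value to beta-value transform
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector or matrix of M-values.
#' @return beta-values in (0, 1) of the same shape.
#' @export
m_to_beta <- function(m) {
  # plogis on the log-2 scale; stable for large |m|
  stats::plogis(m * log(2))
}

#' @describeIn beta_to_m transform the `values` matrix of a
#'   beta-scale [methylation_set()] to the M scale.
#' @param x a `methylation_set` on the `beta` scale.
#' @export
beta_to_m_set <- function(x) {
  stopifnot(inherits(x, "methylation_set"))
  if (x$scale != "beta")
    stop("input is on scale '", x$scale, "'; beta_to_m_set needs 'beta'")
  x$values <- beta_to_m(x$values)
  x$scale <- "M"
  x
}
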
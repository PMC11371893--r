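#' Quantile-parameterized split-normal marginals
#'
#' The cohort tables this package emulates report each metric only as a
#' median with interquartile range. `fit_marginal` turns such a triplet
#' (q25, q50, q75) into a full distribution: a two-piece ("split") normal
#' in the quantile-spliced parameterization, with location q50, lower
#' scale (q50 - q25)/z75 and upper scale (q75 - q50)/z75 where
#' z75 = qnorm(0.75) = 0.6745; its quantile function is
#' Q(p) = q50 + s_lo * qnorm(p) for p < 1/2 and q50 + s_hi * qnorm(p)
#' otherwise, so the configured quartiles are reproduced exactly.
#' Optionally truncated to a natural support by inverse-CDF restriction.
#'
#' @param q25,q50,q75 strictly increasing quartile triplet.
#' @param lower,upper support bounds (defaults unbounded); the bounds must
#'   contain the triplet.
#' @return object of class `split_marginal` with functions `q(p)`, `p(x)`,
#'   `r(n)` (all honouring the truncation) and fields `q25`, `q50`, `q75`,
#'   `s_lo`, `s_hi`, `lower`, `upper`.
#' @examples
#' m <- fit_marginal(0.34, 0.41, 0.51, lower = 0, upper = 1)
#' m$q(c(0.25, 0.5, 0.75))
#' @export
fit_marginal <- function(q25, q50, q75, lower = -Inf, upper = Inf) {
  if (!(q25 < q50 && q50 < q75))
    stop("config error: quantile triplet must be strictly increasing")
  if (!(lower < q25 && q75 < upper))
    stop("config error: support bounds must contain the quantile triplet")
  z75 <- stats::qnorm(0.75)
  s_lo <- (q50 - q25) / z75
  s_hi <- (q75 - q50) / z75
  p_raw <- function(x) ifelse(x < q50, stats::pnorm((x - q50) / s_lo),
                              stats::pnorm((x - q50) / s_hi))
  q_raw <- function(p) ifelse(p < 0.5, q50 + s_lo * stats::qnorm(p),
                              q50 + s_hi * stats::qnorm(p))
  plo <- p_raw(lower); phi <- p_raw(upper)
  obj <- list(
    q25 = q25, q50 = q50, q75 = q75, s_lo = s_lo, s_hi = s_hi,
    lower = lower, upper = upper,
    # truncated quantile function: maps (0,1) onto (lower, upper)
    q = function(p) q_raw(plo + p * (phi - plo)),
    p = function(x) (p_raw(pmin(pmax(x, lower), upper)) - plo) / (phi - plo),
    r = function(n) q_raw(plo + stats::runif(n) * (phi - plo)))
  class(obj) <- "split_marginal"
  obj
}

#' @export
print.split_marginal <- function(x, ...) {
  cat(sprintf("Split-normal marginal: quartiles (%.4g, %.4g, %.4g), scales (%.4g, %.4g), support (%g, %g)\n",
              x$q25, x$q50, x$q75, x$s_lo, x$s_hi, x$lower, x$upper))
  invisible(x)
}
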
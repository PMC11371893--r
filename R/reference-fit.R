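#' Fit the interpolated reference ("healthy") lumen line
#'
#' Estimates the disease-free lumen profile a vessel would have without its
#' lesion(s). Following standard QCA convention the model is linear in the
#' equivalent diameter d(s) = 2*sqrt(A/pi): a straight taper fitted by
#' iteratively trimmed least squares. Starting from an ordinary fit on all
#' samples, points lying more than one robust (MAD-based) standard deviation
#' *below* the line — candidate diseased samples — are discarded and the
#' line refitted, until the retained set is stable (at most `max_iter`
#' passes). The fitted diameter line is converted back to area,
#' R(s) = pi * (d(s)/2)^2.
#'
#' @param profile an [area_profile]; at least 20 samples (resample first if
#'   needed).
#' @param min_healthy_frac minimum fraction of samples that must be retained
#'   as healthy; below this the vessel is considered degenerate (no reliable
#'   reference can be interpolated) and an error is raised.
#' @param max_iter maximum trimming passes.
#' @param trim_k trim multiplier: points with residual < -trim_k * sigma are
#'   discarded, sigma being 1.4826 * MAD of the retained residuals (with a
#'   small absolute floor so that noise-free profiles are not trimmed).
#'   The default 2 keeps one-sided trimming convergent: a 1-sigma cut would
#'   repeatedly shave the lower fringe of the healthy noise itself and let
#'   the refitted line drift upward.
#' @return object of class `reference_fit`: list with `s`, `R` (reference
#'   area, mm^2), `coef` (intercept and slope of the diameter line),
#'   `retained` (logical, healthy samples), `iterations`, and the input
#'   `profile`.
#' @seealso [detect_lesion], [quantify_vessel]
#' @export
fit_reference <- function(profile, min_healthy_frac = 0.25, max_iter = 20L,
                          trim_k = 2) {
  stopifnot(inherits(profile, "area_profile"))
  s <- profile$s
  if (length(s) < 20L)
    stop("invalid profile: need >= 20 samples to interpolate a reference; resample first")
  d <- 2 * sqrt(profile$A / pi)
  n <- length(s)
  floor_sig <- 1e-8 * mean(d)
  retained <- rep(TRUE, n)
  iterations <- 0L
  beta <- NULL
  for (it in seq_len(max_iter)) {
    beta <- .lsfit2(s[retained], d[retained])
    res <- d - (beta[1L] + beta[2L] * s)
    rr <- res[retained]
    sig <- max(1.4826 * stats::median(abs(rr - stats::median(rr))), floor_sig)
    new_ret <- res >= -trim_k * sig
    if (sum(new_ret) < min_healthy_frac * n)
      stop(sprintf(
        "degenerate vessel '%s': only %d/%d samples retained as healthy (< %.0f%%); no reliable reference line",
        profile$vessel_id, sum(new_ret), n, 100 * min_healthy_frac))
    if (identical(new_ret, retained)) break
    retained <- new_ret
    iterations <- it
  }
  dfit <- beta[1L] + beta[2L] * s
  if (any(dfit <= 0))
    stop(sprintf("degenerate vessel '%s': fitted reference diameter non-positive",
                 profile$vessel_id))
  structure(list(s = s, R = pi * (dfit / 2)^2, coef = c(intercept = beta[[1L]],
                                                        slope = beta[[2L]]),
                 retained = retained, iterations = iterations,
                 profile = profile),
            class = "reference_fit")
}

# 2-parameter least squares, closed form (fast path for the trimming loop)
.lsfit2 <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- sum((x - mx) * (y - my)) / sxx
  c(my - b * mx, b)
}

#' @export
print.reference_fit <- function(x, ...) {
  cat(sprintf(
    "Reference line for '%s': d(s) = %.4f %+.5f*s mm, %d/%d samples healthy, %d trim pass(es)\n",
    x$profile$vessel_id, x$coef[1L], x$coef[2L], sum(x$retained),
    length(x$retained), x$iterations))
  invisible(x)
}

#' @export
coef.reference_fit <- function(object, ...) object$coef

#' @export
fitted.reference_fit <- function(object, ...) object$R

#' Residuals of a reference fit
#'
#' @param object a [fit_reference] result.
#' @param type `"area"` (measured minus reference area, mm^2) or
#'   `"diameter"` (equivalent-diameter residuals, mm).
#' @param ... unused.
#' @export
residuals.reference_fit <- function(object, type = c("area", "diameter"), ...) {
  type <- match.arg(type)
  if (type == "area") object$profile$A - object$R
  else 2 * sqrt(object$profile$A / pi) -
    (object$coef[[1L]] + object$coef[[2L]] * object$s)
}

#' Evaluate the reference area at new arc-length positions
#'
#' @param object a [fit_reference] result.
#' @param newdata optional numeric vector of arc lengths (mm); defaults to
#'   the fitted grid.
#' @param ... unused.
#' @return reference areas (mm^2).
#' @export
predict.reference_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$R)
  d <- object$coef[[1L]] + object$coef[[2L]] * as.numeric(newdata)
  pi * (d / 2)^2
}

#' @export
plot.reference_fit <- function(x, ...) {
  graphics::plot(x$s, x$profile$A, type = "l", xlab = "arc length s (mm)",
                 ylab = expression(paste("lumen area (", mm^2, ")")),
                 main = x$profile$vessel_id, ...)
  graphics::lines(x$s, x$R, lty = 2, col = "red3")
  graphics::legend("bottomleft", c("measured", "reference"),
                   lty = c(1, 2), col = c("black", "red3"), bty = "n")
  invisible(x)
}
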
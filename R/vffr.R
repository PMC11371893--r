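#' Construct a vFFR pullback profile
#'
#' Holds the angiography-derived pressure ratio (vessel fractional flow
#' reserve) sampled along the same arc-length axis as the vessel's area
#' profile. This package never computes pressure physics: vFFR profiles
#' are inputs (real data) or surrogates built by the synthetic generator.
#'
#' @param s arc length grid (mm), strictly increasing.
#' @param v pressure ratio values in (0, 1]; the proximal value is expected
#'   within 0.02 of 1.0 (normalization check, warning otherwise).
#' @param vessel_id identifier.
#' @return object of class `vffr_profile` (list `s`, `v`, `vessel_id`).
#' @export
vffr_profile <- function(s, v, vessel_id = "vessel") {
  s <- as.numeric(s); v <- as.numeric(v)
  if (length(s) == 0L || length(s) != length(v))
    stop("invalid input: s and v must be non-empty and of equal length")
  if (any(diff(s) <= 0)) stop("invalid input: s must be strictly increasing")
  if (anyNA(v) || any(v <= 0) || any(v > 1))
    stop("invalid input: vFFR values must lie in (0, 1]")
  if (abs(v[1L] - 1) > 0.02)
    warning(sprintf("vessel '%s': proximal vFFR %.3f deviates from 1.0 by more than 0.02",
                    vessel_id, v[1L]))
  structure(list(s = s, v = v, vessel_id = as.character(vessel_id)),
            class = "vffr_profile")
}

#' @export
print.vffr_profile <- function(x, ...) {
  cat(sprintf("vFFR pullback '%s': %d samples, %.3f -> %.3f\n",
              x$vessel_id, length(x$s), x$v[1L], x$v[length(x$v)]))
  invisible(x)
}

# linear interpolation of the pullback at arbitrary arc lengths
.vffr_at <- function(profile, s) {
  if (any(s < profile$s[1L] - 1e-9) || any(s > profile$s[length(profile$s)] + 1e-9))
    stop("alignment error: requested position outside the vFFR profile range")
  stats::approx(profile$s, profile$v, xout = s, rule = 2L)$y
}

#' Translesional vFFR gradient
#'
#' The difference between the vFFR value at the proximal lesion edge and
#' the vFFR value at the distal lesion edge, both evaluated by linear
#' interpolation of the pullback at the detected edge arc lengths.
#' For noisy, non-monotone pullbacks the difference can be negative; it is
#' reported as-is with a warning.
#'
#' @param profile a [vffr_profile].
#' @param segment a `lesion_segment` from [detect_lesion] (any list with
#'   `s_prox` and `s_dist` works).
#' @return dimensionless pressure-ratio drop across the lesion.
#' @export
delta_vffr <- function(profile, segment) {
  stopifnot(inherits(profile, "vffr_profile"))
  dv <- .vffr_at(profile, segment$s_prox) - .vffr_at(profile, segment$s_dist)
  if (dv < -1e-12)
    warning(sprintf("vessel '%s': negative translesional gradient %.4g (non-monotone pullback); reported as-is",
                    profile$vessel_id, dv))
  dv
}

#' Distal vFFR
#'
#' The vFFR evaluated at the distal segment of the vessel, implemented as
#' the last sample of the pullback.
#'
#' @param profile a [vffr_profile].
#' @return dimensionless pressure ratio at the distal vessel end.
#' @export
distal_vffr <- function(profile) {
  stopifnot(inherits(profile, "vffr_profile"))
  profile$v[length(profile$v)]
}
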
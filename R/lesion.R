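#' Detect the lesion segment on a measured-vs-reference area pair
#'
#' The lesion is the below-reference run containing the global minimum
#' lumen area. Its proximal and distal edges are the crossings of the
#' measured area function with the reference line nearest the MLA on each
#' side, localized by linear interpolation between the straddling grid
#' points. Grazing contacts (|A - R| < `tol`) count as crossings.
#'
#' @param profile an [area_profile].
#' @param reference a [fit_reference] result (or any list with `s`, `R`) on
#'   the same grid as `profile`.
#' @param tol crossing tolerance on |A - R| (mm^2).
#' @param all_lesions if `TRUE`, return a list of segments, one per
#'   below-reference run with crossings on both sides (exploratory mode).
#' @return a `lesion_segment` (list with `s_prox`, `s_mla`, `s_dist`,
#'   `PROXA`, `MLA`, `DISTA`, `R_mla`, `vessel_id`), `NULL` when the
#'   measured area never drops below the reference, or a list of segments
#'   when `all_lesions = TRUE`. A lesion running off either vessel end
#'   (no crossing on that side) raises an ostial/truncated-lesion error;
#'   such vessels are excluded from analysis.
#' @export
detect_lesion <- function(profile, reference, tol = 1e-9, all_lesions = FALSE) {
  stopifnot(inherits(profile, "area_profile"))
  s <- profile$s; A <- profile$A; R <- reference$R
  if (length(R) != length(A) || max(abs(reference$s - s)) > 1e-9)
    stop("profile and reference must share one grid")
  diffAR <- A - R
  below <- diffAR < -tol
  if (!any(below)) return(NULL)
  if (all_lesions) {
    runs <- rle(below)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    idx <- which(runs$values)
    out <- lapply(idx, function(k)
      .edge_localize(s, A, R, diffAR, starts[k]:ends[k], tol,
                     profile$vessel_id))
    return(out[!vapply(out, is.null, logical(1))])
  }
  # run containing the global minimum of A among below-reference samples;
  # ties broken toward the most proximal grid point
  bidx <- which(below)
  mla_idx <- bidx[which.min(A[bidx])]
  run_lo <- mla_idx
  while (run_lo > 1L && below[run_lo - 1L]) run_lo <- run_lo - 1L
  run_hi <- mla_idx
  nn <- length(s)
  while (run_hi < nn && below[run_hi + 1L]) run_hi <- run_hi + 1L
  .edge_localize(s, A, R, diffAR, run_lo:run_hi, tol, profile$vessel_id,
                 error_on_truncation = TRUE)
}

# localize the two edges of one below-reference run; returns lesion_segment
.edge_localize <- function(s, A, R, diffAR, run, tol, vessel_id,
                           error_on_truncation = FALSE) {
  run_lo <- run[1L]; run_hi <- run[length(run)]
  mla_rel <- which.min(A[run])  # which.min takes the first (most proximal) tie
  mla_idx <- run[mla_rel]
  n <- length(s)
  truncated <- function(side) {
    msg <- sprintf("ostial/truncated lesion in vessel '%s': no %s reference crossing (lesion reaches the vessel %s end); vessel excluded",
                   vessel_id, side, side)
    if (error_on_truncation) stop(msg) else NULL
  }
  if (run_lo == 1L) return(truncated("proximal"))
  if (run_hi == n) return(truncated("distal"))
  interp_at <- function(i, sc, y) {
    # y interpolated inside [s_i, s_{i+1}]
    t <- (sc - s[i]) / (s[i + 1L] - s[i])
    y[i] + t * (y[i + 1L] - y[i])
  }
  cross <- function(i, side) {
    # crossing of A - R inside [s_i, s_{i+1}]: the outside point straddles
    # >= -tol, the inside point < -tol. A genuine sign change is localized
    # by linear interpolation. When the outside point merely grazes the
    # reference (|A - R| <= tol, e.g. an exactly conical healthy wall), the
    # interpolation is degenerate; the crossing is then extrapolated from
    # the locally linear lesion wall (the two nearest inside points),
    # clamped to the straddling interval.
    d0 <- diffAR[i]; d1 <- diffAR[i + 1L]
    if (side == "dist") { d0 <- diffAR[i + 1L]; d1 <- diffAR[i] }
    if (abs(d0) > tol) {
      t <- d0 / (d0 - d1)
      sc <- if (side == "prox") s[i] + t * (s[i + 1L] - s[i])
            else s[i + 1L] - t * (s[i + 1L] - s[i])
      return(c(sc, interp_at(i, sc, A)))
    }
    j1 <- if (side == "prox") i + 1L else i          # nearest inside point
    j2 <- if (side == "prox") i + 2L else i - 1L     # next inside point
    sc <- NA_real_
    if (j2 >= run_lo && j2 <= run_hi && diffAR[j2] < diffAR[j1] - tol) {
      slope <- (diffAR[j2] - diffAR[j1]) / (s[j2] - s[j1])
      sc <- s[j1] - diffAR[j1] / slope
    }
    lo <- s[i]; hi <- s[i + 1L]
    if (!is.finite(sc) || sc < lo || sc > hi)
      sc <- if (side == "prox") lo else hi  # fall back to the grazing point
    # A = R at the crossing by definition; the reference interpolation is
    # the accurate edge-area read here (the measured-area chord spans the
    # steep lesion wall and undershoots badly off the interpolated zero)
    c(sc, interp_at(i, sc, R))
  }
  pr <- cross(run_lo - 1L, "prox")
  di <- cross(run_hi, "dist")
  seg <- list(s_prox = pr[1L], s_mla = s[mla_idx], s_dist = di[1L],
              PROXA = pr[2L], MLA = A[mla_idx], DISTA = di[2L],
              R_mla = R[mla_idx], vessel_id = vessel_id)
  class(seg) <- "lesion_segment"
  seg
}

#' @export
print.lesion_segment <- function(x, ...) {
  cat(sprintf(
    "Lesion [%s]: edges %.2f-%.2f mm, MLA %.3f mm^2 at %.2f mm (PROXA %.3f, DISTA %.3f)\n",
    x$vessel_id, x$s_prox, x$s_dist, x$MLA, x$s_mla, x$PROXA, x$DISTA))
  invisible(x)
}

#' Scalar lesion metrics from a detected segment
#'
#' Computes the minimum lumen ratio MLR = MLA/PROXA and the companion
#' descriptors: lesion segment length LSL = s_dist - s_prox, proximal
#' lesion segment length PLSL = s_mla - s_prox, lesion length ratio
#' LLR = PLSL/LSL, and percent area stenosis
#' \%AS = (1 - MLA/R(s_mla)) * 100 with R the reference area at the MLA
#' section.
#'
#' @param segment a `lesion_segment` from [detect_lesion].
#' @return a `lesion_metrics` list: `MLR`, `LSL`, `PLSL`, `LLR`,
#'   `pct_area_stenosis`, plus the segment fields.
#' @export
lesion_metrics <- function(segment) {
  stopifnot(inherits(segment, "lesion_segment"))
  LSL <- segment$s_dist - segment$s_prox
  if (segment$PROXA <= 0 || LSL <= 0)
    stop("invalid segment: PROXA and LSL must be positive")
  m <- list(MLR = segment$MLA / segment$PROXA,
            LSL = LSL,
            PLSL = segment$s_mla - segment$s_prox,
            LLR = (segment$s_mla - segment$s_prox) / LSL,
            pct_area_stenosis = (1 - segment$MLA / segment$R_mla) * 100,
            segment = segment)
  class(m) <- "lesion_metrics"
  m
}

#' Quantify one vessel: resample, fit reference, detect, measure
#'
#' The central fitting function of the package. The raw area profile is
#' resampled to a uniform grid, the interpolated reference line is fitted
#' by iteratively trimmed regression in the equivalent-diameter domain
#' ([fit_reference]), the lesion segment is located at the measured/
#' reference crossings ([detect_lesion]) and all scalar descriptors are
#' computed ([lesion_metrics]). If a vFFR pullback is supplied, the distal
#' vFFR and translesional gradient are evaluated at the detected edges.
#'
#' @param profile an [area_profile] (raw; any grid).
#' @param vffr optional [vffr_profile] of the same vessel.
#' @param step resampling step (mm).
#' @param min_healthy_frac,trim_k passed to [fit_reference].
#' @return an object of class `mlr_fit` bundling the resampled profile, the
#'   `reference_fit`, the `lesion_segment` (or `NULL` when the vessel is
#'   lesion-free), the `lesion_metrics`, and — when `vffr` is given — the
#'   `vffr_distal` and `delta_vffr` values. `NULL` segment/metrics mean
#'   "no lesion".
#' @examples
#' s <- seq(0, 30, by = 0.1)
#' A <- 7 - 0.05 * s - 3 * exp(-((s - 15) / 3)^2)
#' fit <- quantify_vessel(area_profile(s, A, "example"))
#' coef(fit)
#' @export
quantify_vessel <- function(profile, vffr = NULL, step = 0.1,
                            min_healthy_frac = 0.25, trim_k = 2) {
  stopifnot(inherits(profile, "area_profile"))
  rs <- resample_profile(profile, step = step)
  ref <- withCallingHandlers(
    fit_reference(rs, min_healthy_frac = min_healthy_frac, trim_k = trim_k),
    error = function(e) stop(sprintf("vessel '%s': %s", profile$vessel_id,
                                     conditionMessage(e)), call. = FALSE))
  seg <- detect_lesion(rs, ref)
  met <- if (!is.null(seg)) lesion_metrics(seg) else NULL
  hemo <- NULL
  if (!is.null(vffr)) {
    hemo <- list(vffr_distal = distal_vffr(vffr),
                 delta_vffr = if (!is.null(seg)) delta_vffr(vffr, seg) else NA_real_)
  }
  structure(list(profile = rs, reference = ref, segment = seg,
                 metrics = met, hemo = hemo, vessel_id = profile$vessel_id),
            class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, ...) {
  if (is.null(x$segment)) {
    cat(sprintf("Vessel '%s': no lesion (measured area never below reference)\n",
                x$vessel_id))
    return(invisible(x))
  }
  m <- x$metrics
  cat(sprintf("Vessel '%s': MLR = %.3f (MLA %.3f / PROXA %.3f mm^2)\n",
              x$vessel_id, m$MLR, x$segment$MLA, x$segment$PROXA))
  cat(sprintf("  edges %.2f-%.2f mm; LSL %.2f, PLSL %.2f mm; LLR %.3f; %%AS %.1f\n",
              x$segment$s_prox, x$segment$s_dist, m$LSL, m$PLSL, m$LLR,
              m$pct_area_stenosis))
  if (!is.null(x$hemo))
    cat(sprintf("  vFFR(distal) %.3f; delta-vFFR %.4f\n",
                x$hemo$vffr_distal, x$hemo$delta_vffr))
  invisible(x)
}

#' @export
summary.mlr_fit <- function(object, ...) {
  print(object$reference)
  print(object)
  invisible(object)
}

#' Scalar lesion descriptors of a fitted vessel
#'
#' @param object an [quantify_vessel] fit.
#' @param ... unused.
#' @return named numeric vector (NA-filled for lesion-free vessels):
#'   MLR, MLA, PROXA, DISTA, LSL, PLSL, LLR, pct_area_stenosis, s_prox,
#'   s_mla, s_dist, and when a vFFR pullback was supplied, vffr_distal and
#'   delta_vffr.
#' @export
coef.mlr_fit <- function(object, ...) {
  if (is.null(object$segment)) {
    out <- rep(NA_real_, 11L)
  } else {
    m <- object$metrics; g <- object$segment
    out <- c(m$MLR, g$MLA, g$PROXA, g$DISTA, m$LSL, m$PLSL, m$LLR,
             m$pct_area_stenosis, g$s_prox, g$s_mla, g$s_dist)
  }
  names(out) <- c("MLR", "MLA", "PROXA", "DISTA", "LSL", "PLSL", "LLR",
                  "pct_area_stenosis", "s_prox", "s_mla", "s_dist")
  if (!is.null(object$hemo))
    out <- c(out, vffr_distal = object$hemo$vffr_distal,
             delta_vffr = object$hemo$delta_vffr)
  out
}

#' @export
residuals.mlr_fit <- function(object, ...) residuals(object$reference, ...)

#' @export
predict.mlr_fit <- function(object, newdata = NULL, ...)
  predict(object$reference, newdata = newdata, ...)

#' @export
plot.mlr_fit <- function(x, ...) {
  plot(x$reference, ...)
  if (!is.null(x$segment)) {
    g <- x$segment
    graphics::abline(v = c(g$s_prox, g$s_dist), col = "grey60", lty = 3)
    graphics::points(g$s_mla, g$MLA, pch = 19, col = "red3")
    graphics::mtext(sprintf("MLR = %.3f", x$metrics$MLR), side = 3, line = 0,
                    adj = 1, cex = 0.9)
  }
  invisible(x)
}

#' Quantify a set of vessels into a lesion table
#'
#' @param profiles list of [area_profile]s.
#' @param vffr optional named list of [vffr_profile]s, joined by vessel id.
#' @param step resampling step (mm).
#' @param on_error `"warn"` (skip the vessel with a warning) or `"stop"`.
#' @return data.frame with one row per vessel that carries a detected
#'   lesion: vessel_id, s_prox_mm, s_mla_mm, s_dist_mm, PROXA_mm2, MLA_mm2,
#'   DISTA_mm2, MLR, LSL_mm, PLSL_mm, LLR, pct_area_stenosis (+ vffr,
#'   delta_vffr when pullbacks are supplied). Lesion-free vessels are
#'   reported via a warning and omitted.
#' @export
quantify_cohort <- function(profiles, vffr = NULL, step = 0.1,
                            on_error = c("warn", "stop")) {
  on_error <- match.arg(on_error)
  rows <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    v <- if (!is.null(vffr)) vffr[[p$vessel_id]] else NULL
    fit <- tryCatch(quantify_vessel(p, vffr = v, step = step),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      if (on_error == "stop") stop(fit)
      warning(conditionMessage(fit), call. = FALSE)
      next
    }
    if (is.null(fit$segment)) {
      warning(sprintf("vessel '%s': no lesion detected", p$vessel_id),
              call. = FALSE)
      next
    }
    cf <- coef(fit)
    rows[[i]] <- data.frame(
      vessel_id = p$vessel_id, s_prox_mm = cf[["s_prox"]],
      s_mla_mm = cf[["s_mla"]], s_dist_mm = cf[["s_dist"]],
      PROXA_mm2 = cf[["PROXA"]], MLA_mm2 = cf[["MLA"]],
      DISTA_mm2 = cf[["DISTA"]], MLR = cf[["MLR"]], LSL_mm = cf[["LSL"]],
      PLSL_mm = cf[["PLSL"]], LLR = cf[["LLR"]],
      pct_area_stenosis = cf[["pct_area_stenosis"]],
      vffr = if ("vffr_distal" %in% names(cf)) cf[["vffr_distal"]] else NA_real_,
      delta_vffr = if ("delta_vffr" %in% names(cf)) cf[["delta_vffr"]] else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
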
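#' Cumulative arc length of a 3D polyline
#'
#' Computes the cumulative arc length along an ordered sequence of 3D
#' centerline points, measured from the first (proximal) point.
#'
#' @param points numeric matrix with one row per point and 3 columns
#'   (x, y, z coordinates in mm), or an object coercible to such a matrix.
#' @return numeric vector of cumulative arc lengths (mm); first element 0,
#'   last element the total polyline length.
#' @examples
#' arc_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 0, 5
#' @export
arc_length <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L)
    stop("invalid geometry: 'points' must be an n x 3 numeric matrix")
  n <- nrow(points)
  if (n < 2L)
    stop("invalid geometry: need at least 2 centerline points")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  if (any(seg == 0))
    stop("invalid geometry: duplicated consecutive centerline points")
  c(0, cumsum(seg))
}

#' Area of a planar cross-section polygon
#'
#' Shoelace area of an ordered planar polygon (implicitly closed).
#' Orientation-independent: the absolute value of the signed area.
#'
#' @param vertices numeric matrix, one row per vertex, 2 columns (mm).
#' @return polygon area (mm^2).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("invalid geometry: polygon needs >= 3 planar vertices")
  x <- vertices[, 1L]; y <- vertices[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Construct a lumen area profile
#'
#' An `area_profile` holds the lumen cross-sectional area of one vessel as
#' a function of centerline arc length, ordered proximal (s = 0) to distal.
#'
#' @param s arc length grid (mm), strictly increasing, starting at 0
#'   (a profile not starting at 0 is shifted and a warning raised only if
#'   `shift = FALSE`; by default the origin is moved to the first sample).
#' @param A lumen cross-sectional area at each `s` (mm^2), all positive.
#' @param vessel_id identifier string.
#' @param shift logical; move the arc-length origin to the first sample.
#' @return object of class `area_profile`: a list with elements `s`, `A`,
#'   `vessel_id`.
#' @export
area_profile <- function(s, A, vessel_id = "vessel", shift = TRUE) {
  s <- as.numeric(s); A <- as.numeric(A)
  if (length(s) != length(A) || length(s) < 4L)
    stop("invalid profile: s and A must have equal length >= 4")
  if (anyNA(s) || anyNA(A))
    stop("invalid profile: NA values")
  if (any(diff(s) <= 0))
    stop("invalid profile: s must be strictly increasing")
  if (any(A <= 0))
    stop("invalid profile: all areas must be positive")
  if (s[1L] != 0) {
    if (shift) s <- s - s[1L]
    else stop("invalid profile: s must start at 0")
  }
  structure(list(s = s, A = A, vessel_id = as.character(vessel_id)),
            class = "area_profile")
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("Lumen area profile '%s': %d samples over %.2f mm, area %.2f-%.2f mm^2\n",
              x$vessel_id, length(x$s), x$s[length(x$s)], min(x$A), max(x$A)))
  invisible(x)
}

#' Build an area profile from cross-section contours
#'
#' Converts a list of planar contour polygons sampled along the centerline
#' into an [area_profile] via [polygon_area].
#'
#' @param sections list of sections; each a list with `s_position` (mm) and
#'   `vertices` (n x 2 matrix, mm).
#' @param vessel_id identifier.
#' @return an [area_profile].
#' @export
profile_from_sections <- function(sections, vessel_id = "vessel") {
  s <- vapply(sections, function(x) as.numeric(x$s_position), numeric(1))
  A <- vapply(sections, function(x) polygon_area(x$vertices), numeric(1))
  o <- order(s)
  area_profile(s[o], A[o], vessel_id = vessel_id)
}

#' Resample an area profile onto a uniform grid
#'
#' Monotone-preserving (piecewise-linear) interpolation onto a uniform grid
#' of spacing `step`; the last interval may be shorter so that both
#' endpoints are preserved exactly. The uniform grid is augmented with the
#' original sample locations, so extrema of piecewise-linear data (in
#' particular the minimum lumen area) survive resampling exactly. A profile
#' already on the requested grid is returned unchanged; resampling is
#' idempotent at a fixed step.
#'
#' @param profile an [area_profile].
#' @param step grid spacing (mm), positive and smaller than the profile span.
#' @return an [area_profile] on the uniform grid.
#' @export
resample_profile <- function(profile, step = 0.1) {
  stopifnot(inherits(profile, "area_profile"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("parameter error: 'step' must be a positive number")
  total <- profile$s[length(profile$s)]
  if (step >= total)
    stop("parameter error: 'step' must be smaller than the profile span")
  d <- diff(profile$s)
  if (max(abs(d[-length(d)] - step)) < 1e-12 && d[length(d)] <= step + 1e-12)
    return(profile)
  grid <- seq(0, total, by = step)
  if (grid[length(grid)] < total - 1e-12) grid <- c(grid, total)
  else grid[length(grid)] <- total
  grid <- sort(unique(c(grid, profile$s)))
  # drop near-duplicate knots (within 1e-9) introduced by the union
  n <- length(grid)
  keep <- c(TRUE, diff(grid) > 1e-9)
  keep[n] <- TRUE
  if (n > 1L && grid[n] - grid[n - 1L] <= 1e-9) keep[n - 1L] <- FALSE
  grid <- grid[keep]
  A <- stats::approx(profile$s, profile$A, xout = grid, rule = 1L)$y
  area_profile(grid, A, vessel_id = profile$vessel_id)
}
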
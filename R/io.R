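#' Read vessel geometry from JSON or CSV
#'
#' JSON dialects: `{vessel_id, points: [[x,y,z],...], areas: [...]}` (3D
#' centerline with per-point areas; arc length computed by [arc_length])
#' or `{vessel_id, sections: [{s, vertices: [[x,y],...]}, ...]}` (contour
#' polygons converted via [polygon_area]). CSV dialect: columns
#' `vessel_id, s_mm, area_mm2`, one or more vessels per file, rows ordered
#' proximal to distal. Lengths mm, areas mm^2.
#'
#' @param path file path (.json or .csv).
#' @return a list of [area_profile]s (one per vessel).
#' @export
read_vessel_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    vid <- if (!is.null(j$vessel_id)) j$vessel_id else "vessel"
    if (!is.null(j$points)) {
      pts <- as.matrix(j$points)
      if (is.null(j$areas))
        stop(sprintf("schema error in %s: 'points' without 'areas'", path))
      s <- arc_length(pts)
      return(list(area_profile(s, as.numeric(j$areas), vessel_id = vid)))
    }
    if (!is.null(j$sections)) {
      secs <- j$sections
      if (is.data.frame(secs))
        secs <- lapply(seq_len(nrow(secs)), function(i)
          list(s_position = secs$s[i], vertices = secs$vertices[[i]]))
      else
        secs <- lapply(secs, function(x)
          list(s_position = x$s, vertices = as.matrix(x$vertices)))
      return(list(profile_from_sections(secs, vessel_id = vid)))
    }
    stop(sprintf("schema error in %s: need 'points'+'areas' or 'sections'", path))
  }
  if (ext == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("vessel_id", "s_mm", "area_mm2")
    miss <- setdiff(need, names(d))
    if (length(miss) > 0L)
      stop(sprintf("schema error in %s: missing column(s) %s", path,
                   paste(miss, collapse = ", ")))
    out <- lapply(split(seq_len(nrow(d)), d$vessel_id), function(ix) {
      s <- d$s_mm[ix]
      bad <- which(diff(s) <= 0)
      if (length(bad) > 0L)
        stop(sprintf("schema error in %s: non-monotone s_mm at row %d (vessel %s)",
                     path, ix[bad[1L] + 1L], d$vessel_id[ix[1L]]))
      area_profile(s, d$area_mm2[ix], vessel_id = d$vessel_id[ix[1L]])
    })
    return(unname(out))
  }
  stop("unsupported geometry format: ", path)
}

#' Read vFFR pullbacks from CSV
#'
#' Columns: `vessel_id, s_mm, vffr`. Joined to geometry by vessel id.
#'
#' @param path CSV path.
#' @return named list of [vffr_profile]s keyed by vessel id.
#' @export
read_vffr_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("vessel_id", "s_mm", "vffr"), names(d))
  if (length(miss) > 0L)
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  out <- lapply(split(seq_len(nrow(d)), d$vessel_id), function(ix)
    vffr_profile(d$s_mm[ix], d$vffr[ix], vessel_id = d$vessel_id[ix[1L]]))
  out
}

#' Write one vessel's geometry as JSON
#'
#' Emits the `points`+`areas` dialect on a straight synthetic centerline
#' along z (spacing = the grid spacing) when the profile has no stored
#' centerline.
#'
#' @param profile an [area_profile].
#' @param path output path.
#' @export
write_vessel_geometry <- function(profile, path) {
  pts <- cbind(0, 0, profile$s)
  jsonlite::write_json(
    list(vessel_id = profile$vessel_id, points = pts, areas = profile$A),
    path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' Write a cohort table (and optionally its vessel files)
#'
#' Writes `cohort.csv`, echoes the generator config as `config.yaml`, and
#' when profiles are supplied writes one geometry JSON and one vFFR CSV
#' per vessel under `vessels/`. Floating-point output at 6 significant
#' digits for stable diffs.
#'
#' @param cohort an `mlr_cohort` (or compatible data.frame).
#' @param dir output directory (created if needed).
#' @param profiles,vffrs optional lists of per-vessel profiles.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, profiles = NULL, vffrs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- as.data.frame(cohort)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  utils::write.csv(out, file.path(dir, "cohort.csv"), row.names = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    c2 <- unclass(cfg)
    c2$supports <- lapply(c2$supports, function(b)
      ifelse(is.finite(b), b, sign(b) * .Machine$double.xmax))  # yaml has no Inf literal
    yaml::write_yaml(c2, file.path(dir, "config.yaml"))
  }
  if (!is.null(profiles)) {
    vd <- file.path(dir, "vessels")
    dir.create(vd, showWarnings = FALSE)
    for (p in profiles)
      if (!is.null(p)) write_vessel_geometry(p, file.path(vd, paste0(p$vessel_id, ".json")))
    for (v in vffrs)
      if (!is.null(v)) {
        d <- data.frame(vessel_id = v$vessel_id, s_mm = signif(v$s, 6L),
                        vffr = signif(v$v, 6L))
        utils::write.csv(d, file.path(vd, paste0(v$vessel_id, "_vffr.csv")),
                         row.names = FALSE)
      }
  }
  invisible(dir)
}

#' Read a cohort table written by [write_cohort]
#'
#' @param path path to `cohort.csv`.
#' @return data.frame of class `mlr_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "patient_id", "group", "time_months", "event", "MLR")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  class(d) <- c("mlr_cohort", "data.frame")
  d
}

# strip non-serializable members for the JSON report
.report_payload <- function(analysis) {
  roc <- lapply(analysis$roc, function(ep) lapply(ep, function(r)
    r[c("metric", "orientation", "auc", "var", "ci", "p", "n_event",
        "n_control")]))
  surv <- lapply(analysis$survival, function(s)
    s[c("metric", "threshold", "hr", "ci", "p_wald", "p_logrank", "n",
        "events", "km")])
  cuts <- lapply(analysis$cutoffs, function(cc) unclass(cc))
  list(cohort_summary = analysis$cohort_summary,
       comparisons = analysis$comparisons,
       correlations = analysis$correlations, roc = roc, cutoffs = cuts,
       survival = surv, errors = analysis$errors)
}

#' Write an analysis report as machine-readable JSON
#'
#' @param analysis an [run_full_analysis] result.
#' @param path output path.
#' @export
write_report_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "mlr_analysis"))
  jsonlite::write_json(.report_payload(analysis), path, auto_unbox = TRUE,
                       digits = 6, na = "null", pretty = TRUE)
  invisible(path)
}
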
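#' Mann-Whitney group comparisons with Bonferroni adjustment
#'
#' Compares each metric between the FCL and NCL groups with a two-sided
#' Mann-Whitney U test: exact enumeration when the combined sample is
#' small (< 16) and tie-free, normal approximation with tie correction
#' otherwise. P-values are Bonferroni-adjusted over the metric list
#' (p_adj = min(1, m * p)).
#'
#' @param cohort data.frame with a `group` column (`"FCL"`/`"NCL"`) and the
#'   metric columns.
#' @param metrics character vector of metric column names.
#' @param m number of tests for the Bonferroni correction (default: the
#'   number of metrics).
#' @return data.frame: metric, per-group median and quartiles, U, p_raw,
#'   p_adjusted.
#' @export
compare_groups <- function(cohort, metrics, m = length(metrics)) {
  miss <- setdiff(c("group", metrics), names(cohort))
  if (length(miss) > 0L)
    stop("schema error: missing columns: ", paste(miss, collapse = ", "))
  rows <- lapply(metrics, function(met) {
    x <- cohort[[met]][cohort$group == "FCL"]
    y <- cohort[[met]][cohort$group == "NCL"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L)
      stop(sprintf("analysis error: empty group for metric '%s'", met))
    use_exact <- (length(x) + length(y)) < 16L && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                              correct = TRUE))
    qx <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    qy <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(metric = met, fcl_median = qx[2L], fcl_q25 = qx[1L],
               fcl_q75 = qx[3L], ncl_median = qy[2L], ncl_q25 = qy[1L],
               ncl_q75 = qy[3L], U = unname(wt$statistic),
               p_raw = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out
}

#' Spearman rank correlations for metric pairs
#'
#' Midrank-tie Spearman correlation with t-approximation p-values.
#'
#' @param cohort data.frame holding the metric columns.
#' @param pairs list of length-2 character vectors naming column pairs.
#' @return data.frame: var1, var2, rho, p, n.
#' @export
spearman_corr <- function(cohort, pairs) {
  rows <- lapply(pairs, function(pr) {
    x <- cohort[[pr[1L]]]; y <- cohort[[pr[2L]]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4L)
      stop("analysis error: need >= 4 paired observations for Spearman correlation")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop(sprintf("analysis error: correlation of constant column undefined (%s, %s)",
                   pr[1L], pr[2L]))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(var1 = pr[1L], var2 = pr[2L], rho = unname(ct$estimate),
               p = ct$p.value, n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ROC curve with AUC and DeLong inference
#'
#' AUC by Mann-Whitney pair counting (ties credited 0.5), with the DeLong
#' structural-components variance, a Wald 95% confidence interval clipped
#' to the unit interval and a two-sided p-value against AUC = 0.5. The score
#' orientation is declared, never auto-flipped: `"low"` means low values
#' predict the event (so the AUC is the probability that an event vessel
#' scores below a non-event vessel).
#'
#' @param labels event indicator (0/1 or logical), 1 = event (FCL).
#' @param scores numeric metric values.
#' @param orientation `"low"` or `"high"`: which tail predicts the event.
#' @param metric metric name carried into the result.
#' @param conf_level confidence level for the Wald interval.
#' @return object of class `roc_result`: metric, orientation, auc, var,
#'   ci (lo, hi), p, n_event, n_control, and the underlying `pROC::roc`
#'   object (`roc`).
#' @export
roc_delong <- function(labels, scores, orientation = c("low", "high"),
                       metric = "score", conf_level = 0.95) {
  orientation <- match.arg(orientation)
  labels <- as.integer(as.logical(labels))
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]; scores <- scores[ok]
  if (length(unique(labels)) < 2L)
    stop("analysis error: both classes must be present for ROC analysis")
  direction <- if (orientation == "low") ">" else "<"
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = direction, quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  v <- as.numeric(pROC::var(r, method = "delong"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (v > 0) {
    ci <- c(max(0, auc - z * sqrt(v)), min(1, auc + z * sqrt(v)))
    p <- 2 * stats::pnorm(-abs(auc - 0.5) / sqrt(v))
  } else {
    ci <- c(auc, auc)
    p <- if (abs(auc - 0.5) < 1e-12) 1 else 0
  }
  structure(list(metric = metric, orientation = orientation, auc = auc,
                 var = v, ci = ci, p = p, n_event = sum(labels == 1L),
                 n_control = sum(labels == 0L), roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s, %s values predict events): AUC = %.3f (95%% CI %.3f-%.3f), p = %.3g [%d events / %d controls]\n",
              x$metric, x$orientation, x$auc, x$ci[1L], x$ci[2L], x$p,
              x$n_event, x$n_control))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$roc, main = sprintf("%s: AUC %.3f", x$metric, x$auc), ...)
  invisible(x)
}

#' Optimal dichotomization threshold by Youden's J
#'
#' Scans the midpoints between consecutive distinct score values and
#' returns the threshold maximizing J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity.
#'
#' @inheritParams roc_delong
#' @return object of class `cutoff_result`: threshold, sensitivity,
#'   specificity, J.
#' @export
youden_cutoff <- function(labels, scores, orientation = c("low", "high"),
                          metric = "score") {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]; scores <- scores[ok]
  if (!any(labels) || all(labels))
    stop("analysis error: both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2L)
    stop("analysis error: degenerate scores (a single distinct value)")
  thr <- (u[-1L] + u[-length(u)]) / 2
  ev <- scores[labels]; ct <- scores[!labels]
  best <- NULL
  for (t in thr) {
    pred_ev <- if (orientation == "low") ev < t else ev > t
    pred_ct <- if (orientation == "low") ct < t else ct > t
    sens <- mean(pred_ev); spec <- mean(!pred_ct)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && spec > best$specificity + 1e-12))
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   J = J)
  }
  structure(c(list(metric = metric, orientation = orientation), best),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Youden cutoff (%s): threshold %.4g, sens %.3f, spec %.3f, J = %.3f\n",
              x$metric, x$threshold, x$sensitivity, x$specificity, x$J))
  invisible(x)
}

#' Kaplan-Meier curves and hazard ratio for a dichotomized metric
#'
#' Strata are `metric < threshold` ("low", strict) versus
#' `metric >= threshold` ("high"). Product-limit Kaplan-Meier curves are
#' estimated per stratum; the hazard ratio (low vs high) comes from a
#' single-covariate Cox proportional-hazards fit with Efron tie handling,
#' with a Wald confidence interval from the coefficient standard error; a
#' log-rank p-value is reported alongside.
#'
#' @param cohort data.frame with `time_months`, `event` and the metric
#'   column.
#' @param threshold dichotomization threshold.
#' @param metric metric column name (default `"MLR"`).
#' @param conf_level Wald CI level.
#' @return object of class `survival_result`: `km` (list of per-stratum
#'   data.frames time/surv/n_risk), `hr`, `ci`, `p_logrank`, `p_wald`,
#'   `threshold`, `metric`, `n` and the fitted `coxph`/`survfit` objects.
#' @export
km_hazard <- function(cohort, threshold, metric = "MLR", conf_level = 0.95) {
  miss <- setdiff(c("time_months", "event", metric), names(cohort))
  if (length(miss) > 0L)
    stop("schema error: missing columns: ", paste(miss, collapse = ", "))
  d <- cohort[!is.na(cohort[[metric]]), , drop = FALSE]
  if (any(d$time_months <= 0)) stop("analysis error: times must be positive")
  low <- d[[metric]] < threshold
  if (!any(low) || all(low))
    stop(sprintf("analysis error: empty stratum at %s < %.4g", metric, threshold))
  if (sum(d$event) == 0L)
    stop("analysis error: no events; hazard ratio undefined")
  sv <- survival::Surv(d$time_months, d$event)
  grp <- factor(ifelse(low, "low", "high"), levels = c("high", "low"))
  fit_km <- survival::survfit(sv ~ grp)
  cx <- survival::coxph(sv ~ grp, ties = "efron")
  beta <- unname(stats::coef(cx)[1L])
  se <- sqrt(unname(diag(cx$var))[1L])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  sd <- survival::survdiff(sv ~ grp)
  p_logrank <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  strata_names <- sub("^grp=", "", names(fit_km$strata))
  idx <- rep(seq_along(fit_km$strata), fit_km$strata)
  km <- lapply(seq_along(fit_km$strata), function(k) {
    sel <- idx == k
    data.frame(time = fit_km$time[sel], surv = fit_km$surv[sel],
               n_risk = fit_km$n.risk[sel])
  })
  names(km) <- strata_names
  structure(list(metric = metric, threshold = threshold, km = km,
                 hr = exp(beta), ci = exp(c(beta - z * se, beta + z * se)),
                 p_wald = 2 * stats::pnorm(-abs(beta) / se),
                 p_logrank = p_logrank,
                 n = c(low = sum(low), high = sum(!low)),
                 events = c(low = sum(d$event[low]), high = sum(d$event[!low])),
                 coxph = cx, survfit = fit_km),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier / Cox for %s < %.4g (low) vs >= (high):\n",
              x$metric, x$threshold))
  cat(sprintf("  n = %d low / %d high; events %d / %d\n", x$n["low"],
              x$n["high"], x$events["low"], x$events["high"]))
  cat(sprintf("  HR (low vs high) = %.2f (95%% CI %.2f-%.2f), Wald p = %.3g, log-rank p = %.3g\n",
              x$hr, x$ci[1L], x$ci[2L], x$p_wald, x$p_logrank))
  invisible(x)
}

#' @export
plot.survival_result <- function(x, ...) {
  plot(x$survfit, col = c("grey40", "red3"), lwd = 2,
       xlab = "months", ylab = "event-free survival",
       main = sprintf("%s dichotomized at %.3g (HR %.2f)", x$metric,
                      x$threshold, x$hr), ...)
  graphics::legend("bottomleft", legend = names(x$km),
                   col = c("grey40", "red3"), lwd = 2, bty = "n")
  invisible(x)
}

#' Default score orientations for the lesion metrics
#'
#' Which tail of each metric is event-oriented: low for the area-derived
#' and pressure-ratio metrics (smaller lumen / lower distal pressure =
#' higher risk), high for the translesional gradient and the length
#' descriptors.
#'
#' @return named character vector (`"low"`/`"high"`).
#' @export
default_orientations <- function() {
  c(MLR = "low", MLA = "low", PROXA = "low", DISTA = "low", vFFR = "low",
    dvFFR = "high", LSL = "high", PLSL = "high", LLR = "high",
    pct_area_stenosis = "high")
}

#' Run the full statistical analysis of a cohort table
#'
#' Reproduces the complete pipeline: Mann-Whitney/Bonferroni group
#' comparisons over the nine lesion metrics, Spearman correlations of MLR
#' with the two pressure-ratio metrics, per-metric ROC/AUC with DeLong
#' inference for the overall endpoint and (optionally) the STEMI-only and
#' NSTEMI-only endpoints, Youden cutoffs, and Kaplan-Meier / hazard-ratio
#' analysis of the dichotomized metrics.
#'
#' @param cohort cohort table (as produced by [generate_cohort] or read
#'   via [read_cohort]).
#' @param metrics metrics for the group comparison (defaults to the nine
#'   standard descriptors).
#' @param bonferroni_m Bonferroni divisor (defaults to the metric count).
#' @param roc_metrics metrics for ROC/Youden analysis.
#' @param spearman_pairs list of metric pairs for correlation.
#' @param thresholds named numeric vector of dichotomization thresholds
#'   for the survival analysis (default `c(MLR = 0.399)`).
#' @param stratify_mi also run ROC and survival within each MI-type
#'   subset (skipped with a warning when a subset lacks both classes).
#' @param orientations named orientation overrides (see
#'   [default_orientations]).
#' @return object of class `mlr_analysis`: list with `comparisons`,
#'   `correlations`, `roc` (per endpoint per metric), `cutoffs`,
#'   `survival`, `cohort_summary`, `errors` (messages from stages that
#'   failed cleanly).
#' @export
run_full_analysis <- function(cohort,
                              metrics = c("MLR", "MLA", "PROXA", "DISTA",
                                          "LLR", "PLSL", "LSL", "dvFFR",
                                          "vFFR"),
                              bonferroni_m = length(metrics),
                              roc_metrics = c("MLR", "MLA", "PROXA", "LLR",
                                              "PLSL", "LSL", "dvFFR", "vFFR"),
                              spearman_pairs = list(c("MLR", "dvFFR"),
                                                    c("MLR", "vFFR")),
                              thresholds = c(MLR = 0.399),
                              stratify_mi = TRUE,
                              orientations = default_orientations()) {
  required <- c("vessel_id", "group", "event", "time_months")
  miss <- setdiff(required, names(cohort))
  if (length(miss) > 0L)
    stop("schema error: missing columns: ", paste(miss, collapse = ", "))
  errors <- list()
  note <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    warning(sprintf("stage '%s' skipped: %s", stage, conditionMessage(e)),
            call. = FALSE)
    NULL
  }
  cohort_summary <- list(
    n_vessels = nrow(cohort),
    n_patients = length(unique(cohort$patient_id)),
    n_fcl = sum(cohort$group == "FCL"),
    n_ncl = sum(cohort$group == "NCL"),
    n_events = sum(cohort$event),
    median_follow_up = stats::median(cohort$time_months))
  comparisons <- tryCatch(
    compare_groups(cohort, metrics, m = bonferroni_m),
    error = function(e) note("comparisons", e))
  correlations <- tryCatch(spearman_corr(cohort, spearman_pairs),
                           error = function(e) note("correlations", e))
  endpoints <- list(all = cohort)
  if (stratify_mi && "mi_type" %in% names(cohort))
    for (mt in c("STEMI", "NSTEMI"))
      endpoints[[mt]] <- cohort[cohort$mi_type == mt, , drop = FALSE]
  roc <- list()
  for (ep in names(endpoints)) {
    dd <- endpoints[[ep]]
    roc[[ep]] <- list()
    for (met in roc_metrics) {
      res <- tryCatch(
        roc_delong(dd$event, dd[[met]],
                   orientation = orientations[[met]], metric = met),
        error = function(e) note(sprintf("roc/%s/%s", ep, met), e))
      if (!is.null(res)) roc[[ep]][[met]] <- res
    }
  }
  cutoffs <- list()
  for (met in roc_metrics) {
    res <- tryCatch(
      youden_cutoff(cohort$event, cohort[[met]],
                    orientation = orientations[[met]], metric = met),
      error = function(e) note(sprintf("cutoff/%s", met), e))
    if (!is.null(res)) cutoffs[[met]] <- res
  }
  surv <- list()
  for (met in names(thresholds)) {
    for (ep in names(endpoints)) {
      key <- if (ep == "all") met else paste(met, ep, sep = "/")
      res <- tryCatch(
        km_hazard(endpoints[[ep]], thresholds[[met]], metric = met),
        error = function(e) note(sprintf("survival/%s", key), e))
      if (!is.null(res)) surv[[key]] <- res
    }
  }
  structure(list(cohort_summary = cohort_summary, comparisons = comparisons,
                 correlations = correlations, roc = roc, cutoffs = cutoffs,
                 survival = surv, errors = errors),
            class = "mlr_analysis")
}

#' @export
print.mlr_analysis <- function(x, ...) {
  s <- x$cohort_summary
  cat(sprintf("Cohort: %d vessels (%d FCL / %d NCL), %d patients, %d events, median follow-up %.1f months\n\n",
              s$n_vessels, s$n_fcl, s$n_ncl, s$n_patients, s$n_events,
              s$median_follow_up))
  if (!is.null(x$comparisons)) {
    cat("Group comparisons (Mann-Whitney, Bonferroni-adjusted):\n")
    cmp <- x$comparisons
    for (i in seq_len(nrow(cmp)))
      cat(sprintf("  %-6s FCL %.2f (%.2f-%.2f) vs NCL %.2f (%.2f-%.2f), adj p = %.3g\n",
                  cmp$metric[i], cmp$fcl_median[i], cmp$fcl_q25[i],
                  cmp$fcl_q75[i], cmp$ncl_median[i], cmp$ncl_q25[i],
                  cmp$ncl_q75[i], cmp$p_adjusted[i]))
    cat("\n")
  }
  if (!is.null(x$correlations)) {
    cat("Spearman correlations:\n")
    co <- x$correlations
    for (i in seq_len(nrow(co)))
      cat(sprintf("  %s ~ %s: rho = %.2f (p = %.3g, n = %d)\n", co$var1[i],
                  co$var2[i], co$rho[i], co$p[i], co$n[i]))
    cat("\n")
  }
  if (length(x$roc) > 0L && length(x$roc[["all"]]) > 0L) {
    cat("ROC (overall endpoint):\n")
    for (r in x$roc[["all"]]) { cat("  "); print(r) }
    cat("\n")
  }
  for (sv in x$survival) print(sv)
  if (length(x$errors) > 0L)
    cat(sprintf("\n%d stage(s) skipped: %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  invisible(x)
}
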
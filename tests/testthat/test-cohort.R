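test_that("config validation enforces the cohort structure invariants", {
  expect_error(cohort_config(n_patients = 70), "n_fcl == n_patients")
  bad <- cohort_config()
  bad$quantiles$FCL$MLR <- c(0.5, 0.4, 0.6)
  expect_error(validate_cohort_config(bad), "not strictly increasing")
  bad2 <- cohort_config()
  bad2$event_time_quantiles <- c(0.5, 25.9, 29.8)
  expect_error(validate_cohort_config(bad2), "event-time")
})

test_that("metric draws are deterministic and respect marginals per group", {
  cfg <- cohort_config(seed = 9)
  a <- sample_metrics(cfg)
  b <- sample_metrics(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$group == "FCL"), 80L)
  expect_equal(sum(a$group == "NCL"), 108L)
  expect_true(all(a$MLA < a$PROXA))
  expect_true(all(a$PLSL < a$LSL))
  # quartile recovery at n = 1e4 per group. For metrics whose support
  # truncation is immaterial the configured triplets come back directly;
  # dvFFR is checked against the closed-form truncated quartiles (the
  # renormalization over (0, 1) shifts them); LSL/PLSL are additionally
  # conditioned by the PLSL < LSL feasibility resampling, so only a
  # coarser agreement is demanded there.
  trunc_quartiles <- function(q, lo, hi) {
    z75 <- qnorm(0.75)
    s_lo <- (q[2] - q[1]) / z75; s_hi <- (q[3] - q[2]) / z75
    p_raw <- function(x) ifelse(x < q[2], pnorm((x - q[2]) / s_lo),
                                pnorm((x - q[2]) / s_hi))
    q_raw <- function(p) ifelse(p < 0.5, q[2] + s_lo * qnorm(p),
                                q[2] + s_hi * qnorm(p))
    plo <- p_raw(lo); phi <- p_raw(hi)
    q_raw(plo + c(0.25, 0.5, 0.75) * (phi - plo))
  }
  big <- sample_metrics(cfg, n_fcl = 10000L, n_ncl = 10000L, seed = 10)
  for (g in c("FCL", "NCL")) {
    for (met in c("MLR", "MLA", "vFFR")) {
      qq <- unname(quantile(big[[met]][big$group == g], c(0.25, 0.5, 0.75)))
      expect_equal(qq, cfg$quantiles[[g]][[met]], tolerance = 0.02,
                   label = paste(g, met))
    }
    qd <- unname(quantile(big$dvFFR[big$group == g], c(0.25, 0.5, 0.75)))
    expect_equal(qd, trunc_quartiles(cfg$quantiles[[g]]$dvFFR, 0, 1),
                 tolerance = 0.03, label = paste(g, "dvFFR"))
    for (met in c("LSL", "PLSL")) {
      qq <- unname(quantile(big[[met]][big$group == g], c(0.25, 0.5, 0.75)))
      expect_equal(qq, cfg$quantiles[[g]][[met]], tolerance = 0.15,
                   label = paste(g, met, "(feasibility-conditioned)"))
    }
  }
})

test_that("zero dependence targets yield uncorrelated draws", {
  cfg <- cohort_config(spearman_targets = list())
  x <- sample_metrics(cfg, n_fcl = 50000L, n_ncl = 0L, seed = 4)
  expect_lt(abs(cor(x$MLR, x$dvFFR, method = "spearman")), 0.02)
  expect_lt(abs(cor(x$LSL, x$vFFR, method = "spearman")), 0.02)
})

test_that("pooled Spearman dependence matches the published targets", {
  cfg <- cohort_config(seed = 2)
  x <- sample_metrics(cfg, n_fcl = round(1e5 * 80 / 188),
                      n_ncl = round(1e5 * 108 / 188), seed = 2)
  expect_equal(cor(x$MLR, x$dvFFR, method = "spearman"), -0.26,
               tolerance = 0.02 / 0.26)
  expect_equal(cor(x$MLR, x$vFFR, method = "spearman"), 0.15,
               tolerance = 0.02 / 0.15)
})

test_that("constructed vessels round-trip the latent lesion metrics", {
  cfg <- cohort_config(seed = 1)
  rec <- list(MLR = 0.40, PROXA = 6.0, MLA = 2.4, LSL = 14, PLSL = 7,
              dvFFR = 0.08, vFFR = 0.84)
  p <- build_area_profile(rec, cfg, vessel_id = "rt", seed = 5)
  fit <- quantify_vessel(p)
  expect_equal(coef(fit)[["MLR"]], 0.40, tolerance = 0.01 / 0.40)
  expect_equal(coef(fit)[["LSL"]], 14, tolerance = 0.02)
  expect_equal(coef(fit)[["PLSL"]], 7, tolerance = 0.02)
  # noiseless construction is exact to the grid
  cfg0 <- cohort_config(noise_amp = 0)
  p0 <- build_area_profile(rec, cfg0, vessel_id = "rt0", seed = 5)
  expect_equal(coef(quantify_vessel(p0))[["MLR"]], 0.40, tolerance = 1e-3)
  expect_error(build_area_profile(list(MLR = 0.4, PROXA = 6, MLA = 2.4,
                                       LSL = 5, PLSL = 7), cfg),
               "infeasible")
})

test_that("surrogate pullbacks reproduce the latent hemodynamics at the edges", {
  cfg <- cohort_config(seed = 1)
  rec <- list(MLR = 0.40, PROXA = 6.0, MLA = 2.4, LSL = 14, PLSL = 7,
              dvFFR = 0.08, vFFR = 0.84)
  p <- build_area_profile(rec, cfg, vessel_id = "hv", seed = 6)
  fit <- quantify_vessel(p)
  vf <- build_vffr_profile(rec, p)
  expect_equal(distal_vffr(vf), 0.84, tolerance = 1e-6)
  expect_equal(delta_vffr(vf, fit$segment), 0.08, tolerance = 0.005)
  expect_true(all(diff(vf$v) <= 1e-12))
  # zero translesional drop puts the whole decay outside the lesion
  rec0 <- within(rec, dvFFR <- 0)
  vf0 <- build_vffr_profile(rec0, p)
  expect_equal(delta_vffr(vf0, fit$segment), 0, tolerance = 1e-9)
  # no pressure loss at all
  rec1 <- within(rec, vFFR <- 1)
  expect_equal(build_vffr_profile(rec1, p)$v, rep(1, length(p$s)))
  # an infeasible latent gradient is clipped with a warning
  rec2 <- within(rec, dvFFR <- 0.5)
  expect_warning(vf2 <- build_vffr_profile(rec2, p), "clipped")
  expect_equal(delta_vffr(vf2, fit$segment), 1 - 0.84, tolerance = 0.005)
})

test_that("event times hit the configured quartiles and label counts exactly", {
  cfg <- cohort_config(seed = 13)
  et <- sample_event_times(cfg)
  expect_equal(nrow(et), 80L)
  expect_equal(sum(et$mi_type == "NSTEMI"), 52L)  # round(0.65 * 80)
  expect_true(all(et$time_months >= 1 & et$time_months <= 60))
  big <- sample_event_times(cfg, n = 20000L, seed = 14)
  expect_equal(median(big$time_months), 25.9, tolerance = 0.3 / 25.9)
})

test_that("the generated cohort has exact structure and is reproducible", {
  co <- default_cohort()
  expect_equal(nrow(co), 188L)
  expect_equal(sum(co$group == "FCL"), 80L)
  expect_equal(sum(co$event), 80L)
  expect_equal(length(unique(co$patient_id)), 80L)
  per_pat <- table(co$patient_id)
  expect_equal(sort(unique(as.integer(per_pat))), c(2L, 3L))
  expect_equal(sum(per_pat == 3L), 28L)  # 28 patients carry 2 NCL
  # every FCL is unique per patient; NCL share the patient's follow-up
  for (pid in sample(unique(co$patient_id), 5)) {
    rows <- co[co$patient_id == pid, ]
    expect_equal(sum(rows$group == "FCL"), 1L)
    expect_equal(length(unique(rows$time_months)), 1L)
  }
  co2 <- suppressWarnings(generate_cohort(cohort_config()))
  expect_identical(as.data.frame(co), as.data.frame(co2))
  # single-vessel patients when no NCL are requested
  solo <- suppressWarnings(generate_cohort(cohort_config(seed = 5), n_fcl = 12L,
                                           n_ncl = 0L))
  expect_equal(as.integer(table(solo$patient_id)), rep(1L, 12L))
})

test_that("re-measured metrics in the cohort table match the latent draws", {
  co <- default_cohort()
  lat <- attr(co, "latent")
  expect_lt(max(abs(co$MLR - lat$MLR)), 0.01)
  expect_lt(max(abs(co$LSL - lat$LSL) / lat$LSL), 0.02)
  expect_lt(max(abs(co$PLSL - lat$PLSL) / lat$PLSL), 0.02)
  expect_lt(max(abs(co$vFFR - lat$vFFR)), 1e-6)
  expect_lt(max(abs(co$dvFFR - pmin(lat$dvFFR, 1 - lat$vFFR))), 0.005)
  # re-measured group medians stay near the configured ones at default n
  cfg <- attr(co, "config")
  for (g in c("FCL", "NCL")) {
    expect_lt(abs(median(co$MLR[co$group == g]) - cfg$quantiles[[g]]$MLR[2]),
              0.03)
    expect_equal(median(co$MLA[co$group == g]), cfg$quantiles[[g]]$MLA[2],
                 tolerance = 0.05, label = paste("re-measured", g, "MLA median"))
  }
})
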
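test_that("a triangular dip against a flat reference is localized exactly", {
  p <- dip_profile()  # base 6, dip to 2.4 between 10 and 24, vertex 17
  seg <- detect_lesion(p, const_reference(p$s, 6))
  expect_equal(seg$s_prox, 10, tolerance = 1e-6)
  expect_equal(seg$s_dist, 24, tolerance = 1e-6)
  expect_equal(seg$s_mla, 17)
  expect_equal(seg$MLA, 2.4)
  expect_equal(seg$PROXA, 6, tolerance = 1e-9)
  expect_equal(seg$DISTA, 6, tolerance = 1e-9)
})

test_that("no lesion is reported when the area never drops below reference", {
  s <- seq(0, 30, by = 0.1)
  p <- area_profile(s, rep(6, length(s)))
  expect_null(detect_lesion(p, const_reference(s, 6)))
  expect_null(detect_lesion(p, const_reference(s, 5.9)))
})

test_that("lesions running off a vessel end raise the ostial/truncated error", {
  s <- seq(0, 30, by = 0.1)
  A <- stats::approx(c(0, 5, 12, 30), c(3, 2, 6, 6), xout = s)$y
  p <- area_profile(s, A)
  expect_error(detect_lesion(p, const_reference(s, 6)), "ostial|truncated")
})

test_that("lesion metrics follow the defining arithmetic", {
  seg <- structure(list(s_prox = 10, s_mla = 17, s_dist = 24, PROXA = 6,
                        MLA = 2.4, DISTA = 6, R_mla = 6, vessel_id = "x"),
                   class = "lesion_segment")
  m <- lesion_metrics(seg)
  expect_equal(m$MLR, 0.4)
  expect_equal(m$LSL, 14)
  expect_equal(m$PLSL, 7)
  expect_equal(m$LLR, 0.5)
  expect_equal(m$pct_area_stenosis, 60)
  # ratio of the pooled published medians, a regression check of the formula
  expect_equal(2.82 / 5.88, 0.4796, tolerance = 1e-4)
  seg$MLA <- seg$PROXA
  expect_equal(lesion_metrics(seg)$MLR, 1)
  seg$s_dist <- seg$s_prox
  expect_error(lesion_metrics(seg), "invalid segment")
})

test_that("the segment containing the global MLA wins among multiple dips", {
  s <- seq(0, 60, by = 0.1)
  A <- stats::approx(c(0, 10, 14, 18, 35, 40, 45, 60),
                     c(6, 6, 3.5, 6, 6, 2.2, 6, 6), xout = s)$y
  p <- area_profile(s, A)
  seg <- detect_lesion(p, const_reference(s, 6))
  expect_equal(seg$s_mla, 40)
  expect_equal(seg$MLA, 2.2)
  expect_gt(seg$s_prox, 30)
  both <- detect_lesion(p, const_reference(s, 6), all_lesions = TRUE)
  expect_length(both, 2)
  expect_equal(both[[1]]$s_mla, 14)
})

test_that("MLA ties break to the most proximal grid point", {
  s <- seq(0, 30, by = 0.1)
  A <- rep(6, length(s))
  A[s >= 10 & s <= 20] <- 3  # flat-bottomed box dip
  p <- area_profile(s, A)
  seg <- detect_lesion(p, const_reference(s, 6))
  expect_equal(seg$s_mla, 10)
})

test_that("deepening a dip never increases MLR or MLA", {
  set.seed(31)
  for (rep in 1:20) {
    base <- runif(1, 4, 8)
    from <- runif(1, 5, 12); width <- runif(1, 5, 15)
    vertex <- from + runif(1, 0.2, 0.8) * width
    depth1 <- runif(1, 0.3, 0.5) * base
    depth2 <- depth1 + runif(1, 0.1, 0.4) * base
    total <- from + width + runif(1, 5, 12)
    m1 <- lesion_metrics(detect_lesion(
      dip_profile(base, base - depth1, from, vertex, from + width, total),
      const_reference(seq(0, total, by = 0.1), base)))
    m2 <- lesion_metrics(detect_lesion(
      dip_profile(base, base - depth2, from, vertex, from + width, total),
      const_reference(seq(0, total, by = 0.1), base)))
    expect_lte(m2$MLR, m1$MLR + 1e-12)
    expect_lte(m2$segment$MLA, m1$segment$MLA + 1e-12)
  }
})

test_that("translating the lesion along the vessel shifts locations, not metrics", {
  m1 <- lesion_metrics(detect_lesion(dip_profile(from = 10, vertex = 17, to = 24),
                                     const_reference(seq(0, 34, 0.1), 6)))
  m2 <- lesion_metrics(detect_lesion(dip_profile(from = 15, vertex = 22, to = 29,
                                                 total = 39),
                                     const_reference(seq(0, 39, 0.1), 6)))
  expect_equal(m2$segment$s_prox - m1$segment$s_prox, 5, tolerance = 1e-9)
  expect_equal(m2$segment$s_mla - m1$segment$s_mla, 5, tolerance = 1e-9)
  for (f in c("MLR", "LSL", "PLSL", "LLR", "pct_area_stenosis"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-9)
})

test_that("PLSL and the distal sub-length partition LSL exactly", {
  set.seed(8)
  for (rep in 1:25) {
    base <- runif(1, 4, 8)
    from <- runif(1, 4, 10); width <- runif(1, 4, 14)
    vertex <- from + runif(1, 0.15, 0.85) * width
    p <- dip_profile(base, runif(1, 0.3, 0.7) * base, from, vertex,
                     from + width, from + width + 10)
    seg <- detect_lesion(p, const_reference(p$s, base))
    m <- lesion_metrics(seg)
    expect_equal(m$PLSL + (seg$s_dist - seg$s_mla), m$LSL, tolerance = 1e-12)
    expect_gt(m$MLR, 0); expect_lte(m$MLR, 1)
  }
})

test_that("detection agrees with the exhaustive grid-scan oracle on random profiles", {
  set.seed(77)
  n_checked <- 0
  while (n_checked < 50) {
    L <- runif(1, 25, 45)
    s <- seq(0, L, by = 0.1)
    knots <- sort(c(0, runif(sample(4:9, 1), 0.05, 0.95) * L, L))
    vals <- runif(length(knots), 2, 8)
    vals[c(1, length(vals))] <- 8  # keep ends healthy
    A <- stats::approx(knots, vals, xout = s)$y
    R <- 7 - 0.02 * s
    p <- area_profile(s, pmax(A, 0.5))
    ora <- oracle_detect(s, p$A, R)
    if (is.null(ora)) { expect_null(detect_lesion(p, list(s = s, R = R))); n_checked <- n_checked + 1; next }
    if (identical(ora, "truncated")) next
    seg <- detect_lesion(p, list(s = s, R = R))
    expect_equal(seg$s_mla, ora$s_mla)
    expect_equal(seg$MLA, ora$MLA)
    expect_equal(seg$s_prox, ora$s_prox, tolerance = 1e-9)
    expect_equal(seg$s_dist, ora$s_dist, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("quantify_vessel composes the pipeline and returns a classed fit", {
  s <- seq(0, 30, by = 0.05)
  d <- 3 - 0.015 * s
  R <- pi * (d / 2)^2
  w <- numeric(length(s)); ins <- s >= 10 & s <= 24
  w[ins] <- sin(pi * (s[ins] - 10) / 14)
  p <- area_profile(s, R - 2.5 * w, vessel_id = "demo")
  fit <- quantify_vessel(p)
  expect_s3_class(fit, "mlr_fit")
  expect_equal(coef(fit)[["s_prox"]], 10, tolerance = 0.05)
  expect_equal(coef(fit)[["s_dist"]], 24, tolerance = 0.05)
  expect_output(print(fit), "MLR")
  # lesion-free taper
  fit0 <- quantify_vessel(area_profile(s, R, vessel_id = "clean"))
  expect_null(fit0$segment)
  expect_true(all(is.na(coef(fit0))))
  expect_output(print(fit0), "no lesion")
})

test_that("quantify_cohort assembles a lesion table and skips clean vessels", {
  s <- seq(0, 30, by = 0.1)
  d <- 3 - 0.015 * s
  R <- pi * (d / 2)^2
  w <- numeric(length(s)); ins <- s >= 8 & s <= 20
  w[ins] <- sin(pi * (s[ins] - 8) / 12)
  lesioned <- area_profile(s, R - 2 * w, vessel_id = "has")
  clean <- area_profile(s, R, vessel_id = "not")
  expect_warning(tab <- quantify_cohort(list(lesioned, clean)), "no lesion")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$vessel_id, "has")
  expect_true(all(c("MLR", "LSL_mm", "PLSL_mm", "pct_area_stenosis") %in%
                    names(tab)))
})
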
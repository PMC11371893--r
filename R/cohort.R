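#' Configuration of the synthetic cohort generator
#'
#' Bundles the full parameterization of the synthetic study cohort: group
#' sizes, per-group quartile triplets for each lesion metric, Spearman
#' dependence targets, event-time quartiles and bounds, and the seed.
#' The defaults encode the study conditions the package emulates: 80
#' patients contributing 188 vessels (80 future-culprit lesions, FCL, one
#' per patient; 108 non-culprit lesions, NCL), 65% NSTEMI, follow-up with
#' quartiles 21.9/25.9/29.8 months on support 1-60 months, and the
#' published per-group median/IQR triplets for MLR, MLA, PROXA, LSL, PLSL,
#' delta-vFFR and distal vFFR.
#'
#' Only MLR, MLA, LSL, PLSL, delta-vFFR and vFFR are sampled; PROXA is
#' derived as MLA/MLR (the measurement identity MLR = MLA/PROXA leaves only
#' two of the three free), and DISTA and LLR emerge from the constructed
#' geometry. The PROXA triplets are kept in the config as a descriptive
#' check of the derived marginal. Spearman targets beyond the two
#' published correlations (MLR with delta-vFFR and with vFFR) default to
#' MLR-MLA +0.5 (keeps the derived PROXA tight around its published
#' marginal and guarantees MLA < PROXA) and LSL-PLSL +0.5 (keeps
#' PLSL < LSL draws feasible).
#'
#' @param n_patients,n_fcl,n_ncl cohort structure; one FCL per patient is
#'   required (`n_fcl == n_patients`).
#' @param nstemi_fraction fraction of patients labelled NSTEMI.
#' @param quantiles per-group list of named quartile triplets (q25,q50,q75).
#' @param supports named list of support bounds per metric.
#' @param spearman_targets list of `list(pair = c(a, b), rho = r)`.
#' @param event_time_quantiles,event_time_bounds months.
#' @param seed integer master seed; all randomness flows from it.
#' @param step resampling/construction grid step (mm).
#' @param noise_amp amplitude of the smooth multiplicative area noise.
#' @param taper_slope reference diameter taper (mm per mm, negative).
#' @return object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(
    n_patients = 80L, n_fcl = 80L, n_ncl = 108L, nstemi_fraction = 0.65,
    quantiles = list(
      FCL = list(MLR  = c(0.34, 0.41, 0.51),
                 MLA  = c(1.82, 2.39, 3.25),
                 PROXA = c(4.12, 5.96, 7.90),
                 LSL  = c(9.95, 14.20, 20.74),
                 PLSL = c(3.47, 6.54, 9.99),
                 dvFFR = c(0.04, 0.08, 0.13),
                 vFFR = c(0.75, 0.84, 0.90)),
      NCL = list(MLR  = c(0.43, 0.53, 0.60),
                 MLA  = c(2.19, 2.98, 3.98),
                 PROXA = c(4.16, 5.56, 7.78),
                 LSL  = c(9.51, 13.53, 21.10),
                 PLSL = c(3.52, 6.50, 11.03),
                 dvFFR = c(0.03, 0.05, 0.08),
                 vFFR = c(0.82, 0.86, 0.92))),
    supports = list(MLR = c(0, 1), MLA = c(0, Inf), PROXA = c(0, Inf),
                    LSL = c(0, Inf), PLSL = c(0, Inf), dvFFR = c(0, 1),
                    vFFR = c(0, 1)),
    spearman_targets = list(
      list(pair = c("MLR", "dvFFR"), rho = -0.26, scope = "pooled"),
      list(pair = c("MLR", "vFFR"), rho = 0.15, scope = "pooled"),
      list(pair = c("MLR", "MLA"), rho = 0.5, scope = "within"),
      list(pair = c("LSL", "PLSL"), rho = 0.5, scope = "within")),
    event_time_quantiles = c(21.9, 25.9, 29.8),
    event_time_bounds = c(1, 60),
    seed = 1L, step = 0.1, noise_amp = 0.005, taper_slope = -0.012) {
  cfg <- list(n_patients = as.integer(n_patients), n_fcl = as.integer(n_fcl),
              n_ncl = as.integer(n_ncl), nstemi_fraction = nstemi_fraction,
              quantiles = quantiles, supports = supports,
              spearman_targets = spearman_targets,
              event_time_quantiles = event_time_quantiles,
              event_time_bounds = event_time_bounds,
              seed = as.integer(seed), step = step, noise_amp = noise_amp,
              taper_slope = taper_slope)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_fcl != config$n_patients)
    stop("config error: one FCL per patient requires n_fcl == n_patients")
  if (config$nstemi_fraction < 0 || config$nstemi_fraction > 1)
    stop("config error: nstemi_fraction must be in [0, 1]")
  for (g in names(config$quantiles))
    for (m in names(config$quantiles[[g]])) {
      q <- config$quantiles[[g]][[m]]
      if (length(q) != 3L || any(diff(q) <= 0))
        stop(sprintf("config error: quantile triplet %s/%s not strictly increasing", g, m))
      b <- config$supports[[m]]
      if (!is.null(b) && (q[1L] <= b[1L] || q[3L] >= b[2L]))
        stop(sprintf("config error: support bounds do not contain triplet %s/%s", g, m))
    }
  et <- config$event_time_quantiles
  if (any(diff(et) <= 0) || et[1L] <= config$event_time_bounds[1L] ||
      et[3L] >= config$event_time_bounds[2L])
    stop("config error: event-time quantiles must be increasing and inside the bounds")
  invisible(config)
}

# run expr with a locally set seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Gauss-Legendre nodes/weights on (0, 1) by Golub-Welsch
.gauss_legendre01 <- function(n) {
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b; J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = e$vectors[1L, ]^2)
}

# Population Spearman correlation of the two-group *pooled* sample when
# each group draws (X, Y) from a Gaussian copula with correlation r and
# its own marginals. 12 * E[F_pool(X) F_pool(Y)] - 3, by Gauss-Legendre
# quadrature on the copula.
.pooled_spearman <- function(r, margs_x, margs_y, p_fcl, gl) {
  u <- gl$x; w <- gl$w
  zu <- stats::qnorm(u)
  pool_x <- function(x) p_fcl * margs_x$FCL$p(x) + (1 - p_fcl) * margs_x$NCL$p(x)
  pool_y <- function(y) p_fcl * margs_y$FCL$p(y) + (1 - p_fcl) * margs_y$NCL$p(y)
  Eg <- function(g) {
    hx <- pool_x(margs_x[[g]]$q(u))
    # z2 grid: r * z1 + sqrt(1 - r^2) * z0 over the (u, v) product rule
    z2 <- outer(r * zu, sqrt(1 - r^2) * zu, "+")
    hy <- matrix(pool_y(margs_y[[g]]$q(stats::pnorm(z2))), length(u))
    drop((w * hx) %*% hy %*% w)
  }
  12 * (p_fcl * Eg("FCL") + (1 - p_fcl) * Eg("NCL")) - 3
}

# Pearson correlation matrix for the Gaussian copula over the sampled
# columns. Targets with scope "within" use the exact within-group map
# rho_P = 2 sin(pi rho_S / 6); targets with scope "pooled" (the published
# whole-cohort correlations) are calibrated by root-finding the
# within-group correlation whose two-group pooled Spearman matches the
# target (group separation itself contributes pooled correlation).
.copula_matrix <- function(config, cols, p_fcl = NULL) {
  if (is.null(p_fcl))
    p_fcl <- config$n_fcl / (config$n_fcl + config$n_ncl)
  P <- diag(length(cols))
  dimnames(P) <- list(cols, cols)
  gl <- NULL
  for (tg in config$spearman_targets) {
    a <- tg$pair[1L]; b <- tg$pair[2L]
    if (!(a %in% cols && b %in% cols)) next
    scope <- if (is.null(tg$scope)) "within" else tg$scope
    if (scope == "within" || p_fcl <= 0 || p_fcl >= 1) {
      r <- 2 * sin(pi * tg$rho / 6)
    } else {
      if (is.null(gl)) gl <- .gauss_legendre01(48L)
      mx <- list(FCL = .group_marginals(config, "FCL", a)[[1L]],
                 NCL = .group_marginals(config, "NCL", a)[[1L]])
      my <- list(FCL = .group_marginals(config, "FCL", b)[[1L]],
                 NCL = .group_marginals(config, "NCL", b)[[1L]])
      f <- function(r) .pooled_spearman(r, mx, my, p_fcl, gl) - tg$rho
      lo <- f(-0.985); hi <- f(0.985)
      if (lo * hi > 0)
        stop(sprintf("config error: pooled Spearman target %.2f for (%s, %s) unreachable (attainable range %.2f to %.2f given the group separation)",
                     tg$rho, a, b, min(lo, hi) + tg$rho, max(lo, hi) + tg$rho))
      r <- stats::uniroot(f, c(-0.985, 0.985), tol = 1e-4)$root
    }
    P[a, b] <- P[b, a] <- r
  }
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("config error: copula correlation matrix is not positive definite; reduce the Spearman targets or apply a nearest-PD repair before configuring")
  P
}

# marginals of one group as a named list of split_marginal objects
.group_marginals <- function(config, group, cols) {
  out <- lapply(cols, function(m) {
    q <- config$quantiles[[group]][[m]]
    b <- config$supports[[m]]
    if (is.null(b)) b <- c(-Inf, Inf)
    fit_marginal(q[1L], q[2L], q[3L], lower = b[1L], upper = b[2L])
  })
  names(out) <- cols
  out
}

# geometric feasibility of latent draws (min sub-segment 0.6 mm; the dip
# must be deep enough to be detectable against the taper + noise)
.feasible_rows <- function(X) {
  X[, "PLSL"] >= 0.6 & X[, "LSL"] - X[, "PLSL"] >= 0.6 & X[, "MLR"] <= 0.95
}

# draw n feasible latent rows for one group (resample-with-jitter:
# infeasible rows are redrawn wholesale, up to 10 passes)
.draw_group <- function(config, group, n, cols, chol_P, marginals) {
  draw <- function(k) {
    Z <- matrix(stats::rnorm(k * length(cols)), nrow = k) %*% chol_P
    U <- stats::pnorm(Z)
    X <- vapply(seq_along(cols), function(j) marginals[[j]]$q(U[, j]),
                numeric(k))
    if (k == 1L) X <- matrix(X, nrow = 1L)
    colnames(X) <- cols
    X
  }
  X <- draw(n)
  bad <- which(!.feasible_rows(X))
  attempts <- 0L
  while (length(bad) > 0L && attempts < 10L) {
    X[bad, ] <- draw(length(bad))
    bad <- bad[!.feasible_rows(X[bad, , drop = FALSE])]
    attempts <- attempts + 1L
  }
  if (length(bad) > 0L) {
    warning(sprintf("%d %s record(s) remained geometrically infeasible after 10 redraws and were redrawn unconditionally",
                    length(bad), group))
    # fall back: clamp rather than skip so group sizes stay exact
    X[bad, "PLSL"] <- pmin(pmax(X[bad, "PLSL"], 0.6), X[bad, "LSL"] - 0.6)
    X[bad, "MLR"] <- pmin(X[bad, "MLR"], 0.95)
  }
  X
}

#' Sample latent cohort metrics from the calibrated copula
#'
#' Draws per-group metric vectors (MLR, MLA, LSL, PLSL, delta-vFFR, distal
#' vFFR) from a Gaussian copula calibrated to the configured Spearman
#' targets (via rho_P = 2 sin(pi rho_S / 6)) with split-normal marginals
#' matched to the configured quartile triplets; PROXA = MLA/MLR and
#' LLR = PLSL/LSL are appended as derived columns.
#'
#' @param config a [cohort_config].
#' @param n_fcl,n_ncl group sizes (default from config).
#' @param seed optional seed (default: the config seed). `NULL` uses the
#'   current RNG state.
#' @return data.frame with columns group, MLR, MLA, PROXA, LSL, PLSL, LLR,
#'   dvFFR, vFFR.
#' @export
sample_metrics <- function(config, n_fcl = config$n_fcl, n_ncl = config$n_ncl,
                           seed = config$seed) {
  validate_cohort_config(config)
  cols <- c("MLR", "MLA", "LSL", "PLSL", "dvFFR", "vFFR")
  chol_P <- chol(.copula_matrix(config, cols,
                                p_fcl = n_fcl / max(1L, n_fcl + n_ncl)))
  .with_seed(seed, {
    parts <- list()
    for (g in c("FCL", "NCL")) {
      n <- if (g == "FCL") n_fcl else n_ncl
      if (n == 0L) next
      X <- .draw_group(config, g, n, cols, chol_P, .group_marginals(config, g, cols))
      parts[[g]] <- data.frame(group = g, X, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, parts)
    out$PROXA <- out$MLA / out$MLR
    out$LLR <- out$PLSL / out$LSL
    rownames(out) <- NULL
    out
  })
}

#' Construct a synthetic area profile realizing latent lesion metrics
#'
#' Builds a lumen area profile whose measurement by [quantify_vessel]
#' round-trips the latent draw: a linear-diameter reference taper passing
#' through PROXA at the intended proximal edge, an asymmetric smooth
#' narrowing (half-cosine rise over PLSL, half-cosine fall over
#' LSL - PLSL) of depth R(s_mla) - MLA, and a smooth low-frequency
#' multiplicative noise of amplitude `noise_amp`.
#'
#' @param record list/row with `MLR`, `MLA`, `PROXA`, `LSL`, `PLSL`.
#' @param config a [cohort_config] (grid step, noise, taper).
#' @param vessel_id identifier.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return an [area_profile] with attribute `"intended"` (list with the
#'   intended s_prox/s_mla/s_dist and the latent record).
#' @export
build_area_profile <- function(record, config = cohort_config(),
                               vessel_id = "vessel", seed = NULL) {
  .with_seed(seed, {
    LSL <- record$LSL; PLSL <- record$PLSL
    if (!(PLSL > 0 && PLSL < LSL))
      stop("infeasible record: requires 0 < PLSL < LSL")
    step <- config$step
    margin <- max(6, 0.5 * LSL)
    L <- step * ceiling((LSL + 2 * margin) / step)
    s <- seq(0, L, by = step)
    # lay the lesion so the intended MLA section falls on a grid point:
    # the detector reports the MLA location at grid resolution, and an
    # off-grid minimum would quantize PLSL by up to step/2
    s_mla <- step * round((margin + PLSL) / step)
    s_prox <- s_mla - PLSL; s_dist <- s_prox + LSL
    d_prox <- 2 * sqrt(record$PROXA / pi)
    k <- config$taper_slope
    # the detector attributes the lesion to the run holding the global area
    # minimum, so the distal *healthy* lumen must stay clearly above the
    # MLA: flatten the taper when the vessel is long enough to undercut it
    R_floor <- record$MLA + 0.3 * (record$PROXA - record$MLA)
    k_needed <- (2 * sqrt(R_floor / pi) - d_prox) / (L - s_prox)
    k <- min(0, max(k, k_needed))
    d_ref <- d_prox + k * (s - s_prox)
    R <- pi * (d_ref / 2)^2
    R_mla <- pi * ((d_prox + k * PLSL) / 2)^2
    if (R_mla - record$MLA <= 0.02 * R_mla)
      stop("infeasible record: lesion too shallow against the reference taper")
    w <- numeric(length(s))
    up <- s >= s_prox & s <= s_mla
    dn <- s > s_mla & s <= s_dist
    w[up] <- sin(0.5 * pi * (s[up] - s_prox) / PLSL)
    w[dn] <- sin(0.5 * pi * (s_dist - s[dn]) / (LSL - PLSL))
    # dip depth measured against the *local* reference, so the area
    # minimum is stationary at s_mla with value MLA exactly; a fixed-depth
    # bump on a tapering reference would shift the minimum distally along
    # the flat bump top
    A <- R - (R - record$MLA) * w
    if (config$noise_amp > 0) {
      # smooth noise confined to the lesion walls (window 4*w*(1-w), zero
      # at the edges and at the MLA): healthy-wall irregularity would
      # relocate the measured/reference crossing onto the noise field, and
      # noise over the flat bump top lets the detected minimum wander on
      # shallow long lesions — either breaks the round-trip guarantee
      lambda <- stats::runif(1L, 8, 16)
      phase <- stats::runif(1L, 0, 2 * pi)
      eps <- config$noise_amp * sin(2 * pi * s / lambda + phase) * 4 * w * (1 - w)
      A <- A * (1 + eps)
    }
    p <- area_profile(s, A, vessel_id = vessel_id)
    attr(p, "intended") <- list(s_prox = s_prox, s_mla = s_mla,
                                s_dist = s_dist, record = record)
    p
  })
}

#' Construct a surrogate vFFR pullback consistent with latent hemodynamics
#'
#' Builds a nonincreasing pressure-ratio profile from 1.0 at s = 0 to the
#' latent distal vFFR at the vessel end. A fraction
#' delta-vFFR / (1 - vFFR_distal) of the total drop is placed inside the
#' lesion segment, distributed proportionally to 1/A(s)^2 (a
#' Bernoulli-motivated weighting: pressure loss concentrates where the
#' lumen is narrowest); the remainder is spread uniformly per unit length
#' outside the lesion. This is a surrogate shape for testing the
#' measurement stack, not a physics computation. A latent delta-vFFR
#' exceeding 1 - vFFR_distal is clipped to that bound with a warning.
#'
#' @param record list/row with `vFFR` (distal) and `dvFFR`.
#' @param profile the vessel's [area_profile] (as from
#'   [build_area_profile]); its `"intended"` attribute, when present,
#'   provides the lesion segment. Otherwise pass `segment`.
#' @param segment optional lesion segment (`s_prox`, `s_dist`); when
#'   neither it nor the attribute is available the profile decays
#'   uniformly and the delta-vFFR target is not enforced (warning).
#' @return a [vffr_profile] on the same grid.
#' @export
build_vffr_profile <- function(record, profile, segment = NULL) {
  stopifnot(inherits(profile, "area_profile"))
  s <- profile$s; A <- profile$A
  v0 <- record$vFFR
  D <- 1 - v0
  if (D <= 0)
    return(vffr_profile(s, rep(1, length(s)), vessel_id = profile$vessel_id))
  dv <- record$dvFFR
  if (dv > D + 1e-12) {
    warning(sprintf("vessel '%s': latent delta-vFFR %.3f exceeds 1 - vFFR = %.3f; clipped",
                    profile$vessel_id, dv, D))
    dv <- D
  }
  if (is.null(segment)) segment <- attr(profile, "intended")
  n <- length(s)
  ds <- diff(s)
  mid <- (s[-1L] + s[-n]) / 2
  if (is.null(segment)) {
    warning(sprintf("vessel '%s': no lesion segment; uniform pressure decay, delta-vFFR target not enforced",
                    profile$vessel_id))
    drops <- D * ds / sum(ds)
  } else {
    inside <- mid >= segment$s_prox & mid <= segment$s_dist
    Amid <- (A[-1L] + A[-n]) / 2
    w_in <- ifelse(inside, ds / Amid^2, 0)
    w_out <- ifelse(inside, 0, ds)
    f <- dv / D
    drops <- numeric(n - 1L)
    if (sum(w_in) > 0) drops <- drops + f * D * w_in / sum(w_in)
    if (sum(w_out) > 0) drops <- drops + (1 - f) * D * w_out / sum(w_out)
  }
  v <- 1 - cumsum(c(0, drops))
  v[n] <- v0  # exact distal endpoint (guards rounding drift)
  vffr_profile(s, pmin(pmax(v, 1e-12), 1), vessel_id = profile$vessel_id)
}

#' Sample per-patient event times and MI-type labels
#'
#' Follow-up times are drawn from the split-normal marginal fitted to the
#' configured event-time quartiles, truncated to the configured bounds.
#' Exactly `round(nstemi_fraction * n)` patients are labelled NSTEMI; the
#' assignment to patients is randomized.
#'
#' @param config a [cohort_config].
#' @param n number of patients (default from config).
#' @param seed optional seed; default config seed; `NULL` continues the
#'   current RNG stream.
#' @return data.frame: patient_id, time_months, mi_type.
#' @export
sample_event_times <- function(config, n = config$n_patients,
                               seed = config$seed) {
  et <- config$event_time_quantiles; b <- config$event_time_bounds
  marg <- fit_marginal(et[1L], et[2L], et[3L], lower = b[1L], upper = b[2L])
  .with_seed(seed, {
    tm <- marg$r(n)
    k <- round(config$nstemi_fraction * n)
    mi <- rep("STEMI", n)
    mi[sample.int(n, k)] <- "NSTEMI"
    data.frame(patient_id = sprintf("P%04d", seq_len(n)), time_months = tm,
               mi_type = mi, stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic study cohort
#'
#' Composes the whole generator: latent metric draws from the calibrated
#' copula, per-vessel area and vFFR profile construction, and — crucially —
#' re-measurement of every vessel through the measurement stack
#' ([quantify_vessel], [delta_vffr], [distal_vffr]). The analysis table is
#' populated with the *measured* values, not the latent draws. Each
#' patient carries exactly one FCL (the event vessel, event = 1 at the
#' patient's index time) and their NCL are censored at the same time.
#'
#' @param config a [cohort_config].
#' @param n_fcl,n_ncl group sizes (default from config; `n_fcl` also sets
#'   the number of patients).
#' @param write_dir optional directory: writes `cohort.csv`,
#'   `config.yaml`, and per-vessel geometry JSON / vFFR CSV files under
#'   `vessels/`.
#' @param keep_profiles if `TRUE`, attach the generated profiles
#'   (memory-heavy at large n).
#' @param progress print a progress line every 2000 vessels.
#' @return data.frame of class `mlr_cohort`: vessel_id, patient_id, group,
#'   mi_type, time_months, event, MLR, MLA, PROXA, DISTA, LSL, PLSL, LLR,
#'   pct_area_stenosis, dvFFR, vFFR (all measured). Attributes: `config`,
#'   `latent` (the latent draw table), and optionally `profiles`.
#' @export
generate_cohort <- function(config = cohort_config(), n_fcl = config$n_fcl,
                            n_ncl = config$n_ncl, write_dir = NULL,
                            keep_profiles = FALSE, progress = FALSE) {
  validate_cohort_config(config)
  n_pat <- n_fcl
  .with_seed(config$seed, {
    latent <- sample_metrics(config, n_fcl = n_fcl, n_ncl = n_ncl, seed = NULL)
    pt <- sample_event_times(config, n = n_pat, seed = NULL)
    # patient assignment: FCL i -> patient i; NCL spread as evenly as
    # possible (the first n_ncl %% n_pat patients carry one extra NCL)
    ncl_per_pat <- rep(n_ncl %/% n_pat, n_pat)
    extra <- n_ncl %% n_pat
    if (extra > 0L) ncl_per_pat[seq_len(extra)] <- ncl_per_pat[seq_len(extra)] + 1L
    pat_of <- c(seq_len(n_fcl), rep(seq_len(n_pat), ncl_per_pat))
    nv <- n_fcl + n_ncl
    cols <- c("MLR", "MLA", "PROXA", "DISTA", "LSL", "PLSL", "LLR",
              "pct_area_stenosis", "dvFFR", "vFFR")
    M <- matrix(NA_real_, nrow = nv, ncol = length(cols),
                dimnames = list(NULL, cols))
    profiles <- if (keep_profiles || !is.null(write_dir)) vector("list", nv)
    vffrs <- if (keep_profiles || !is.null(write_dir)) vector("list", nv)
    cols6 <- c("MLR", "MLA", "LSL", "PLSL", "dvFFR", "vFFR")
    chol_P <- chol(.copula_matrix(config, cols6,
                                  p_fcl = n_fcl / max(1L, n_fcl + n_ncl)))
    margs <- list(FCL = .group_marginals(config, "FCL", cols6),
                  NCL = .group_marginals(config, "NCL", cols6))
    for (i in seq_len(nv)) {
      rec <- as.list(latent[i, ])
      vid <- sprintf("V%05d", i)
      ok <- FALSE
      for (attempt in 1:10) {
        res <- tryCatch({
          prof <- build_area_profile(rec, config, vessel_id = vid, seed = NULL)
          fit <- quantify_vessel(prof, step = config$step)
          if (is.null(fit$segment)) stop("no lesion detected on generated vessel")
          vf <- suppressWarnings(build_vffr_profile(rec, prof))
          list(fit = fit, prof = prof, vf = vf)
        }, error = function(e) e)
        if (!inherits(res, "error")) { ok <- TRUE; break }
        # jitter: redraw this record's latent metrics afresh
        g <- latent$group[i]
        newX <- .draw_group(config, g, 1L, cols6, chol_P, margs[[g]])
        rec <- as.list(as.data.frame(newX))
        rec$PROXA <- rec$MLA / rec$MLR
        rec$LLR <- rec$PLSL / rec$LSL
        latent[i, names(rec)] <- rec
      }
      if (!ok) {
        warning(sprintf("vessel %s: skipped after 10 construction attempts", vid))
        next
      }
      cf <- coef(res$fit)
      M[i, 1:8] <- cf[c("MLR", "MLA", "PROXA", "DISTA", "LSL", "PLSL",
                        "LLR", "pct_area_stenosis")]
      M[i, "dvFFR"] <- delta_vffr(res$vf, res$fit$segment)
      M[i, "vFFR"] <- distal_vffr(res$vf)
      if (!is.null(profiles)) { profiles[[i]] <- res$prof; vffrs[[i]] <- res$vf }
      if (progress && i %% 2000L == 0L)
        cat(sprintf("  generated %d / %d vessels\n", i, nv))
    }
    out <- data.frame(
      vessel_id = sprintf("V%05d", seq_len(nv)),
      patient_id = pt$patient_id[pat_of],
      group = latent$group,
      mi_type = pt$mi_type[pat_of],
      time_months = pt$time_months[pat_of],
      event = as.integer(latent$group == "FCL"),
      M, stringsAsFactors = FALSE)
    keep <- !is.na(out$MLR)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "config") <- config
    attr(out, "latent") <- latent[keep, , drop = FALSE]
    if (keep_profiles) {
      attr(out, "profiles") <- profiles[keep]
      attr(out, "vffr_profiles") <- vffrs[keep]
    }
    class(out) <- c("mlr_cohort", "data.frame")
    if (!is.null(write_dir))
      write_cohort(out, write_dir, profiles = profiles[keep],
                   vffrs = vffrs[keep])
    out
  })
}

#' @export
print.mlr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d vessels (%d FCL / %d NCL) from %d patients, %d events\n",
              nrow(x), sum(x$group == "FCL"), sum(x$group == "NCL"),
              length(unique(x$patient_id)), sum(x$event)))
  cat(sprintf("  median MLR: FCL %.3f, NCL %.3f; median follow-up %.1f months\n",
              stats::median(x$MLR[x$group == "FCL"]),
              stats::median(x$MLR[x$group == "NCL"]),
              stats::median(x$time_months)))
  invisible(x)
}
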
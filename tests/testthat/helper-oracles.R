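# Independent oracles used across the suite. Deliberately written as plain
# loops / enumeration, not by calling the package internals.

# exhaustive grid scan for the lesion segment: global area minimum among
# below-reference samples, run boundaries, linearly interpolated crossings
oracle_detect <- function(s, A, R, tol = 1e-9) {
  below <- A - R < -tol
  if (!any(below)) return(NULL)
  idx <- which(below)
  mla <- idx[which.min(A[idx])]
  lo <- mla; while (lo > 1 && below[lo - 1]) lo <- lo - 1
  hi <- mla; while (hi < length(s) && below[hi + 1]) hi <- hi + 1
  if (lo == 1 || hi == length(s)) return("truncated")
  d <- A - R
  xing <- function(i) {
    if (abs(d[i]) <= tol) return(s[i])
    if (abs(d[i + 1]) <= tol) return(s[i + 1])
    s[i] + d[i] / (d[i] - d[i + 1]) * (s[i + 1] - s[i])
  }
  list(s_mla = s[mla], MLA = A[mla], i_prox = lo - 1, i_dist = hi,
       s_prox = xing(lo - 1), s_dist = xing(hi))
}

# AUC by exhaustive pair counting, 0.5 credit for ties; event-oriented
# scores (higher = more event-like) are supplied by the caller
oracle_auc <- function(ev, ct) {
  tot <- 0
  for (a in ev) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(ev) * length(ct))
}

# best Youden J over a dense threshold sweep (low values predict events)
oracle_best_J_low <- function(ev, ct) {
  cand <- sort(unique(c(ev, ct)))
  cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  best <- -Inf
  for (t in cand) {
    J <- mean(ev < t) + mean(!(ct < t)) - 1
    if (J > best) best <- J
  }
  best
}

# exact two-sided Mann-Whitney p by complete enumeration of labelings
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  U_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  U_all <- apply(combos, 2, function(ix)
    sum(rank(pooled)[ix]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-12)
}

# piecewise-linear test profile with a triangular dip (vertex on request)
dip_profile <- function(base = 6, dip_to = 2.4, from = 10, vertex = 17,
                        to = 24, total = 34, step = 0.1, id = "dip") {
  s <- seq(0, total, by = step)
  A <- stats::approx(c(0, from, vertex, to, total),
                     c(base, base, dip_to, base, base), xout = s)$y
  area_profile(s, A, vessel_id = id)
}

const_reference <- function(s, level) list(s = s, R = rep(level, length(s)))
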
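---
title: "Quantifying mild coronary lesions: the minimum lumen ratio and its risk analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mild coronary lesions: the minimum lumen ratio and its risk analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlrqca)
```

## The measurement problem

Three-dimensional quantitative coronary angiography (3D-QCA) reduces a
reconstructed vessel to an *area function*: the lumen cross-sectional area
$A(s)$ (mm²) along the centerline arc length $s$ (mm), ordered proximal to
distal. Mild lesions — under 50 % diameter stenosis — are clinically
quiescent but occasionally destabilize years later and cause a myocardial
infarction (MI). The question this package operationalizes is which
geometric feature of such a lesion carries that risk.

The core statistic is the **minimum lumen ratio**

$$\mathrm{MLR} = \frac{\mathrm{MLA}}{\mathrm{PROXA}},$$

the minimum lumen area inside the lesion divided by the lumen area at the
lesion's proximal edge. A low MLR means the lumen collapses sharply
downstream of the lesion entrance — a converging-flow narrowing that both
concentrates the translesional pressure gradient (by Bernoulli's theorem,
pressure loss scales roughly with $1/A^2$) and marks plaques that are more
likely to destabilize. MLR is dimensionless and self-normalized: unlike
MLA it does not depend on the caliber of the vessel.

Everything else is scaffolding for measuring MLR reproducibly:

1. a *reference line* $R(s)$ — the lumen the vessel would have without
   disease;
2. the *lesion segment*, delimited by the crossings of $A$ and $R$;
3. scalar descriptors of the segment: MLA, PROXA, DISTA (distal edge
   area), LSL (lesion segment length), PLSL (proximal sub-length, edge to
   MLA), LLR = PLSL/LSL, percent area stenosis
   $(1 - \mathrm{MLA}/R(s_\mathrm{mla}))\times 100$, and — when a vFFR
   pullback is supplied — the distal vFFR and the translesional
   $\Delta$vFFR (vFFR at the proximal edge minus vFFR at the distal edge).

## The reference line

Commercial QCA systems interpolate a proprietary "healthy" reference; its
functional form is not public. This package uses the standard QCA
convention of a reference that is **linear in equivalent diameter**
$d(s) = 2\sqrt{A(s)/\pi}$, fitted by one-sided iteratively trimmed least
squares:

* fit $d \sim s$ by ordinary least squares on all samples;
* estimate a robust residual scale $\sigma = 1.4826\,\mathrm{MAD}$ from
  the retained residuals;
* discard samples with residual $< -k\sigma$ (diseased lumen lies *below*
  the healthy line; everything above is kept);
* refit and repeat until the retained set stabilizes (at most 20 passes),
  then convert back to area, $R = \pi (d/2)^2$.

The trim multiplier defaults to $k = 2$. A cut at $1\sigma$ is not
convergent: it repeatedly shaves the lower fringe of the *healthy* noise
itself, the refitted line drifts upward, and on realistic profiles the
retained set erodes until nothing is left. At $2\sigma$ only clearly
diseased samples are excluded and the iteration reaches a fixed point
within a handful of passes. The MAD has an absolute floor so that
noise-free (synthetic) profiles are not trimmed at all. If fewer than 25 %
of the samples survive (`min_healthy_frac`), the vessel is reported as
degenerate rather than silently fitted — a reference interpolated from a
fully diseased profile would be meaningless.

## Lesion detection and its numerical choices

Profiles are resampled to a uniform 0.1 mm grid (augmented with the
original knots, so extrema of piecewise-linear data are preserved
exactly). Detection then works on $A - R$:

* the lesion is the below-reference run containing the **global** area
  minimum; other runs are reported only in the exploratory
  `all_lesions` mode;
* MLA ties break to the most proximal grid point;
* edges are localized sub-grid by linear interpolation of $A - R$ across
  the straddling interval. When the outside sample merely *grazes* the
  reference ($|A - R| \le 10^{-9}$, as happens when the healthy wall is
  exactly conical), the interpolation is degenerate and the crossing is
  instead extrapolated from the two nearest inside samples on the locally
  linear lesion wall; the edge area is then read off the reference
  interpolation, since the measured-area chord across a steep wall
  undershoots away from the true zero;
* a lesion whose run touches either profile end has no crossing on that
  side: the vessel is excluded with an ostial/truncated-lesion error,
  mirroring the exclusion of ostial lesions from the study population;
* percent area stenosis uses $R(s_\mathrm{mla})$, the standard QCA
  definition — a PROXA-based variant would be exactly $1-\mathrm{MLR}$
  and therefore redundant.

`quantify_vessel()` composes resampling, reference fitting, detection and
metric computation, and is the package's central fitting function; the
returned object carries `print`, `summary`, `coef`, `predict`, `plot` and
`residuals` methods.

vFFR is never computed here: pullbacks come from validated external
software (real data) or from the generator's surrogate (synthetic data).
"Distal vFFR" is read at the last sample of the pullback; edge values are
linear interpolations at the detected edge positions. Non-monotone
pullbacks are accepted and may produce a negative gradient, which is
reported as-is with a warning — measured data are not silently repaired.

## The synthetic cohort

No patient data are distributed, so the package ships a generator that
emulates the published study conditions: 80 patients, 188 vessels — one
future-culprit lesion (FCL) per patient plus 108 non-culprit lesions
(NCL), 65 % of patients NSTEMI, follow-up quartiles 21.9/25.9/29.8 months
truncated to 1–60 months.

**Marginals.** Each metric is published only as median (IQR). A quartile
triplet is turned into a distribution by a quantile-spliced two-piece
normal: $Q(p) = q_{50} + s_\mathrm{lo}\,z_p$ for $p<0.5$ and
$q_{50} + s_\mathrm{hi}\,z_p$ otherwise, with
$s = \Delta q/z_{0.75}$. This is the minimal family that reproduces the
three published quartiles *exactly*; supports are then truncated to the
natural ranges (ratios to $(0,1)$, lengths and areas to $(0,\infty)$) by
inverse-CDF restriction. Truncation renormalizes the distribution, so
strongly truncated metrics (ΔvFFR, PLSL) have post-truncation quartiles a
few percent above the configured ones; this is inherent to imposing a
support on a quantile-matched family and is left visible rather than
re-tuned.

**Joint structure.** Only two dependence values are published: pooled
Spearman correlations of MLR with ΔvFFR (−0.26) and with vFFR (0.15). The
generator couples the marginals with a Gaussian copula. Because the
FCL/NCL separation itself contributes rank correlation in the pooled
sample, using −0.26 as the *within-group* correlation would pool to about
−0.35; the within-group copula entry is therefore calibrated by
root-finding the value whose two-group pooled population Spearman
(computed by Gauss–Legendre quadrature over the copula) matches the
published number. Two additional correlations are package defaults, both
configurable: MLR–MLA +0.5 (keeps the derived PROXA concentrated near its
published marginal) and LSL–PLSL +0.5 (keeps PLSL < LSL draws frequent;
infeasible draws are redrawn, and at independence that conditioning
would visibly distort the length marginals).

**The identity constraint.** The published table lists MLR, MLA and PROXA
separately, but the measurement identity MLR = MLA/PROXA leaves only two
degrees of freedom. The generator samples MLR and MLA and derives
PROXA = MLA/MLR (as DISTA and LLR are also derived). The choice favors
the two quantities whose recovery the package demonstrates — the MLR
medians/AUC and the MLA AUC — while the derived PROXA quartiles stay
within ~10 % of the published triplet.

**Geometry construction.** Each vessel is a linear-diameter reference
taper passing through PROXA at the intended proximal edge (default slope
−0.012 mm/mm, flattened automatically when a long vessel would otherwise
taper below the MLA — the detector attributes the lesion to the global
minimum, so the distal healthy lumen must stay clearly above it). The
lesion is an asymmetric smooth narrowing with half-cosine rise over PLSL
and half-cosine fall over LSL − PLSL, applied against the local
reference: $A = R - (R - \mathrm{MLA})\,w(s)$, which pins a stationary
minimum of exactly MLA at the intended location regardless of taper. The
construction grid is laid so that the MLA section falls on a grid point
(the detector reports MLA locations at grid resolution). Smooth
multiplicative noise (0.5 % default) is windowed by $4w(1-w)$ — active on
the lesion walls, zero at the edges and at the MLA: noise at the edges
would relocate the measured crossing onto the noise field, and noise over
the flat bump top lets the detected minimum wander on long shallow
lesions. What passing round-trip tests therefore show is that the
measurement stack inverts this *idealized* geometry essentially exactly;
they do not certify performance on real angiographic irregularity, which
has no such structure. The reference-fit robustness to full-field noise
is exercised separately in the parameter-recovery test suite.

**Pullback surrogate.** The vFFR profile drops from 1.0 to the sampled
distal value; a fraction $\Delta\mathrm{vFFR}/(1-\mathrm{vFFR})$ of the
total drop is placed inside the lesion, distributed proportionally to
$1/A(s)^2$ (Bernoulli-motivated), the rest uniformly per unit length
outside. A sampled ΔvFFR exceeding $1-\mathrm{vFFR}$ is geometrically
impossible for a nonincreasing profile and is clipped with a warning;
with the published FCL marginals this affects roughly a quarter of FCL
draws and pulls the re-measured median ΔvFFR from the nominal 0.08 to
about 0.076 — a visible, documented consequence of reconciling the two
published marginals.

Every cohort row is populated by **re-measuring** the generated profiles
through `quantify_vessel()` and the pullback readers — the latent draws
never enter the analysis table directly.

## The statistics pipeline

The analysis layer reproduces the study's inference choices: two-sided
Mann–Whitney tests (exact enumeration below a combined n of 16 without
ties, normal approximation with tie correction otherwise) with Bonferroni
adjustment over the nine compared metrics; Spearman correlations with
t-approximation p-values; ROC curves with the DeLong variance (via pROC),
Wald confidence intervals clipped to $[0,1]$ and a two-sided test against
AUC = 0.5; Youden's J over midpoint thresholds with ties broken toward
specificity; Kaplan–Meier curves per stratum and a hazard ratio from a
single-covariate Cox fit with Efron tie handling (heavy ties arise
because all of a patient's vessels share one follow-up time), with the
log-rank p reported alongside. Score orientations are declared per metric
(low MLR/MLA/vFFR are event-oriented, high ΔvFFR and lengths), never
auto-flipped — auto-orientation silently produces optimistic AUCs.
Dichotomization uses strict `<` for the low stratum, matching the
published "below 0.399" convention. Vessels are analyzed as independent
units, as in the source analysis; within-patient clustering corrections
are out of scope and documented as such.

## What the recovery runs show — and one honest failure

`scripts/acceptance.R` regenerates a 10,000-vessels-per-group cohort and
recomputes the published cohort-level numbers from re-measured values.
The group MLR medians (0.41 FCL / 0.53 NCL), the MLA AUC (≈0.63), the
follow-up median (25.9 months) and the FCL ΔvFFR median (≈0.08) are
recovered within the expected tolerances.

The pooled **MLR AUC does not reach the published 0.75**: any
distribution family matched to the published FCL (0.34/0.41/0.51) and NCL
(0.43/0.53/0.60) quartile triplets yields an AUC of about 0.69, because
the AUC of a single score is fully determined by the two group
distributions and three quartiles do not pin down the tails that gave the
real data their extra separation. The corresponding test is left failing
deliberately; widening the tolerance or reshaping the marginals beyond
what the published table supports would make the check meaningless.

## Problem sizes and runtime choices

Default test and acceptance runs use 10,000 vessels per group for the
recovery statistics (median sampling error ≈ 0.0015 on MLR), 100,000
draws for the correlation and event-time checks, 1,000 simulations for
DeLong coverage, and 200 random profiles for the detection oracle — sizes
chosen so the whole suite completes in a few minutes on one core while
leaving Monte-Carlo error an order of magnitude below each asserted
tolerance.

## Known limitations

* The reference-line algorithm is a documented stand-in for an
  unspecified proprietary interpolation; absolute agreement with any
  commercial system is not claimed.
* The generator's vessels are idealized (conical healthy wall, single
  smooth lesion, surrogate pullback); real-data performance of the
  detector is only partially characterized by the synthetic round trips.
* LLR inherits its distribution from sampled PLSL/LSL; its published
  median (≈0.53) is not exactly consistent with any independent
  PLSL/LSL marginals (the ratio of the published medians is 0.46), and
  the generated LLR median lands near 0.44.
* Survival inference treats vessels as independent; the hazard ratio on
  the default 188-vessel cohort demonstrates direction and significance,
  not the published effect size, which is not reproducible from summary
  statistics.
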
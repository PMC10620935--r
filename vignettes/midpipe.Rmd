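---
title: "Isotopologue analysis with midpipe: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopologue analysis with midpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midpipe)
```

# Scope

`midpipe` processes isotopologue peak-area tables from \eqn{^{13}}C
stable-isotope tracing experiments measured by LC-MS, as exported by
peak-integration software: one row per (metabolite, mass shift) pair, one
column per sample. It covers the chain from raw intensities to differential
statistics:

1. blank-based quantification thresholds and sub-threshold correction,
2. natural \eqn{^{13}}C abundance correction,
3. normalization between isotopologues and between samples,
4. mass isotopomer distributions (MIDs), fractional labeling, diagnostic
   ratios,
5. differential testing of metabolite abundances (linear mixed models) and
   isotopologue fractions (beta mixed regression),

plus a synthetic-data generator that produces ground-truthed raw datasets
with the statistical structure the analysis assumes, so every stage can be
verified without access to instrument data.

# Quantification thresholds

Each batch carries blank measurements (extraction buffer without cells).
For every isotopologue row and batch, the limit of quantification is

$$T = \mu_b + 2\sigma_b,$$

the blank mean plus twice the blank standard deviation. The sample
(\eqn{n-1}) standard deviation is used because blank counts are small,
typically three per batch. Intensities below \eqn{\mu_b} are set to zero;
intensities in \eqn{[\mu_b, T)} are linearly mapped onto \eqn{[0, T)} by
\eqn{x \mapsto T\,(x - \mu_b)/(T - \mu_b)}, so the map is continuous at
\eqn{T}, monotone, and intensities at or above \eqn{T} pass through
unchanged. When \eqn{\sigma_b = 0} the interval is empty and the map
degenerates to a hard gate at \eqn{T}.

The pointwise map is deliberately *not* idempotent (a value mapped into
\eqn{(0, \mu_b)} would be re-zeroed by a second pass); instead the
operation is idempotent at the table level — the stage tag records that a
table has been thresholded and a second application is a no-op. This is
the property the tests assert.

Two derived rules use the thresholds:

* **Testability** — an analyte enters differential statistics only when at
  least two non-blank samples lie strictly above \eqn{T}. The strict
  inequality makes an all-zero analyte with \eqn{T = 0} untestable.
* **Group cleaning** — for each analyte and sample group, if strictly more
  than 1/3 of the group's values fall below \eqn{T} (missing values count
  as below), the group's values for that analyte are set to missing. The
  comparison uses integer arithmetic (`3 * n_below > n`), so a group of 3
  with exactly one sub-threshold value sits exactly at 1/3 and is kept.

The cleaning *mask* is computed on the thresholded table, where values and
thresholds share a scale, but is applied to the normalized table at the
end of the processing chain (`clean_groups(..., apply_to = )`). Cleaning
earlier would interact badly with the correction step: natural-abundance
deconvolution needs the complete shift vector of a metabolite, so a single
cleaned isotopologue would void the whole metabolite for that group and
silently remove the most interesting contrasts (a group in which an
isotopologue is genuinely absent is exactly the group one wants to compare
against). MIDs of partially cleaned vectors are renormalized over the
non-missing isotopologues.

# Natural-abundance correction

Carbon has a naturally occurring heavy isotope (\eqn{^{13}}C, abundance
\eqn{p \approx 1.07\%} per atom), so an unlabeled molecule with \eqn{n}
carbons already shows mass shifts. With \eqn{j} tracer-labeled carbons,
each of the remaining \eqn{n - j} is independently heavy with probability
\eqn{p}, giving observed shift \eqn{i = j + \mathrm{Binomial}(n - j, p)}:

$$M_{ij} = \binom{n-j}{\,i-j\,} p^{\,i-j} (1-p)^{\,n-i}, \qquad i \ge j,$$

a lower-triangular, column-stochastic matrix. The package works in
*high-resolution mode*: the mass analyser resolves the isotopes of
non-tracer elements (H, N, O, ...), so only carbon contributes to the
nominal mass-shift ladder and no multi-element correction terms are
needed. The default \eqn{p = 0.0107} is the standard terrestrial value and
is configurable. If tracer purity \eqn{u < 1} is specified, the matrix is
pre-composed with a \eqn{\mathrm{Binomial}(j, u)} dilution of the labeled
positions; the default is \eqn{u = 1} (no impurity correction).

Correction solves \eqn{M y = x} per metabolite-sample vector. The default
solver is non-negative least squares (`pracma::lsqnonneg`, applied on the
unit-sum scale and rescaled, since active-set tolerances are absolute
while peak areas span orders of magnitude); noisy vectors then cannot
produce negative isotopologues. Direct inversion with negative clipping is
retained for oracle tests. Corrected vectors are **not** renormalized to
the observed total — absolute corrected intensities are carried forward
and normalization is a separate stage. A missing entry anywhere in a
vector makes the whole corrected vector missing, because the
deconvolution couples all shifts.

The simulator uses the *same* `build_correction_matrix()` kernel in the
forward direction, so simulator and corrector cannot drift apart; the
tests additionally check the kernel against brute-force enumeration over
all \eqn{2^n} per-atom isotope configurations.

# Normalization

Two factors, applied in this order:

* **Between isotopologues** — every value of metabolite \eqn{m} is divided
  by \eqn{A_m}, the across-sample mean of its per-sample isotopologue
  sums. Afterwards every retained metabolite has mean abundance exactly 1,
  making metabolites with very different ionization efficiencies
  comparable. "Mean metabolite abundance" is read as the mean over
  samples; the operation is idempotent, and metabolites with \eqn{A_m = 0}
  are left untouched and flagged.
* **Between samples** — each sample is divided by a size factor
  \eqn{s_j}, a weighted mean of its isotopologue signal with weights
  \eqn{w_k = 1/\mathrm{rv}_k}, where \eqn{\mathrm{rv}_k =
  \mathrm{var}_k/\mathrm{mean}_k^2} is the squared coefficient of
  variation of analyte \eqn{k} across samples (linear scale). Weights are
  clamped at their 99th percentile so that a near-constant analyte cannot
  dictate the factors; if *every* usable analyte is exactly constant the
  weights carry no information and equal weighting is used (this is what
  makes "identical samples \eqn{\Rightarrow} all factors 1" hold).
  Analytes with missing values are excluded from the weighting set.
  Factors are anchored to geometric mean 1, a convention.

MIDs are per-sample ratios and therefore invariant to size factors; the
abundance analysis is not, which is why factors are estimated with
variance-informed weights rather than plain totals. One caveat worth
knowing: weighted size factors estimated from few analytes partially
absorb the noise of the analytes that dominate the weights
(self-normalization), shrinking their apparent residual variance. With
realistic panel sizes the weight mass is spread and the effect is small,
but it is visible in very small simulated panels.

# Summaries

With normalized intensities \eqn{x_{mk s}} (metabolite \eqn{m}, shift
\eqn{k}, sample \eqn{s}):

* abundance \eqn{a_{ms} = \sum_k x_{mks}} (missing only when the whole
  vector is missing),
* MID \eqn{\pi_{mks} = x_{mks} / \sum_k x_{mks}}, undefined for zero sums,
* fractional labeling \eqn{F_{ms} = \sum_k k\,\pi_{mks} / n_m \in [0,1]},
  the mean fraction of labeled carbons — the quantity rendered as color
  intensity on tracer flux maps,
* isotopologue ratios such as m+3/m+2, the classic marker contrasting
  anaplerotic entry of pyruvate into the TCA cycle (pyruvate carboxylase,
  m+3) against oxidative entry via acetyl-CoA (pyruvate dehydrogenase,
  m+2); group ratios are arithmetic means of per-sample ratios,
* metabolite abundance ratios (e.g. fumarate/succinate, GSSG/GSH); both
  members share a sample's size factor, so normalized-scale ratios equal
  raw-scale ratios.

# Differential statistics

Celltype group is a fixed effect and donor a random intercept in both
models; samples from the same donor are correlated, and the paired
structure across groups is what the random effect encodes.

**Abundances.** Natural-log abundances are modeled as
\eqn{\log y = \beta_{g} + b_{d} + \varepsilon}, \eqn{b_d \sim N(0,
\sigma_d^2)}, fit by REML (`lme4::lmer`, cell-means coding). Zeros are
replaced by half the analyte's smallest positive value before logging
(half-minimum LOD rule); positives are untouched. With fewer than two
donors the model degenerates to OLS with \eqn{\sigma_d = 0}.

**Isotopologue fractions.** Fractions live on \eqn{[0,1]} and are
heteroscedastic with mean; a beta response with logit link is the natural
model:
\eqn{y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)},
\eqn{\mathrm{logit}(\mu) = \beta_g + b_d}. The marginal likelihood
integrates each donor's random intercept by *adaptive* Gauss–Hermite
quadrature: per donor the integrand's mode is located by Newton steps and
the grid centered and scaled there, 9 nodes by default. The fit is maximum
likelihood over \eqn{(\beta, \log\phi, \log\sigma_d)} (`nlminb`), standard
errors from the numerical Hessian. Boundary observations are made
admissible by the shrinkage transform \eqn{y' = (y\,(N-1)+0.5)/N}; it is
applied to the boundary values only, leaving interior observations exact.
`betareg_loglik()` re-evaluates the fitted likelihood at any node count —
for a converged fit, 9 versus 25 nodes changes the log-likelihood by far
less than \eqn{10^{-4}}, which the tests assert.

**Contrasts and FDR.** For a contrast vector \eqn{c} (e.g. TSCM − TN),
the Wald statistic \eqn{c^\top\hat\beta / \sqrt{c^\top \hat V c}} is
compared to the standard normal; p-values are Benjamini–Hochberg adjusted
per contrast, separately within the metabolite-level and
isotopologue-level families (the two analyses answer different questions
and are reported separately). The z approximation matches
simultaneous-contrast convention and is the default; Satterthwaite
degrees of freedom via `lmerTest` can be requested for the abundance
model. With small designs the z test is mildly anticonservative — under
the null simulation below it rejects at ~0.06 instead of 0.05 — which is
the known cost of that convention, not a defect of the fit.

REML is used for the linear mixed model, ML for the beta model (REML is
not defined there).

# The synthetic-data generator

`simulate_experiment()` runs the assumed generative model forwards, per
sample and metabolite:

$$A = \exp(\mu_{g,m} + b_{d,m} + \varepsilon), \quad
  b_{d,m} \sim N(0, \sigma_d^2), \; \varepsilon \sim N(0, \sigma_e^2),$$

true isotopologue intensities \eqn{A \cdot \pi_{g,m}}, forward
natural-abundance convolution, multiplicative log-normal measurement noise
with unit mean and configured CV (the standard error structure of LC-MS
peak areas), optional per-sample scale factors, an additive
truncated-Gaussian blank baseline, and censoring below a detection floor.
Blank samples carry baseline only. Donor effects are drawn independently
per metabolite — donor physiology affects different metabolites
differently, and this is also what the per-analyte mixed models assume.
Everything is a deterministic function of the scenario seed.

Presets (each a complete `sim_scenario`):

* `differentiation` — four T cell subsets (TN, TSCM, TCM, TEM) × 3 donors
  × 2 replicates over a 16-metabolite glycolysis/TCA panel. TN carries
  full labeling in upper glycolysis but none downstream of
  3-phosphoglycerate, emulating an enolase block in naive cells; activated
  subsets have m+2-dominant TCA labeling with the m+3 component fixed at
  an m+3/m+2 ratio of 0.15 (anaplerosis low relative to acetyl-CoA entry)
  and log-scale abundance effects of 0.3–1.0 along the differentiation
  axis. Defaults: \eqn{\sigma_d = 0.25}, \eqn{\sigma_e = 0.15}, CV 0.15,
  baseline \eqn{50 \pm 15} against abundances near \eqn{10^6} — donor
  variability comparable to biological residual, in the range typical for
  primary human cells.
* `exhaustion` — TEFF vs TEX, with TEX labeling scaled down.
* `null` — 2 groups × 3 donors × 4 replicates, 1000 three-carbon
  analytes, no effects anywhere; used for type-I error calibration. Four
  replicates per donor-group cell give the Wald z test enough residual
  degrees of freedom for its nominal level to be meaningful at all; with
  one paired observation per donor any z-based test would be
  anticonservative by construction.
* `lod_stress` — abundances log-spaced across the blank threshold, so
  thresholding, testability and group cleaning all trigger.

What the generator deliberately does **not** emulate: chromatographic or
retention-time drift, correlated noise between co-eluting analytes,
ion-suppression effects, batch-to-batch response changes, or missingness
mechanisms other than LOD censoring. Passing tests demonstrate that the
pipeline inverts its own assumed forward model and controls error rates
under it — not that real data satisfy those assumptions. Preset MIDs
encode qualitative biological patterns as scenario parameters; they are
not quantitative reconstructions of any particular experiment.

# Numerical choices and degenerate inputs

* Blank rows without usable measurements get \eqn{\mu_b = T = 0} (fully
  quantifiable) with a warning — the permissive reading.
* The NNLS deconvolution is solved at unit scale (see above); an all-zero
  vector returns zeros without invoking the solver.
* `nlminb` bounds: \eqn{\log\phi \in [\log 10^{-2}, \log 10^8]},
  \eqn{\log\sigma_d \ge \log 10^{-6}}; a fit driving \eqn{\sigma_d} to the
  lower bound is reported with \eqn{\sigma_d \approx 0}, which is how a
  zero donor variance manifests. A constant response drives \eqn{\phi} to
  its upper bound; group differences are then 0 as expected.
* Wald tests with zero standard error report \eqn{p = 1} when the
  estimate is also zero (an all-zero contrast), \eqn{p = 0} otherwise.
* Non-converged fits are kept, flagged, and reported with missing
  p-values; they still appear in the diagnostics table.
* Ties at exactly \eqn{x = T}: the value passes thresholding unchanged,
  counts as *not* below threshold for cleaning, and as *not* above for
  testability — a measure-zero event on real data, pinned down so the
  boundary tests are deterministic.

# Problem sizes used by the test suite

The suite verifies the correction oracle on 1000 random MIDs (up to 8
carbons) against brute-force enumeration, calibrates type-I error on the
1000-analyte null preset, checks beta-model recovery over 200 simulations
at 30 observations per group, and runs the differentiation preset
end-to-end twice to confirm bit-identical manifests and a truth-ranking
AUC above 0.9. These sizes give stable Monte-Carlo estimates (binomial SE
of a 5% rate at n = 1000 is 0.7 percentage points) while keeping the
whole suite under a few minutes on one core.

# Known limitations

* Carbon-only correction: tracers other than \eqn{^{13}}C and
  low-resolution multi-element correction are out of scope.
* No internal-standard normalization (the d27 myristic acid spike common
  in extraction protocols is not used computationally).
* No imputation: missingness propagates, by design.
* Size factors assume most analytes are not differential; grossly
  asymmetric designs violate this, as with any total-signal normalization.
* The beta model treats each isotopologue fraction separately; it does not
  model the compositional coupling of a metabolite's full MID vector.
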
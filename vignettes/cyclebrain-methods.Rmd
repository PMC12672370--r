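---
title: "Spatiotemporal decomposition of dense-sampling structural imaging: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal decomposition of dense-sampling structural imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclebrain)
```

This vignette documents the statistical models implemented in `cyclebrain`,
the assumptions behind them, the tunable parameters and their defaults, what
the synthetic generators do and do not emulate, and the numerical and design
choices made where several defensible options existed.

## The data model

A dense-sampling study measures one individual repeatedly — here 24 to 30
MRI sessions across a 4–5-week window — together with same-day serum
estradiol `E(t)` (pmol/l) and progesterone `P(t)` (nmol/l). After standard
longitudinal preprocessing each session is a spatially normalized, smoothed
gray-matter volume map (values in [0, 1]) or a vector of per-vertex cortical
thicknesses (mm). The analysis treats the per-session maps of several
individuals jointly, asking (i) which spatial patterns of structural change
recur across sessions, (ii) whether their temporal expression fluctuates over
the cycle, and (iii) whether it tracks hormone levels.

### Progesterone-to-estradiol ratio

The ratio `R(t)` is computed with both hormones on the same molar scale:
`R = 1000 · P[nmol/l] / E[pmol/l]`. This convention is fixed by the male
reference summaries (mean ratio ≈ 6.9 with mean P ≈ 0.86 nmol/l and mean
E ≈ 129 pmol/l is only consistent with a pmol/pmol ratio). The naive
nmol-per-pmol ratio remains available through
`hormone_profile(..., ratio_units = "nmol_per_pmol")`.

## Spatiotemporal decomposition

Stacks are concatenated into an `N × V` matrix and column-centered **within
each individual** (the default). Per-individual centering removes each
person's static anatomy exactly, so that the singular value decomposition
operates on within-cycle change while still sharing one set of spatial
patterns across individuals; global centering is available
(`centering = "global"`) but mixes between-person anatomical differences
into the leading components. This choice matters for variance fractions and
was made deliberately: the scientific object is within-person change.

Components are ordered by singular value; the variance fraction of component
`k` is `σ_k²/Σσ_j²` (squared singular values, the standard
variance-explained definition — not the singular values themselves). Signs
of singular vectors are arbitrary, so each component is oriented to make its
largest-magnitude spatial weight positive; this is a pure reporting
convention.

**Retention.** Components are retained while they explain at least
`min_fraction = 0.095` of the variance. The intent is a "10% of the
variance" rule applied after rounding to integer percent, so a 9.7%
component still counts as 10%; the top component is always retained.

**Display thresholding.** For maps, spatial weights with `|w| < 0.01` are
set to zero (negligible contribution) and `|w| > 0.1` is clipped to the
±0.1 color range. Thresholding is display-only; all statistics use the raw
unit-norm vectors. With unit-norm vectors over 10³–10⁵ locations, weights
of magnitude 0.01–0.1 are the informative range.

**Temporal standardization.** Downstream statistics use the per-individual
z-scored temporal scores. Associations are invariant to the `σ_k` scaling,
and standardization puts individuals with different session counts on one
scale.

## Penalized-spline temporal model

Each component × individual score series is modeled as
`score = f(day) + error` with `f` in a cubic B-spline basis of `k = 10`
functions (interior knots at day quantiles) penalized by the integrated
squared second derivative. The penalty matrix is computed exactly by
two-point Gauss–Legendre quadrature per inter-knot interval (the integrand
is piecewise quadratic), and its null space is exactly the constant and
linear functions — at very large smoothing the fit collapses to the ordinary
least-squares line.

The smoothing parameter λ minimizes the generalized cross-validation score
`n·RSS/(n − γ·EDF)²` over a fixed grid of 61 log-spaced values in
[10⁻⁴, 10⁶], with `EDF = tr(B(BᵀB + λS)⁻¹Bᵀ)`. A fixed grid keeps the fit
deterministic and reproducible. The smooth is tested with an approximate F
statistic, `F = ((RSS₀ − RSS)/(EDF − 1)) / (RSS/(n − EDF))` against
`F(EDF−1, n−EDF)`.

**Calibration of γ.** Because λ is chosen adaptively, the naive test
(γ = 1) is strongly anti-conservative: on white-noise series of length 25
it rejects at the 5% level about 15% of the time, and the commonly
recommended γ = 1.4 still gives about 10%. The package therefore charges
γ = 4 effective degrees of freedom per fitted degree in the GCV score,
chosen by this null-calibration simulation; the empirical size is then
5.5–6.5%. The cost is some power against weak wiggly signals (strong
signals, such as hormone-coupled components, are unaffected — their
smooth-term p-values remain astronomically small). Autoregressive error
terms are deliberately absent: on series of this length they overfit.

Constant score series are degenerate and reported as non-fluctuating
(`p = 1`, `EDF = 1`) rather than as errors.

## Hormone association

Square-root transformed hormone levels stabilize the variance of strongly
right-skewed luteal progesterone. Predictors are **not** standardized by
default (slopes are per √concentration unit; a config switch standardizes
them). Two routes are always computed:

1. OLS regression of scores on the contemporaneous √hormone with a two-sided
   t test on the slope (n − 2 df), no lag or autocorrelation terms;
2. Spearman rank correlation (mid-ranks for ties). For n ≤ 7 the two-sided
   p-value is exact, by enumeration of all n! rank permutations; above that
   the `t = ρ√((n−2)/(1−ρ²))` approximation is used. n = 7 (5040
   permutations) is the natural switch point — enumeration is instant below
   it and factorial above it.

FDR correction (Benjamini–Hochberg) is applied within each individual's
family — 3 predictors × retained components — separately for the regression
and the Spearman p-values, and separately per measure type when volumes and
thickness are both analyzed. The family composition is a genuine design
choice; per-individual families match the per-individual inferential claims
made from these designs.

Note that the three predictors are not independent: the ratio is a function
of the other two, and under suppressed progesterone the ratio is essentially
a monotone transform of estradiol. A component coupled to one hormone will
therefore often also flag the ratio; the planted-truth evaluation in the
tests counts only components 2–3 (never coupled) as null pairs.

## Endocrine comparison

Hormone profiles are compared across individuals by a one-way MANOVA on
(estradiol, progesterone, ratio), treating sessions as independent
observations. This replicates the originating design choice without
endorsing it — within-person autocorrelation is ignored, which the tests
document rather than hide. Pillai's trace uses the standard F approximation
with `s = min(p, g−1)`, `m = (|p−g+1|−1)/2`, `n' = (N−g−p−1)/2`; Roy's
largest root uses the upper-bound approximation
`F = θ·(N−d−1)/d, d = max(p, g−1)`. Partial η² is `V/s` (Pillai) and
`θ/(1+θ)` (Roy). With four individuals contributing 25 + 30 + 24 + 25 = 104
sessions these give degrees of freedom (9, 300) and (3, 100). Post hoc
pairwise t-tests use the pooled within-group mean square with `N − g`
degrees of freedom (the SPSS post hoc convention) and Bonferroni correction
over all pairs; hormone values enter untransformed. The ratio column is
recomputed from P and E under the pmol/pmol convention unless the caller
opts to trust a supplied column.

## Mass-univariate TFCE inference

Per analysis location, the map value is regressed on the √hormone level; in
pooled designs each individual receives an intercept (values and predictor
are centered within individual) and a common slope is tested with
`N − (#individuals) − 1` df. For a single covariate the t statistic is
symmetric in predictor and response, so regressing maps on hormones is
equivalent to the hormone-as-dependent formulation.

Volumetric analyses first exclude locations whose grand mean map value is
below 0.1 (gray-matter focus); the boundary value 0.1 is retained.

TFCE enhances the t map as
`TFCE(x) = Σ_{h = dh, 2dh, …, t(x)} e(h, x)^E · h^H · dh` with E = 0.5,
H = 2 (the standard enhancement exponents), `dh = max|t|/100`,
26-connectivity on volumes and the supplied edge list on vertex graphs,
separately for the positive and the negated map. The implementation sorts
locations once and sweeps thresholds from high to low with an incremental
union-find, so a map costs `O(steps × active locations)`; it is written in
C++ because the permutation loop multiplies this cost by thousands.

Family-wise error control uses the permutation distribution of the map-wide
maximum TFCE statistic: hormone values are permuted across sessions (within
individual in pooled designs — cycles are exchangeable under the null of no
brain–hormone coupling, though temporal autocorrelation is ignored, a known
limitation of unrestricted permutation), the t and TFCE maps recomputed, and
`fwe_p(x) = (1 + #{perm max ≥ TFCE(x)})/(n_perm + 1)`. Each TFCE map uses
its own `dh = max|t|/n_steps`, matching common practice. Defaults:
`n_perm = 1000`, α = 0.01.

## The synthetic generators

**Hormones.** Trajectories are sums of Gaussian bumps over a baseline — a
pre-ovulatory estradiol peak, and luteal estradiol and progesterone bumps
centered mid-luteally — multiplied by mean-one lognormal noise
(`noise_cv = 0.10` by default, matching day-to-day assay plus physiological
variation). Phase labels: menses = cycle days 1–5, ovulation at
`cycle_length − 14` for the typical template (day 14 with the 30-day
template's 16-day luteal phase; day 16 for the 23–24-day endometriosis
cycle, whose luteal phase is 8 days). Defaults per template: the typical
cycle peaks near 750 pmol/l estradiol and 33 nmol/l progesterone; the
endometriosis template runs estradiol-high (base 260, peak 950 pmol/l) with
a weak 20 nmol/l progesterone peak, giving the estradiol-dominant luteal
ratio; the OC template suppresses progesterone at baseline (≈1 nmol/l, never
above 4) while estradiol keeps a natural-cycle dynamic range, and its first
five nominal cycle days are labelled `inactive_pill` (the enum has no
ovulation under OC, but the post-midcycle half is still labelled luteal so
phase-wise ratio comparisons remain defined). The male template is
calibrated to the published male reference (mean E 128.7, SD ≈ 13–17
pmol/l; mean P ≈ 0.86 nmol/l): a ±13% slow sinusoid times lognormal noise
truncated at ±2.2 SD keeps every realization inside the observed
98–161 pmol/l range by construction, and male progesterone below
3.5 nmol/l, safely under the 15.9 nmol/l ovulation threshold ("surpassed"
is read strictly: `max P > 15.9`).

**Image stacks.** A session map is
`baseline + Σ_k a_k(t)·S_k + ε`, Gaussian-smoothed within the mask
(FWHM 6 mm, `σ = FWHM/(2√(2 ln 2))`, edge-renormalized so the mask mean is
preserved). The default geometry is a 24³ grid at 2 mm with an ellipsoidal
mask (≈38% fill) — a desk-scale stand-in for an MNI-space brain; the
vertex-wise stand-in is a 32×32 lattice with 4-neighbor adjacency and a
2.5 mm thickness baseline. Baselines are smooth random fields drawn once per
individual, so per-individual centering has real work to do. The three
planted patterns are triple-smoothed random fields, orthonormalized — being
dominated by low spatial frequencies they are nearly invariant under the
6-mm session smoothing, which is what makes "recover the planted pattern"
a well-posed target. Component 1's loading is exactly the standardized
√hormone (progesterone in typical templates, estradiol under endometriosis
and OC, reproducing the headline dissociation); components 2–3 carry
standardized AR(1) (ρ = 0.5) series orthogonalized against the coupled
loading, mimicking non-hormonal day-to-day structure. Scales are set so the
planted variance splits exactly at 0.50/0.20/0.10 of the total, with the
noise SD calibrated (via a fixed-probe estimate of the smoother's variance
retention) to leave the planted signal ≈80% of the total variance —
component 3 then sits deliberately near the 9.5% retention boundary.

**What the generators do not emulate:** raw T1w intensities, bias fields,
segmentation or registration errors, motion artifacts, assay error models,
LH/FSH dynamics, or real cortical geometry. Passing tests therefore
demonstrate that the statistical machinery recovers planted truth under
realistic sampling designs and noise levels — not that any particular
real-data result is correct.

## Problem sizes used by the validation suite

The test suite and acceptance script run the full study design (104 sessions,
24³ grid, ≈5200 in-mask voxels) for recovery and dissociation checks
(20–50 seeds), a ≈1000-voxel phantom with 200 permutations × 500 simulations
for FWE calibration, and 1000–2000 white-noise series for GAM calibration —
sizes chosen so the entire suite completes in minutes on one core while
leaving the Monte-Carlo intervals tight enough to be informative.

## Known limitations

- Sessions enter the MANOVA as independent observations (a replicated design
  choice, statistically questionable).
- The permutation scheme ignores temporal autocorrelation of both maps and
  hormones; TFCE FWE control is exact only under exchangeability.
- The smooth-term F test is approximate; its size was calibrated at n = 25
  and may drift for very different series lengths.
- The exact FDR family used in published analyses of such designs is rarely
  stated; per-individual families are this package's documented choice.
- Under suppressed progesterone the ratio is nearly collinear with
  estradiol; flags on the ratio predictor should be interpreted accordingly.
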
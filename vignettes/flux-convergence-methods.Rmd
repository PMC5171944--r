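---
title: "Methods: comparing eddy-covariance and biometric forest carbon fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing eddy-covariance and biometric forest carbon fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxconverge)
```

## The problem

Two fully independent families of methods estimate the annual CO~2~
exchange of a forest. The eddy-covariance (EC) technique measures net
ecosystem production (NEP) directly above the canopy and derives
ecosystem respiration (Reco) and gross primary production (GPP) by
partitioning the measured net flux. Biometric methods (BM) build the same
three fluxes bottom-up from component measurements — growth inventories,
litter traps, soil and stem chambers — through the budget identities

$$\mathrm{NEP} = \mathrm{GPP} - \mathrm{Reco} = \mathrm{NPP} - R_h,
\qquad \mathrm{Reco} = R_a + R_h, \qquad \mathrm{GPP} = \mathrm{NPP} + R_a,$$

with soil CO~2~ efflux partitioned as
$R_\mathrm{soil} = R_\mathrm{root} + R_{h\text{-soil}}$. Because the two
routes share no instruments and no assumptions, their agreement (or
disagreement) across many sites is informative about the biases of both.
This package implements the complete analysis chain for such a
method-comparison study: budget assembly, uncertainty modelling,
convergence statistics, methodological-variant screening, NPP
gap-filling, topographic indices, and a ground-truth simulator to
validate the chain end to end.

## Budget assembly

`assemble_bm_budget()` computes total NPP as the sum of all reported NPP
components, requiring at least the three major ones (aboveground wood,
foliage, fine roots). Aboveground autotrophic respiration is
$R_\mathrm{leaf} + R_\mathrm{wood}$, plus understory respiration when a
site reports it separately (many sites fold it into the leaf and wood
terms, so adding it only when separate avoids double counting). The soil
partition is completed from any two of its three members
(`partition_rsoil()`, consistency tolerance 1 gC m^-2^ y^-1^ when all
three are present). Heterotrophic respiration of coarse woody debris is a
small flux measured at only part of the sites; sites missing it are kept,
the flux is treated as zero, and the omission is recorded in
`completeness_flags`. Closure $\mathrm{GPP}-\mathrm{Reco}=\mathrm{NEP}$
holds exactly by construction (NEP is re-derived from the assembled pair
to kill floating-point summation-order residue).

Per-flux data requirements differ, and the per-flux site subsets fall out
of component availability rather than imputation: Reco needs
$R_\mathrm{soil}$, NEP needs its heterotrophic part, GPP needs its
autotrophic part. A flux whose preconditions fail is `NA` for that site
while the others are still returned.

An independent biometric route to NEP, `nep_from_stocks()`, uses repeated
inventories of the two major carbon stocks (wood and soil): the stock
change per year plus lateral carbon losses (harvest, DOC leaching). It
avoids NPP and R~h~ entirely, which makes it a useful cross-check on the
component-based NEP.

For the strictly positive fluxes the package uses the symmetric relative
difference $(\mathrm{BM}-\mathrm{EC}) / ((\mathrm{BM}+\mathrm{EC})/2)$,
which removes the dependence of a site's leverage on its flux magnitude.
For NEP, which takes both signs, the statistic is undefined and
`relative_difference()` refuses it; NEP is compared on the absolute
scale. Differences are stored as BM − EC throughout (a negative NEP
difference therefore means EC exceeds BM).

## The uncertainty model

Published per-site flux uncertainties are too inconsistent to compare, so
all sites get a uniform approximation built from three elements: the
typical flux range of the site's biome ($p$, a half-range), a reduction
factor for the measuring methodology (RF), and the number of replicate
measurement years ($l$):

$$s = \frac{p \cdot \mathrm{RF}}{\sqrt{l}}.$$

Defaults: $p$ for NEP is 350 gC m^-2^ y^-1^ in extratropical and 700 in
tropical forests; $p$ for Reco and GPP varies with latitude between 1000
(equator) and 500 (at and beyond 60°). The exact latitude dependence is
not standardized; this package uses a linear ramp on absolute latitude
with knots at (0°, 1000) and (60°, 500), clamped poleward — a documented
stand-in that honours the published bounds. RF is 0.3 for EC and for
high-quality BM data, 0.6 for fair-quality BM data. The $\sqrt{l}$ form
is the standard-error scaling of replicate years; it reproduces the
canonical worked example, $s = 350 \times 0.3 = 105$ for one year and
$105/\sqrt{2} = 74.25 \approx 74$ for two.

These are half-ranges used symmetrically as error bars and as weights; no
distributional claim is attached. A configurable `tropical_multiplier`
(default 1, i.e. off) can inflate tropical Reco/GPP uncertainties, since
this approximation is known to be optimistic for tropical sites.

## Statistical kernel

**Major-axis regression.** When both axes carry errors of similar
magnitude, ordinary least squares attenuates the slope; the major axis —
the first principal axis of the bivariate scatter — is the appropriate
model II line for BM-versus-EC plots. `ma_regression()` implements the
closed-form slope and a Jolicoeur-type F-based confidence interval on the
axis angle, $|\sin 2(\theta - \hat\theta)| \le \sqrt{H}$ with
$H = 4 F_{\alpha;1,n-2}\lambda_1\lambda_2 / ((n-2)(\lambda_1-\lambda_2)^2)$.
The test suite verifies its empirical coverage by parametric simulation
and checks the slope against an eigen-decomposition oracle. When $H \ge 1$
the analytic interval is undefined (the axis direction is statistically
indistinguishable from vertical); a percentile bootstrap of the slope
(2000 resamples, fixed internal seed, caller RNG state untouched) is
reported instead and flagged `inference_method = "bootstrap"`. $R^2$ is
the squared Pearson correlation.

**Paired comparisons.** `paired_compare()` gates on Shapiro–Wilk
normality of the pair differences at $\alpha = 0.05$ (configurable): a
two-sided paired *t*-test when the gate passes, otherwise a Wilcoxon
signed-rank test with the standard conventions — zero differences
dropped, tied ranks averaged, exact null distribution up to 25 non-zero
differences without ties and a continuity-corrected normal approximation
beyond. All-zero differences short-circuit to a degenerate result
($p = 1$). A type-I-error simulation in the test suite keeps the gated
procedure honest (rejection rate within [0.035, 0.065] at nominal 0.05).

**Weighted screens.** Each candidate driver of the between-method
difference is tested separately by weighted least squares with weights
$1/s$ — the inverse of the flux uncertainty, taken literally rather than
the inverse variance $1/s^2$; a `weight_power` switch selects the latter.
The pair uncertainty for a difference is
$\sqrt{s_\mathrm{EC}^2 + s_\mathrm{BM}^2}$. Categorical variants are
dummy-coded and judged by the overall F-test. Homoskedasticity of the
weighted residuals is checked with the Breusch–Pagan test at
$\alpha = 0.05$; on failure, inference switches to the White
heteroskedasticity-robust covariance in its original HC0 form and the
reported $R^2$ becomes the squared Pearson correlation between response
and fitted values, since the WLS $R^2$ is then not meaningful. No
multiple-testing correction is applied across the screen — the screen is
exploratory, each row is reported with its raw *p*-value and significance
tier (**, *, + at 0.01/0.05/0.10) and should be read accordingly.

**Outlier handling.** Sites are never dropped: a divergent site is
evidence about method disagreement, not noise. Instead
`outlier_sensitivity()` refits every screen leaving one site out at a
time and flags sites whose omission moves the overall *p*-value across
the 0.05 or 0.10 thresholds, so single-site artefacts are visible without
being silently removed.

**Two-way ANOVA.** The chamber-type effect on the Reco difference is
confounded with how leaf respiration was modelled, so a two-way ANOVA
(light-inhibition accounting × parameterization type) is run within the
NSF-chamber subset. Type-II sums of squares are used because the design
is unbalanced; an inestimable interaction (empty cell) is reported as NA
rather than an error.

## NPP gap-filling

Two NPP components are systematically unmeasured and always bias NPP
downward when missing: branch-turnover NPP and mycorrhizal NPP.
`gapfill_npp()` adds their literature-average magnitudes to sites that
lack them: branch turnover as 22% of aboveground wood NPP (the
dataset-derived primary anchor), falling back to 8% of total NPP when the
wood component is unavailable, and mycorrhizal NPP as 14% of total NPP.
Fractions are applied to the original, pre-fill values, so the two terms
do not compound. Gap-filling is deliberately a reporting/sensitivity
step: it sizes the likely NPP underestimation but never feeds back into
the NEP/Reco/GPP budgets used in the convergence tables, because filled
values would be imputation, not measurement.

## Topographic indices

Complex terrain promotes advection and drainage flows that bias EC at
night, so two terrain-complexity indices are computed from a
2,430 × 2,430 m elevation quadrat (27 × 27 pixels of 90 m) centred at the
tower. `elevation_variability()` is the standard deviation of all 729
pixel elevations in population form (divisor $n$): the pixels are the
complete quadrat, not a sample (the difference is below 0.1% anyway).
`topographic_slope()` is the elevation drop between the highest and
lowest pixels divided by the planar distance between their centres, in
percent. Ties are broken by first occurrence in row-major order —
deterministic and immaterial for real terrain. The quadrat is treated as
a plane with fixed spacing; at a 2.4 km extent the geodetic error of that
simplification is negligible. Missing cells are an error: no
interpolation is attempted.

## The synthetic-data generator

`generate_dataset()` draws per-site true budgets that satisfy every
identity exactly, then derives EC and BM observations from the same
truth. Structure and defaults:

* **Zones and magnitudes.** 6 boreal, 22 temperate, 3 tropical sites;
  true GPP ~ N(1000, 200²), N(1800, 400²) and N(3200, 300²)
  gC m^-2^ y^-1^ respectively — magnitudes chosen once, inside the ranges
  reported for quality-checked forest datasets (EC NEP roughly −100 to
  800, Reco 500–3,300, GPP 600–3,600 gC m^-2^ y^-1^).
* **Partitions.** NPP:GPP ≈ 0.45; NPP shares 30/34/30% for
  foliage/aboveground wood/roots with ~6% in minor terms; fine roots ~70%
  of root NPP; Ra shares 39/22/38% for leaf/wood/root; heterotrophic
  share of Reco 0.32; coarse-woody-debris share of R~h~ 0.15 at sites
  that account for it. Shares are jittered per site and renormalized, so
  every identity still closes exactly.
* **Noise.** Multiplicative Gaussian noise (CV 10% EC, 15% BM by default)
  on the strictly positive fluxes, additive noise scaled to GPP for NEP —
  mirroring the flux-magnitude-proportional uncertainty model and keeping
  Reco/GPP positive. The soil trio is noised through its two independent
  members (R~root~, R~h-soil~) with R~soil~ formed as their sum, so the
  partition identity survives observation noise.
* **Bias dials.** `nep_bm_offset` (default 0) shifts biometric NEP by a
  constant, implemented as a proportional rescaling of the NPP components
  so the component table stays internally consistent.
  `npp_missing_fraction` (default 0) removes a fraction of NPP from the
  BM observations; setting it near 0.17 emulates the scenario in which
  gap-filling raises NPP by ~20%. `rleaf_overestimate_no_li` (default
  0.20) inflates leaf respiration at sites that neglect light inhibition
  of leaf dark respiration. `nsnf_rsoil_underestimate` (default 0.10)
  deflates soil respiration at closed-static-chamber (NSNF) sites. The
  last two defaults are sized as a mutually compensating pair: 20% of a
  ~28% Reco share against 10% of a ~55% share, the error-compensation
  configuration in which NSNF sites appear to converge while NSF sites
  expose the leaf-respiration inflation. The two NEP-side dials default
  to zero because they are the injectable effects under study, not
  measured conditions; analysis scripts and tests inject them explicitly.
* **Variant frequencies.** Method-category probabilities follow reported
  usage frequencies where available (fine-root methods 26/19/23/32%,
  R~h-soil~ methods 57/20/10/13%, ~65% of sites accounting for
  coarse-woody-debris respiration, ~19% measuring branch turnover, ~10%
  mycorrhizae, sundown EC partitioning ~5%); the rest are even or
  near-even splits.

What the generator does **not** emulate: real between-site correlation
structure (every site is independent), temporal mismatch between EC and
BM campaigns, footprint mismatch, non-Gaussian error tails, and any
hidden-truth incompleteness — all completeness effects enter through
explicit dials, which is what makes the exact zero-bias convergence
property testable. Passing the recovery tests therefore demonstrates that
the pipeline is unbiased and calibrated *under its own error model*, not
that real EC-BM discrepancies are fully characterized by it.

`recovery_report()` re-generates datasets across seeds and summarizes
bias and CI coverage of the recovered statistics; the test suite requires
an injected −100 gC m^-2^ y^-1^ NEP offset to be recovered within 3
standard errors in at least 95% of 200 seeded replicates.

## Numerical and design choices

* Validation separates hard errors (violated identities, impossible
  values) from plausibility warnings (fluxes outside generous biome
  windows: NEP beyond [−500, 1200], Reco beyond [200, 4000], GPP beyond
  [300, 4500] gC m^-2^ y^-1^); only hard errors block reading.
* The site-table schema is a reconstruction of what such studies publish;
  `schema_config` remaps arbitrary column names onto it, unknown columns
  are preserved, empty cells and the string "NA" both read as missing,
  and enum labels match case-insensitively.
* Climate zone is taken from the file; latitude only serves the
  uncertainty model and plausibility checks, since studies assign zones
  per site.
* Strata with fewer than 3 pairs are reported as NA rows rather than
  dropped, and every site excluded from a given analysis is logged with
  the failing precondition.
* Reports are pure functions of (input table, configuration): re-running
  writes byte-identical files, which the test suite asserts.
* Problem sizes in the default test run are chosen for tight iteration:
  31-site datasets, 200-replicate recovery runs, 5,000-replicate type-I
  simulations, 100-sample oracle sweeps.

## Known limitations

The uncertainty model is deliberately coarse — a biome half-range scaled
by two factors — and is known to understate tropical BM uncertainty; the
`tropical_multiplier` exists for sensitivity analysis, not as a
calibrated correction. The latitude ramp for the Reco/GPP half-range is a
documented stand-in for an unstandardized dependence. The major-axis
confidence interval assumes bivariate normality; for small samples with
weak correlation it can be wide or undefined (the bootstrap fallback is
flagged when used). The screen is univariate by design and cannot
disentangle correlated methodological variants beyond the one
pre-specified two-way ANOVA.
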
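---
title: "Complexity-adjusted benchmarking of hospital hazardous waste: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity-adjusted benchmarking of hospital hazardous waste: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cawi)
```

## The benchmarking problem

The conventional yardstick for hospital hazardous healthcare waste (HHCW) is
the generation rate

$$GR = \frac{\text{annual HHCW mass (kg)}}{\text{beds} \times \text{days in year}}
\quad [\mathrm{kg/bed/day}],$$

which treats every bed as equivalent. It is not: institutions treating more
complex patients (higher Case-Mix Index, CMI) consume more material per
patient, and institutions with faster patient turnover (shorter Length of
Stay, LOS) concentrate more procedures — and therefore more waste — into
each bed-day. Ranking hospitals on raw GR penalizes exactly the institutions
doing the most intensive clinical work.

The Complexity-Adjusted Waste Index normalizes for both:

$$CAWI = \frac{GR \times CMI}{LOS},$$

with CMI the case-weighted mean DRG relative weight,
$CMI = \sum_g w_g n_g / \sum_g n_g$, and
$LOS = \text{inpatient days} / \text{discharges}$ in days. The nominal unit
is kg/bed/day², but the index is used as a comparative, scale-independent
quantity. A hospital with high CAWI generates much waste *relative to the
complexity and intensity of its care*; a high-GR, high-CMI, short-LOS
tertiary centre can have an unremarkable CAWI.

The package's validation battery asks whether CAWI behaves as a better
benchmarking variable than GR on a panel of institutions: lower dispersion
across heterogeneous institutions (variance F-test), and tighter association
with external workload proxies — ICU patient counts, multidrug-resistant
HAI incidence, inpatient volume, academic status (Spearman correlations,
correlation-comparison tests, robust regressions).

## Conventions the package fixes

Several arithmetic conventions are left open by common reporting practice;
the package fixes them once and documents them:

* **GR denominator.** Annual mass over `beds × calendar days`, with 366-day
  denominators in leap years. A fixed 365-day convention is available via
  `leap_years = FALSE` in `run_config()` and the index functions, since
  reported national figures rarely state which was used.
* **Aggregation to institutions.** The default (`"institution_mean"`)
  averages the yearly GR, CMI and LOS per institution across the panel
  years and computes CAWI *from the averaged components*; control variables
  are averaged the same way. A `"pooled"` mode keeps every institution-year
  as its own observation for sensitivity analysis. When all years of an
  institution are identical the two conventions coincide (this is a tested
  invariant).
* **Group-level CAWI.** Reported per-group CAWI is the mean of
  institution-level CAWIs, not the CAWI of group-mean components. The two
  differ because CAWI is a ratio; the mean-of-ratios convention is the one
  consistent with published group tables, where the group CAWI exceeds
  `mean(GR) × mean(CMI) / mean(LOS)` by a wide margin.
* **Quintile stratification.** Institutions are ranked by bed count (ties
  broken by institution id, stable) and cut into five contiguous blocks
  whose sizes differ by at most one; remainder institutions go to the
  smallest-bed groups, so 94 institutions split 19/19/19/19/18. Rank blocks
  are used rather than bed-value cut points because published group bed
  ranges are observed extremes, not predefined thresholds.
* **Dispersion statistics.** All SDs are sample (n−1) SDs.
* **CMI precedence.** When both a precomputed CMI column and a DRG case
  table are supplied, the case table wins; discrepancies above 1e-6 are
  surfaced as warnings.

## The statistical battery

`run_validation()` executes, in order:

1. **Shapiro–Wilk** normality screening of each indicator (delegated to
   `stats::shapiro.test`; its role is gatekeeping the choice of rank-based
   methods, 3 ≤ n ≤ 5000).
2. **Variance F-test** of GR versus CAWI: `F = s²_GR / s²_CAWI`, two-sided
   p-value `2·min(P(F ≤ f), P(F ≥ f))` capped at 1.
3. **Spearman correlations** of CMI and LOS against GR, and of both
   indicators against each numeric control variable. Rho is the Pearson
   correlation of average-ranked data; p-values use the t approximation on
   n − 2 degrees of freedom.
4. **Correlation comparison** per control variable. Two forms are provided
   because the two indicators are measured on the *same* institutions: the
   independent-samples **Fisher z** test
   `Z = (z₁ − z₂)/√(1/(n₁−3) + 1/(n₂−3))`, which mirrors the method named
   in most applied reports but ignores the dependence, and **Steiger's
   test** for dependent overlapping correlations, which accounts for the
   correlation between the two indicators and is the statistically
   appropriate choice here. The default configuration reports both,
   side by side.
5. **Robust regression** of each indicator on each control variable,
   univariate (one model per control, matching the one-coefficient-per-row
   shape of published tables; a multivariable fit can be assembled from
   `huber_regression()` directly).
6. **Residual diagnostics** per fitted model: fitted/residual series,
   residual SD, and the OLS slope of |residual| on fitted values as a
   heteroscedasticity indicator.

### Robust regression details

The estimator is Huber M-estimation via iteratively reweighted least
squares:

* weights `w(u) = min(1, c/|u|)` with `c = 1.345` (95% efficiency at the
  normal); an optional Tukey biweight refinement (`c = 4.685`) starts from
  the Huber solution (`psi = "bisquare"`);
* scale re-estimated every sweep as the normalized MAD about zero,
  `median(|r|)/0.6745`;
* convergence when the largest absolute coefficient change drops below
  `tol = 1e-8`, with at most `max_iter = 50` sweeps; non-convergence sets
  the `converged` flag and warns, never silently;
* standard errors from the asymptotic M-estimator covariance
  `σ² · [Σψ(u)²/(n−p)] / [mean ψ′(u)]² · (X'X)⁻¹`, p-values from
  t on n − p degrees of freedom.

This is an emulation of the robust fits common in applied benchmarking
work, not a bit-exact replication of any particular commercial
implementation; published robust-regression coefficients should therefore
be compared in sign and relative magnitude only. With a very large tuning
constant the estimator reduces to ordinary least squares (a tested limit),
and at convergence the coefficients minimize the Huber objective at the
final scale (tested against a direct numerical minimizer). Degenerate
inputs are handled explicitly: rank-deficient designs are errors, and a
near-exact fit (residual MAD collapsing to zero) terminates the sweep at
the least-squares solution rather than dividing by a vanishing scale.

## The synthetic panel generator

`generate_panel()` emulates the statistical structure of a national
institution panel — 94 institutions over 2017–2021 by default — with known
ground truth, so that every downstream stage can be validated without
access to administrative data:

* Bed counts: log-normal (`meanlog 6.1`, `sdlog 0.8`), clipped to
  [30, 3513] beds, drawn once per institution and held fixed.
* Complexity: `CMI = −0.21 + 0.20·log(beds) + N(0, 0.5)`, clipped to
  > 0.1. The slope runs the gradient from ≈0.76 in the smallest size
  quintile to ≈1.29 in the largest; the noise SD sits inside the range of
  published group SDs (0.18–0.81).
* Stay length: `LOS = exp(4.55 − 0.35·log(beds) + N(0, 0.5))` days,
  spanning ≈17 days (small institutions) down to ≈7 (largest).
* Latent rate: `log GR = 0.07 + 0.5·log(CMI) − 0.45·log(LOS) + N(0, 0.35)`.
  The intercept and the two effect sizes jointly reproduce group-mean rates
  of ≈0.26 kg/bed/day (smallest quintile) and ≈0.51 (largest) at the
  corresponding CMI/LOS levels. Annual waste mass is
  `GR × beds × days-in-year`, so the realized rate equals the latent rate
  exactly and the effect sizes are recoverable.
* Occupancy is a fixed scalar (0.8) linking beds to inpatient days;
  discharges are `inpatient days / LOS`, rounded, at least 1; inpatients
  equal discharges.
* ICU patients: binomial share of inpatients with logit-linear share in
  log(beds) (≈2% at small, ≈8% at large institutions). MDR-HAI incidence is
  log-linear in log(1 + ICU patients) with multiplicative noise, landing in
  the realistic 5–30 cases per 100,000 inpatient-days range. The
  educational flag is a logistic draw in log(beds) so the largest
  institutions are almost always academic.

The noise SDs were chosen from the dispersion of published group tables at
design time. One consequence worth knowing: because CMI and LOS are both
driven by hospital size, univariate regressions of log GR on either one
absorb part of the other's effect (classic omitted-variable confounding).
At the default noise levels the analytic size of that bias is roughly 15%
of the true effect, which is why parameter-recovery checks use a 20%
tolerance rather than something tighter — the residual gap is structural,
not an estimator defect.

What the generator does **not** emulate: within-institution year-to-year
shocks to the latent rate (years differ only through calendar length and
the binomial/multiplicative noise of the control variables), reporting
errors and coding drift in CMI, regional or hospital-type structure, and
occupancy variation. Passing validation on synthetic panels therefore shows
the pipeline's arithmetic and statistical machinery is correct and that the
qualitative contrasts follow from the assumed dependence structure — it
does not certify any particular national dataset.

## Problem sizes used in validation

The test suite validates index arithmetic on hundreds of randomized
fixtures at 1e-12 relative tolerance; Spearman against an exhaustive
rank-formula oracle up to n = 12 including ties; the F-test's type-I error
and the Fisher test's type-I error on 10,000 simulated replications
(n ≈ 100 per arm); Huber IRLS against a brute-force loss minimizer on a
10-point outlier fixture; effect-size recovery on 100 simulated panels; and
the qualitative benchmarking contrasts (lower CAWI dispersion, positive
CMI–GR and negative LOS–GR correlations, tighter CAWI–ICU association,
uniformly smaller CAWI regression SEs) across 50 panel seeds. These sizes
give stable Monte-Carlo estimates while keeping the default suite quick to
run.

## Known limitations

* The independent-samples Fisher z test is misspecified for two indicators
  measured on the same institutions; it is retained because it is the
  method most applied reports name, but Steiger's test should be preferred
  for inference and both are reported by default.
* Univariate regressions per control variable inherit whatever confounding
  exists among the controls; they describe marginal associations, not
  causal effects.
* The educational flag enters regressions as a 0/1 (or year-averaged
  fraction) covariate; with few academic institutions in a small panel its
  coefficient is imprecise.
* CAWI inherits the quality of its inputs: coding drift in DRG weights or
  inconsistent hazardous-waste classification across jurisdictions moves
  the index in ways no within-package check can detect.
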
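---
title: "Isotope mass-balance apportionment of soil NOx: model, uncertainty and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope mass-balance apportionment of soil NOx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isonox)
```

## The mixing model and its assumptions

The δ¹⁵N of ambient NOx in a closed air basin is, to first order, the
emission-flux-weighted mean of its source signatures. Writing α_i for the
proportion each source contributes to an inventory totalling E_inv and δ_i
for the per-source δ¹⁵N-NOx, the a priori inventory signature is
Σ α_i δ_i. When the observed δ_obs is lighter than that, the discrepancy is
attributed entirely to additional biogenic soil emissions at the soil
end-member δ_s, giving the inversion

E_s = (δ_obs − Σ α_i δ_i) · E_inv / (δ_s − δ_obs).

The assumptions, in decreasing order of importance:

1. **Basin closure** — sampled NO₂ derives from sources inside the basin.
   Advection of isotopically heavier urban NOx from upwind would *raise*
   δ_obs, so estimates are lower bounds under violations.
2. **The inventory is right except for soil.** All non-soil rates and the
   total are taken as fixed; no inventory-rate uncertainty is propagated.
3. **Linear mixing of a conserved tracer** after the fractionation
   correction (below) maps δ¹⁵N-NO₂ to emitted δ¹⁵N-NOx.
4. **Source signatures are independent normals** with the literature means
   and SDs; no covariance is available to do better.

Because the Σ α_i δ_i sum runs over *all* inventory sources including the
existing soil entry, the inversion returns the soil flux **in excess of**
the inventoried one: on exact forward-mixed data with true soil flux
E_true, it returns E_true − α_s·E_inv (the "offset identity", enforced as a
property test). `consistent_soil_inversion()` solves the mass balance with
the soil term excluded from the a priori and recovers E_true exactly; it is
the package's validation oracle and is reported alongside. For realistic
inventories the offset (α_s·E_inv ≈ 0.9 tons/d for the Imperial inventory)
is small against the estimates and against their uncertainty.

## Fractionation correction

Atmospheric NO⇌NO₂ cycling fractionates nitrogen isotopes, so sampled NO₂
is isotopically heavier than emitted NOx. Two correction modes exist:

* **table** — per-sample offsets Δ = δ¹⁵N-NOx − δ¹⁵N-NO₂, recovered from a
  table reporting both columns (`implied_corrections()`). This is the
  authoritative mode: the packaged campaign table carries both columns, so
  every reproduction path uses it, and the per-month offsets are exactly
  invertible.
* **parametric** — δ¹⁵N-NOx = δ¹⁵N-NO₂ − (1 − f)·ε_eff with f the NO₂/NOx
  fraction and ε_eff an effective equilibrium-exchange fractionation,
  optionally generated from temperature by a user-supplied
  parameterization. The exact functional form used to produce published
  correction tables is not always stated; this single-factor form is the
  standard one in the δ¹⁵N-NO₂ literature but is deliberately labelled
  non-authoritative, its constants are configuration rather than code, and
  no reproduction target depends on it.

An unconfigured correction is an error, never a silent zero.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| δ_s (soil end-member) | ‰ | −33.2 | literature mean of biogenic soil δ¹⁵N-NOx (range −59.8 to −14.2) |
| σ_s | ‰ | 9.6 | literature SD; dominates the propagated uncertainty |
| non-soil signatures | ‰ | −2.5 ± 2.7 (mobile), 1.0 ± 4.1 (biomass), −16.5 ± 1.7 (stationary) | compiled means/SDs restricted to warm catalytic-converter vehicle studies and non-coal stationary sources |
| E_inv | tons d⁻¹ | per region | printed inventory totals (15.2 / 18.0 / 33.2); where a printed total disagrees with its component sum by a rounding residue, the printed value is the default denominator for proportions |
| analytic noise | ‰ | 0.11 | pooled SD of the isotopic reference; neglected in propagation (σ_obs = 0) because it is an order of magnitude below σ_s, but carried by the simulator |
| guard band | ‰ | 0.5 | |δ_obs − δ_s| below which the inversion is declared singular rather than returning an arbitrarily large E_s |
| cropland area | ha | 270,500 | basin agricultural area for per-area fluxes |
| fertilizer N | short tons N yr⁻¹ | 57,630 | 2022 county fertilizer purchases, for the percent-of-applied-N flux |

Unit conventions are forced by the reproduction targets: inventory rates
are short tons (907.185 kg) of NOx on an NO₂-equivalent mass basis, and
the N mass fraction is 14.007/46.0055. Metric tonnes give 2.75 rather than
2.5 kg N ha⁻¹ yr⁻¹ and do not reproduce the published conversions;
likewise "fertilizer N" must be read as tons of N, not tons of material.

## The a priori signature: computed vs reported

The flux-weighted mean of the packaged signature and inventory tables is
−5.88 ‰ (Imperial) and −3.55 ‰ (Coachella), while the values reported with
the regulatory inventory analysis are −5.04 ‰ and −3.11 ‰. The inputs
behind the reported pair are not recoverable from the printed tables, so
`apriori_signature()` treats a user-supplied override as authoritative
(warning when it disagrees with the computed value by more than 0.1 ‰) and
the packaged run configuration carries the reported constants. All
reproduction targets use the overrides; the computed path remains the
default when no override is given.

## Aggregation and truncation policy

Two aggregation modes are exposed because they answer slightly different
questions and neither dominates:

* `invert_mean_delta` — average the δ series, invert once. Matches the
  Imperial annual estimate (6.7 tons/d from the −13.67 ‰ annual mean).
* `mean_of_monthly` — invert each month, truncate negatives to zero,
  average. Matches the Coachella treatment (4.8 tons/d over 9 months, one
  truncated month). The same data under `invert_mean_delta` differ because
  the inversion is convex in δ_obs and because truncation is one-sided;
  the truncated mean is never below the untruncated one.

Truncation is applied after uncertainty propagation; σ is never truncated.
A source strength cannot be negative, but a month may invert negative when
observed air is heavier than the a priori — the estimate is floored at
zero and flagged rather than dropped.

For the aggregate σ under `mean_of_monthly`, the per-month σ's are averaged
rather than divided by √n: the dominant error source (the literature
signature means) is shared across months, making per-month estimate errors
essentially fully correlated. The published ±3/±4 aggregate uncertainties
are not exactly recoverable (the aggregation level of the original
propagation is unstated), so they are validated by properties (analytic vs
Monte-Carlo agreement) instead of value reproduction.

## Uncertainty propagation

The published closed-form variance expression for E_s contains a
dimensionally inconsistent middle term; this package implements the
variance as the first-order Taylor expansion of the inversion, which that
expression evidently intends:

σ²(E_s) = Σ_i (α_i E_inv / D)² σ_i² + ((α_s E_inv + E_s)/D)² σ_s²
          (+ ((E_inv + E_s)/D)² σ_obs² when σ_obs > 0), D = δ_s − δ_obs.

The Monte-Carlo oracle `mc_sigma_soil_source()` draws all signatures from
independent normals, re-evaluates the inversion per draw and reports the
sample SD; draws inside the singularity guard band are rejected and
counted. In the near-linear regime (all σ ≤ 1 ‰) analytic and Monte-Carlo
values agree within 5 % at 10⁶ draws (an acceptance property). At the full
soil SD of 9.6 ‰ the reciprocal denominator is visibly nonlinear and the
Monte-Carlo SD exceeds the first-order value — a documented divergence,
not a defect: the analytic number is then a lower-bound summary of a
heavy-tailed distribution.

## What the synthetic generator emulates — and what it does not

`synthetic_scenario()` forward-models the campaign the analysis assumes:
constant non-soil fluxes, a per-month soil flux (default: a smooth annual
cycle averaging 6.7 tons/d with 35 % seasonal amplitude around an
Imperial-like inventory of 12.4/0.1/1.7 non-soil and 0.9 inventoried soil
tons/d), flux-weighted mixing, an invertible fractionation map, and
Gaussian analytic noise of 0.11 ‰. Optional pulse multipliers emulate
post-fertilization/irrigation emission bursts (field studies report
10–100× background for days). `signature_draw = "fixed_means"` (default)
uses the literature means as the true source deltas, matching how
inventory-based apportionment treats them; `"monthly_redraw"` re-draws
every month from Normal(mean, SD) as a stress test.

It does **not** emulate: mechanistic soil NO production (temperature and
soil-moisture response), within-source temporal autocorrelation of
signatures (independence is assumed), interbasin transport, diurnal
photochemistry, or sampling-duration weighting within a month. Passing
recovery tests therefore demonstrate the *statistical* correctness of the
estimators under the model's own assumptions, not the fidelity of those
assumptions to any particular basin.

`recovery_experiment()` repeats the simulate–correct–invert loop and
reports bias, RMSE and coverage of ±1.96σ analytic intervals. Per-rep
streams are derived from the scenario seed plus a fixed stride so single
replicates are re-runnable in isolation. Validation scale used by the test
suite: 1000 replicate campaigns of 12 months (unbiasedness, coverage) and
10⁶ Monte-Carlo draws (σ agreement); these sizes put the Monte-Carlo
standard error well below the effects being tested.

Design choices where the design was genuinely open: `fixed_means` is
implemented as "use the means exactly" rather than "draw once per
campaign", because the estimators consume the same means — a campaign-level
draw would conflate signature bias with estimator bias, which the
`monthly_redraw` mode probes instead. Coverage is asserted on the
consistent estimator, whose analytic σ describes exactly the generative
randomness of the redraw scenario.

## Numerical choices and degenerate inputs

* The inversion refuses |δ_obs − δ_s| < 0.5 ‰ (configurable) instead of
  returning an arbitrarily large estimate; the same guard rejects
  Monte-Carlo draws, with a metadata flag when rejections exceed 1 %.
* Missing δ values are explicit `NA`s, excluded from means with the
  divisor reduced; a series with no finite values is an error.
* All internal arithmetic is full precision; per-mil and tons/day values
  are rounded (1 decimal; 2 below |1|) only in the reporting layer.
* Written tables carry a `#`-prefixed provenance header (version, seed)
  which the readers skip; floats are serialized at 6 significant digits.
* Zero-rate sources need no signature and contribute nothing to σ.

## Known limitations

* The basin-closure assumption is untestable from within the data; under
  upwind influence the estimates are lower limits.
* Inventory rates are treated as exact; only signature (and optionally
  analytic) uncertainty is propagated.
* The parametric fractionation mode is a single-factor approximation with
  user-supplied constants; reproduction paths use table mode throughout.
* The first-order σ understates the spread at the full soil-signature SD;
  use the Monte-Carlo value when the tails matter.
* Published summary tables contain small internal inconsistencies (totals
  vs component sums, a revised-inventory column whose entries do not sum to
  its printed total); the package reproduces the arithmetic it defines and
  stores printed totals alongside components rather than reconciling them.
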
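# isonox

Nitrogen stable-isotope source apportionment of biogenic soil NOx
emissions.

## The problem

Regulatory NOx emission inventories in agricultural air basins are built
around combustion sources, yet microbially produced soil NO (nitrification,
denitrification — the "leaky pipe") can be a major, poorly inventoried
contributor to ambient NOx, ozone and PM2.5. Nitrogen isotopes make the
soil contribution observable: microbial NO production strongly favours the
light isotope, so biogenic soil NOx is far more ¹⁵N-depleted (δ¹⁵N ≈ −33 ‰)
than mobile (≈ −2.5 ‰), biomass-burning (≈ +1 ‰) or stationary (≈ −16.5 ‰)
sources. Ambient δ¹⁵N-NO₂ lighter than the inventory's flux-weighted mean
signature therefore implies the inventory is missing soil emissions — and
by how much.

`isonox` is for atmospheric chemists and air-quality scientists who run
denuder-based δ¹⁵N-NO₂ campaigns and want a tested, reproducible pipeline
from monthly isotope tables to revised emission inventories.

## The model

Let α_i be the proportion each source contributes to an inventory totalling
E_inv (short tons NOx d⁻¹, NO₂-equivalent mass), δ_i the literature source
signatures, δ_s the biogenic-soil end-member and δ_obs the observed
(fractionation-corrected) δ¹⁵N-NOx. The soil source strength solves the
flux-weighted isotope mass balance:

    E_s = (δ_obs − Σ_i α_i δ_i) · E_inv / (δ_s − δ_obs)

Negative solutions (observed air heavier than the a priori mixture) are
truncated to zero. Source-signature uncertainty is propagated analytically
by a first-order Taylor expansion of E_s and cross-validated by a
Monte-Carlo oracle. Because the Σ α_i δ_i term includes the inventory's own
soil entry, E_s is an increment over the inventoried soil flux; the exact
mass-balance solution for the *total* soil flux is provided as
`consistent_soil_inversion()` and used as the estimator-validation oracle.

The package also converts apportioned emissions into agronomic units
(kg N ha⁻¹ yr⁻¹ over the basin's cropland; percent of applied fertilizer N)
and ships a synthetic-campaign simulator (`synthetic_scenario()` /
`recovery_experiment()`) that forward-models monthly flux-weighted
mixtures, fractionation and 0.11 ‰ analytic noise to measure estimator
bias, RMSE and interval coverage.

## Worked example

Apportion the packaged Coachella Valley (Thermal) campaign month by month
against the 2022 regulatory inventory, with the reported a priori
inventory signature of −3.11 ‰ and the soil end-member −33.2 ‰:

```r
library(isonox)

s   <- field_samples()                      # packaged monthly delta15N table
coa <- cepam_inventory("coachella")         # 18.0 tons/d a priori inventory
thermal <- s[s$site == "Thermal", ]

res <- apportion_series(
  thermal$delta_nox, apriori = -3.11,
  e_inv = inventory_total(coa), delta_soil = -33.2,
  policy = apportionment_policy("mean_of_monthly"),
  labels = format(thermal$period_start, "%b %Y"),
  inventory = coa, signatures = default_signatures())
print(res)
```

```
Soil NOx apportionment (a priori -3.11 permil, E_inv 18.0 tons/d, soil end-member -33.2 permil)
     label delta_obs e_soil_raw e_soil truncated    sigma
1 Jul 2022     -16.1       13.7   13.7     FALSE 8.132689
2 Aug 2022      -8.0        3.5    3.5     FALSE 2.190018
...
5 Nov 2022       0.2       -1.8    0.0      TRUE 1.377703
...
aggregate (mean_of_monthly): 4.8 tons/d +/- 3.1
```

Each row inverts one month: July's very light −16.1 ‰ implies 13.7 tons/d
of soil NOx, while November's +0.2 ‰ (heavier than the a priori) inverts
negative and is truncated to zero. The aggregate 4.8 tons/d is roughly
fifty times the 0.1 tons/d the inventory carries for this valley; `sigma`
is the per-month analytic uncertainty from the literature signature SDs
(soil ±9.6 ‰ dominates).

`report_bundle()` runs the whole pipeline on the packaged fixtures — both
sites, inventory revision, unit conversions and the NO₂–tNO₃ correlation —
and prints, among others: Imperial annual soil NOx 6.7 tons/d
(= 2.5 kg N ha⁻¹ yr⁻¹ over 270,500 ha, 1.3 % of applied fertilizer N) and
a revised basin inventory in which soil rises from 3 % to ~26 % of total
NOx.

A thin command-line wrapper is installed at `inst/cli/isonox`
(subcommands `apportion`, `simulate`, `recover`, `convert`, `report`).

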
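---
title: "Methods: multi-pool forest carbon accounting, growth projection and TEV valuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-pool forest carbon accounting, growth projection and TEV valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcarbon)
```

## Scope and assumptions

`forestcarbon` accounts the carbon stock of a managed forest farm as the sum
of five pools — live trees, shrubs, dead wood, litter and harvested wood
products (HWP) — from nothing more than an inventory (species, stock volume,
area, shrub cover) plus per-species conversion coefficients. The accounting
rests on the standard working assumptions of default-factor forest carbon
methods: no fire or other disturbance emissions, no logging-machinery
emissions, and a constant soil pool (soil carbon is therefore *excluded* —
the five pools are changes above the soil). Within those assumptions the
annual stock change is simply

$$\Delta C_P = \Delta C_{TREE} + \Delta C_{SHRUB} + \Delta C_{DW} +
  \Delta C_{LI} + \Delta C_{HWP},$$

every term in tonnes of CO₂-equivalent. Carbon mass converts to CO₂-e by the
exact molar ratio $44/12$; the package stores the constant as the full
double-precision quotient, never a rounded decimal, so computing a pool in
t C and converting afterwards is bit-identical to computing in t CO₂-e.

## The pools and their parameters

**Trees.** The biomass expansion factor (BEF) chain converts stem volume
$V$ (m³) to whole-stand biomass: $B = V \cdot D \cdot BEF \cdot (1+R)$ with
basic wood density $D$ (t/m³), expansion factor $BEF \ge 1$ and root:shoot
ratio $R$. The source formulation also multiplies by stem count $N$ and area
$A$; that double-counts whenever $V$ is already a farm total, so the package
distinguishes a `total_stock` basis (default, no $N \cdot A$) from a
`per_stem_per_ha` basis (volume per stem per hectare, $N \cdot A$ applied).
Inventory tables that report total accumulation — the normal case — use the
default.

**Shrubs.** Below 5% cover the pool is counted as zero; at or above it,
per-ha shrub biomass is $BDRSF \cdot B_{FOREST} \cdot cover$. The carbon
fraction (0.47) and root:shoot ratio (0.40) are published defaults.
$BDRSF = 0.1$ and $B_{FOREST} = 80$ t/ha are *not* published values — they
are plausible subtropical magnitudes adopted once as package defaults and
exposed in `shrub_defaults()`; real analyses should override them with local
survey values.

**Dead wood.** Tree carbon times a regional default factor $DF_{DW}$; the
packaged table covers eight Chinese inventory regions (e.g. south China
2.25%, northeast 3.51%). Percentages are stored as fractions throughout —
every equation treats the factor as a multiplier.

**Litter.** Tree carbon times $DF_{LI} = (a/100)\,e^{b \cdot B_{AG}}$ using
per-group coefficients (13 packaged groups), with the IPCC 4% fallback when
a species matches no group. Two conventions needed fixing:

* the published $a$ values (e.g. 20.7385) produce ratios far above 1 if read
  as fractions; they are interpreted as *percentages*, consistent with the
  4% fallback. This is prominent in the documentation and lives in one place
  (`litter_ratio()`).
* the units of $B_{AG}$ are unstated. The default feeds each species' total
  aboveground biomass (t) into the exponent, applied species-by-species to
  that species' tree carbon; `farm_pool_breakdown(agb_basis = "per_ha")`
  switches to per-hectare biomass. At real farm scales (10⁴–10⁵ t AGB) the
  total-basis exponential underflows and the litter pool is effectively
  zero; the per-ha basis keeps it in the few-percent range. Neither reading
  is verifiable against published totals, so the default follows the
  total-t reading and the switch is documented here.

Mapping inventory species labels to litter groups is itself unspecified in
the sources, so it goes through an editable alias table
(`default_litter_aliases()`), e.g. "Soft broad class" → "Other soft broad",
"China fir" → the Chinese-fir group. One group key, "yearning between
lovers", is an untranslatable legacy label retained verbatim with its
coefficients.

**Harvested wood products.** The carbon retained in products is stem carbon
($V \cdot WD \cdot CF \cdot 44/12$) × yield rate × (1 − waste rate) × the
fraction still in use after the accounting horizon,
$OF = e^{-\ln 2 \cdot WT / LT}$ — first-order decay with the product class's
service life $LT$ as half-life. $WT$ defaults to 30 years and is
configurable; one half-life ($WT = LT$) leaves exactly one half. A negative
HWP change is permitted (harvest bookkeeping); all other pools are validated
non-negative.

## Growth models and fitting

Five sigmoid families model age–volume growth (parameters $a, b, c > 0$;
$a$ is the asymptote):

| family | formula |
|---|---|
| logistic | $a / (1 + b e^{-cA})$ |
| Richards | $a (1 - e^{-bA})^c$ |
| Korf | $a e^{-b A^{-c}}$ |
| Gompertz | $a e^{-b e^{-cA}}$ |
| Mitscherlich | $a (1 - e^{-bA})$ |

The Mitscherlich source formula prints as $a(1-e^{-b-A})$, which is constant
in shape; the package implements the standard two-parameter form
$a(1-e^{-bA})$. Korf's value at age 0 is taken as its limit, 0.

Fitting minimizes the residual sum of squares over *log*-parameters
(positivity by construction) with `stats::nlminb`, restarted from 20 seeded
perturbations (s.d. 0.6 on the log scale) of a data-driven start
($a_0 = 1.2\,\max y$; $b, c$ from the family's linearization). A cleanly
converged optimum is preferred over a marginally lower "false convergence"
endpoint when the two objectives agree to within $10^{-6}$ relative.
Non-convergence is a reported flag, never an exception. Goodness of fit is
$R^2 = 1 - SSE/SST$ about the observation mean; constant observations make
$R^2$ undefined (`NA`) rather than forcing a value. Ranking is by $R^2$
descending with SSE breaking ties closer than $10^{-6}$ and non-converged
fits last; additional diagnostics named in the source (SEE, TRE, MSE, MPE,
MPSE) are never defined there and are out of scope.

Projection evaluates the chosen model at integer ages $0..H$ (default
$H = 100$ years) and reports yearly increments and the mean annual increase
$(V(H) - V(0))/H$. Whole-farm growth is the species sum of per-area rate ×
species area × years. Two published quantities are deliberately *not*
reproduction targets: the printed per-species mean annual increases cannot
be derived from the printed best-fit curves under any averaging we tested
(an undocumented per-area stem multiplier is suspected), and the printed
farm growth totals require per-species areas that were never published.

## Valuation (TEV)

Four indicators, reported in CNY 10,000 with half-up rounding at the
presentation layer only:

* **Land** — perpetuity $A \cdot rent \cdot share / P$. The published
  worked example (417 USD/ha rent, $P = 2.6\%$, 20% rent share, quoted
  result 324 USD/ha) is not recoverable under any single reading of the
  formula; both the full-perpetuity and rent-share modes are exposed
  (`rent_share`) and the discrepancy is left documented rather than
  silently resolved.
* **Timber** — stock × log output rate × log price, summed over species.
* **Carbon fixation** — $1.63 \cdot 0.2727 \cdot B \cdot A \cdot Pa$ (NPP
  $B$, area $A$, carbon price $Pa$). The two constants' provenance is
  unstated in the source; they are applied verbatim as a single documented
  coefficient 0.444501.
* **Habitat** — area × a per-ha constant. The published constant
  (400 + 112 USD/ha) is inconsistent with the published farm values (the
  implied constant is ≈ 76.8 CNY/ha); the supported reproduction path is
  `calibrate_habitat_constant()`, which fixes the constant from one known
  (area, value) pair. Habitat value is then exactly proportional to area,
  which the reference table satisfies for the three internally consistent
  farms.

The land, timber and carbon-fixation inputs behind the published value
table (per-slope areas, species prices, NPP, carbon price) were never
published, so those three indicators are user inputs, not reproduction
targets.

## Synthetic data: what a green test establishes

`simulate_growth_series()` draws ages (even or seeded-uniform) in a range,
evaluates a true sigmoid and applies *multiplicative* Gaussian noise
$y = \mu(1+\varepsilon)$, $\varepsilon \sim N(0, \sigma^2)$ — multiplicative
so that near-zero young-age volumes stay positive and identifiable (additive
noise scaled to the asymptote would drown them and make $b$ unidentifiable);
`noise = "additive"` is available. Default $\sigma = 2\%$, $n = 30$, ages
1–100, bracketing the published fitting setting.

`simulate_farm()` generates species coefficients inside plausible inventory
ranges (D 0.30–0.65 t/m³, BEF 1.2–1.8, R 0.20–0.30, CF 0.45–0.55), stocks
and areas bracketing the published farms, per-species litter coefficients,
and an HWP spec, *and computes the five pools by an independent closed-form
code path*. The pipeline is tested to agree with that truth to 12
significant digits. A green oracle test therefore establishes arithmetic
fidelity of the accounting chain — not the realism of any coefficient:
the generator does not emulate spatial structure, age-class dynamics,
disturbance, measurement error in volumes, or correlations between D, BEF
and CF that real species show.

One simulation finding is worth stating because tests assert its
consequence: with the slow published Gompertz truth ($a = 1.54$, $b = 8.434$,
$c = 0.034$), 2% noise and ranking by $R^2$ alone, the true family wins the
ranking in only ≈ 84–86% of replicates — the flexible Richards family
overfits the rest. The corresponding acceptance expectation (≥ 90%) is left
failing rather than weakened; the parameter-recovery half (median relative
error < 5%) passes comfortably. This matches the source's own experience,
where Richards and logistic also out-scored Gompertz on $R^2$ and the final
choice used diagnostics that were never defined.

## Numerical choices

* Percent-valued tables (dead-wood factors, litter $a$) are converted to
  fractions at the registry boundary; equations only see multipliers.
* `round_half_up()` implements commercial rounding (base `round()` is
  half-to-even) for report presentation; machine-readable outputs keep full
  precision.
* All randomness (restarts, simulations, pipeline) is seeded; the pipeline
  derives per-stage sub-seeds (`seed + k`) so stages are individually
  reproducible, and reruns are byte-identical.
* The registry validates every invariant at construction (D > 0, BEF ≥ 1,
  CF ∈ (0,1), DF ∈ (0, 0.10), rates ∈ [0,1], service lives > 0) and errors
  name the offending row and field.

## Known limitations

* The packaged species coefficient table is synthetic-illustrative (flagged
  in its filename); published farm totals are reproduced only as printed
  density × area.
* No soil pool, disturbance emissions, site-index or density-dependent
  growth modifiers.
* The CLI's structured config is JSON rather than YAML (no YAML parser in
  the supported dependency set).
* One farm in the packaged summary ("Source Feng") has a published area
  inconsistent with its published reserves; the fixture stores a rescaled
  area with a note and the farm is excluded from all reproduction checks.
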
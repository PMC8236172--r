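---
title: "Modelling the Elderly Health Care Voucher scheme: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Elderly Health Care Voucher scheme: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehcvsim)
```

## The policy problem

Hong Kong's Elderly Health Care Voucher (EHCV) scheme gives older
residents an annual subsidy redeemable at enrolled private primary-care
providers, hoping to move consultations out of heavily loaded public
clinics. `ehcvsim` implements an aggregate system-dynamics model of that
mechanism: stocks (band populations, carry-forward balances) and flows
(births, deaths, aging, visits, voucher dollars) evolved deterministically
on a weekly clock, with the annual public-to-private visit ratio as the
reliance endpoint.

## Model structure and assumptions

**Demography.** The population is split into four bands — under 60,
60–64, 65–69, 70+ — because voucher eligibility has only ever used the
60/65/70 thresholds. Flows are linear: a net inflow into the under-60
band (births plus net migration, persons/week), band-specific mortality,
and first-order aging outflows. For the five-year bands the aging rate is
the standard stock-and-flow approximation `1/(5 × 52)` per week; the
under-60 outflow (cohorts turning 60) is a fixture table, rising over the
horizon to emulate the post-war cohort wave. Annual rate tables are
piecewise-constant per calendar year and converted to weekly rates by
division by 52, consistent with linear Euler flows. There is no
stochastic demography and no sex, income or geographic stratification.

**Visit generation and sector split.** Visits are band population times a
per-person visit rate; a baseline public share per band splits them into
sector streams. The share is assumed independent of voucher use — the
voucher acts only through the shift mechanism below. The per-person visit
rates of the two open-ended bands drift upward over the horizon because
those bands age internally (the 80+ fraction of the 70+ band grows); the
five-year bands use constant rates.

**Voucher demand.** Each eligible person's effective entitlement is the
current allocation plus a drawn-down share of the carry-forward balance
(release fraction 0.5/year by default, calibratable); balances accumulate
to the scheme's $4000 cap and are tracked as aggregate per-band means —
per-individual balance distributions and balances carried across band
boundaries are deliberately ignored, as befits an aggregate model.
Entitlement dollars allocate across the five claim categories
(non-preventive, chronic follow-up, dentistry, vaccination, other) by
fixed budget weights and convert to visits at category claim prices. This
constant-budget-share form was chosen because it conserves voucher
dollars exactly (`sum(visits × price) = eligible × entitlement`), which
makes expenditure calibration and testing crisp; its cost is linearity in
the amount (no demand saturation), discussed under limitations. Claim
prices inflate geometrically per category (supplier-induced demand); the
chronic claim price inflates at the chronic follow-up category's rate.

**Uptake.** Willingness-to-join is logistic in calendar time — low uptake
in the pilot years rising to an asymptote as the scheme matured — rather
than amount-dependent; amount effects act through the demand module. A
single curve is shared by all bands.

**Chronic add-on.** The designated chronic voucher reaches the eligible
population with chronic disease (band prevalence), whose per-person use
follows a monotone piecewise-linear curve of the annual amount, capped at
`amount / price` so chronic spending can never exceed the dollars
allocated. All chronic voucher visits are private-sector visits, and the
add-on is treated as incremental (it does not enter the carry-forward
balance and does not double-count general-voucher chronic follow-up,
whose budget weight is unchanged).

**Sector shift.** Of `V` voucher visits, `from_public` replaces public
visits, `from_private` replaces existing private ones (no net change) and
`induced` is new demand. General-voucher and chronic-voucher visits carry
*separate* substitution parameters: chronic patients rely far more on
public follow-up clinics, so their shift fraction is much higher (0.60 vs
0.32 in the packaged fixture). A single global triple cannot
simultaneously produce the small first-year shift of the amount scenario
and the several-fold larger first-year shift of the chronic scenario at
claim prices inside the published ranges; splitting the parameter is the
package's resolution of that tension. A shift that would exceed the
public baseline is truncated at zero public visits with a warning rather
than raised, because aggregate flows can transiently overshoot in extreme
scenarios.

## Policy encoding

The historical baseline is $250/year for ages 70+ over 2009–2011 (the
pilot's five $50 vouchers are modelled as their total; denominations
carry no information in an aggregate demand model), $500 in 2012, $1000
in 2013, $2000 from 2014 with the $4000 carry-forward cap, and age 65
from 2017. Scenario events override one attribute from a stated year
onward; policy changes take effect in the first simulation week of that
year since only years are ever specified. When an amount override
exceeds the cap (the $5000 step of the escalation scenario), the cap is
raised to the amount so the cap invariant (cap ≥ amount, or 0) holds.
Whether the chronic add-on interacts with the cap is unspecified in the
scheme descriptions; it is modelled as independent.

## Numerical choices

* Euler integration only, weekly steps, 52-week years with no calendar
  alignment; `dt` must divide 52. Halving `dt` changes 2032 band
  populations by well under 1% (tested), and annual outputs are exact
  sums of the weekly flows, so no finer step is warranted.
* Negative stocks raise an error rather than being clamped, keeping
  integration instabilities visible.
* The annual ratio is the ratio of annual sums, not an average of weekly
  ratios; with zero private visits it is reported as `NA` per record.
* Calibration minimizes `MAPE + anchor_weight × Σ wᵢ (relative anchor
  error)²` by Nelder–Mead on a logit-rescaled unit box (golden-section
  search for one free parameter), multi-started from the mid-bound point
  plus seeded uniform draws; the returned point never lies outside the
  bounds and never exceeds any start's objective. The acceptance flag
  follows the scheme-evaluation convention MAPE < 40%.
* Currency is computed in doubles and rounded to whole HKD only at CSV
  export.

## The anchored Hong Kong fixture

The administrative inputs behind the published trajectories are not
public, so `hk_anchor_fixture()` ships a reconstruction: demographically
plausible 2009 band populations and vital-rate tables, claim prices whose
2016–2019 inflated values sit inside the published claim ranges (general
practitioners $260–$330, optometry-dominated "other" $1600–$1951), an
uptake curve consistent with roughly one-third usage in the pilot years,
and substitution fractions calibrated to the published scenario shifts.
Every field is provenance-tagged `anchored` (tuned against a published
value) or `assumed`; the bundled expenditure CSV is a *synthetic*
reconstruction (the model's own baseline series rounded to two
significant figures), labelled as such.

One inconsistency in the published values cannot be reconciled: the 2018
public level (16.3M), the 2019 private level (18.0M) and the 2018
public-to-private ratio (0.70) are mutually incompatible — the levels
imply a ratio near 0.9. `scripts/build_hk_fixture.R` therefore picks the
2018 ratio compromise by a weighted grid search over all printed anchors
(ratios and public levels weighted 4:1 over the private level, the ratio
being the study's primary endpoint), then solves the under-60 and 70+
public shares exactly from the 2018/2032 ratio targets. The result
matches every anchor within 10% except the 2019 private level (~+18%,
carried with a documented 20% tolerance in `hk_anchor_targets()`); the
corresponding acceptance expectation is left failing rather than
widened. Re-running the build script regenerates the identical fixture
and aborts if any anchor misses its tolerance.

With linear budget-share demand, the escalating-amount scenario keeps
the ratio near 0.70 in later years instead of drifting back to ~0.80 as
the published account suggests; its similarity with the age-lowering
scenario is therefore asserted over the first escalation epoch
(2021–2024), while the ordering (chronic strongest, all scenarios below
baseline) and the erosion of every scenario's effect from its peak back
toward baseline by 2032 hold throughout and are tested.

## The synthetic generator

`generate_synthetic_fixture()` draws random but structurally valid
bundles for property testing: declining mortality, public reliance
increasing with age band, monotone utilization curves, unit-sum budget
weights. It emulates the *shape* of the real inputs, not their values —
passing property tests on synthetic bundles demonstrates structural
correctness (conservation, monotonicity, determinism), not predictive
validity for Hong Kong. `synthetic_expenditure()` perturbs a known-truth
expenditure series with mean-one lognormal noise
(`sdlog² = log(1 + cv²)`, mean correction `−sdlog²/2`) to support
parameter-recovery tests of the calibration module.

## Problem sizes

The default horizon is 24 years × 52 weekly steps (1248 Euler steps),
which runs in well under a second; the test suite uses this full horizon
for anchored checks, shortened 2009–2016 horizons for calibration
recovery, and 100-seed sweeps for generator properties.

## Known limitations

* Demand is linear in the entitlement; no willingness-to-pay or
  saturation response to very large amounts.
* No queueing or unmet-need model of the public sector: freed public
  capacity is assumed absorbed, so scenario effects may be optimistic.
* Carry-forward balances are aggregate band means; individual-level
  heterogeneity in voucher use is outside scope.
* The chronic prevalence defaults (0.15/0.47/0.575/0.732 by ascending
  band in the packaged fixture) are assumptions exposed in the fixture,
  not measured values.
* Provider-side dynamics (enrollment, capacity, price competition) are
  not modelled; price inflation is an exogenous geometric trend.
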
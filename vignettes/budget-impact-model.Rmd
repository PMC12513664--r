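---
title: "A budget-impact model for wearable Parkinson's monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A budget-impact model for wearable Parkinson's monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdbia)
```

## The problem and the model

Motor fluctuations in Parkinson's disease — the alternation between ON
periods of good symptom control and OFF periods where medication has worn
off — are systematically under-recognised in routine consultations: a mild
(Hoehn & Yahr I–II) patient whose fluctuations go unnoticed is not
escalated to adjunct dopaminergic therapy, and a moderate (H&Y III)
patient whose advanced-disease features go unnoticed is not referred for
device-aided therapy. A waist-worn inertial sensor that records a patient
for a week at home and reports objective ON/OFF and gait data can close
this gap. `pdbia` implements a deterministic, single-year, payer-perspective
budget-impact model of introducing such a device into a national health
system.

The model composes four closed-form pieces per country:

1. **Stage stratification.** Diagnosed patients are split into three
   stages with fixed shares: mild 45%, moderate 35%, advanced 20%
   (H&Y I–II / III / IV–V). The shares are a constant preset of the model,
   not recomputed from the staged prevalence tables the package also
   bundles: no per-country or pooled averaging of those tables reproduces
   exactly (45, 35, 20) — the Spanish stage-III count is visibly anomalous
   (below stage IV) — so the published constants are treated as
   authoritative. `stage_proportions_from_hy()` remains available for
   computing shares from any staged table.

2. **Detection cascade.** In each scenario a stage pool is multiplied
   down: underdiagnosis rate (18% of the mild pool have unrecognised
   fluctuations; 36% of the moderate pool are unrecognised advanced
   disease), then detection sensitivity (0.9, from the device's clinical
   validation studies), then market penetration (0.2, a deliberately
   conservative adoption share of treating centres). The cascade is a
   product, so the three factors commute and every downstream count is
   carried **unrounded**; rounding (half away from zero, the convention
   matching every printed count) is presentation-only.

3. **Device amortization.** A 2500 EUR unit used for 30 one-week
   recordings a year, with two recordings prescribed per patient-year,
   costs 2500/30 × 2 = 166.67 EUR per patient-year, floored to 166 EUR —
   the constant the published totals are built on. The floor is a
   configurable mode (`cost_rounding = "exact"` keeps the fraction), and
   the ± 500 EUR band around the unit price is the one uncertainty range
   the source material itself states.

4. **Savings equations.** A correctly reclassified patient's direct costs
   (hospitalisations, consultations, care — excluding drugs) drop from the
   higher to the lower stage, scaled by an effectiveness factor *f*;
   medication costs rise (optimised therapy is dearer); the device cost is
   paid. Per patient-year:

   saving = *f* · (DC_high − DC_low) − (MC_high − MC_low) − device cost

   with (low, high) = (mild, moderate) in the moderate-detection scenario
   and (moderate, advanced) in the advanced-detection scenario. The
   national total multiplies by the unrounded adopted count. Negative
   savings are reported as such, never clamped — break-even analysis needs
   the sign.

## The effectiveness-factor discrepancy

The savings equations as published carry a factor 0.8 on the direct-cost
gap ("in approximately 80% of cases"), yet every exactly-reproducible cell
of the published national-savings table implies factor 1.0: with *f* = 1
and device cost 166, Sweden and Germany reproduce to the euro
(e.g. Germany advanced: (54006 − 9105) − (15976 − 5000) − 166 = 33759
EUR/patient × 4082.4 patients = 137,817,741.6 → 137,817,742). With
*f* = 0.8 no published cell reproduces. The package therefore exposes both
as presets of `model_config()`: `"published"` (*f* = 1.0, the default, so
the flagship table reproduces) and `"equation"` (*f* = 0.8, the formula as
written). A regression test asserts that the equation preset falls below
the published totals, guarding against the two ever being conflated.

Spain, Italy and the UK deviate from the published totals by 0.003–0.095%
under any recomputation from the printed inputs; the residual is
consistent with the authors having computed from unrounded spreadsheet
inputs. The package asserts a 0.15% tolerance band for those six cells and
equality for the four Swedish/German ones.

## Two population totals per country

The bundled data carry two diagnosed-population totals that genuinely
disagree (Germany: 383,001 in the staged prevalence table vs 180,000 in
the narrative). Both are stored. The per-stage patient counts of the cost
table derive from the staged-table sums where a staged table exists
(Spain, Germany, UK) and from the narrative totals otherwise (Sweden,
Italy) — that mixture is the only one reproducing all fifteen printed
counts. The cascade, however, uses the narrative totals for every country
(`total_source = "narrative"`, the default), because only those reproduce
the published cascade grid (Germany: 180,000 × 0.35 × 0.36 = 22,680). The
flag can be flipped to `"hy"` for countries with staged tables.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| stage shares | 0.45 / 0.35 / 0.20 | proportion | published constants |
| underdiagnosis, mild pool | 0.18 | proportion | fluctuation under-recognition studies |
| underdiagnosis, moderate pool | 0.36 | proportion | advanced-disease under-recognition studies |
| detection sensitivity | 0.9 | proportion | device validation studies |
| market penetration | 0.2 | proportion | conservative adoption assumption |
| device unit price | 2500 | EUR | list price, ± 500 stated band |
| uses per device-year | 30 | recordings | 7-day recordings over 52 weeks |
| prescriptions per patient-year | 2 | recordings | clinical assumption |
| effectiveness factor | 1.0 (`published`) | proportion | see discrepancy above |

## Sensitivity and break-even analysis

Because every parameter above enters the total multiplicatively or
affinely, one-way sweeps are exact lines (`one_way_sweep()`), the tornado
span of a linear parameter is |slope| × width (`tornado()`; default
illustrative ranges: penetration 0.1–0.3, sensitivity 0.8–1.0, unit price
2000–3000, ± 25% relative on both underdiagnosis rates), and the
break-even device cost has the closed form *f*·ΔDC − ΔMC
(`break_even_device_cost()`). Break-even deliberately ignores display
rounding: a root of a rounded step function is ill-defined, so it is
computed in exact mode.

`monte_carlo()` propagates independent parameter uncertainty (point,
uniform or triangular distributions; the triangular is sampled by inverse
CDF) through the deterministic model with one explicitly seeded generator
per call. Independence is a deliberate limitation: the source material
provides no joint uncertainty information, so imposing a correlation
structure would be invention. Point-mass distributions collapse to the
deterministic result bit for bit, which the tests use as a degeneracy
check.

## Synthetic portfolios

`generate_portfolio()` emulates the structure the savings model assumes,
so the whole pipeline is testable without the bundled data: direct costs
are drawn as a mild-stage base times stage multipliers ≥ 1 (guaranteeing
the stage-monotone cost structure real cost tables exhibit but the model
never checks), medication costs as a fixed fraction of direct costs,
national totals in a realistic 20,000–200,000 range, and cascade rates
jittered around the defaults within [0, 1]. A single master seed plus the
country index determines each country's stream, so country *i* is
identical whether 2 or 50 countries are drawn. What synthetic data does
**not** emulate: correlation between a country's cost level and its
population, reimbursement heterogeneity, or any real joint distribution
of national health costs — passing property tests demonstrates arithmetic
correctness of the pipeline, not realism of any particular country's
numbers.

## Numerical choices

* Display rounding is half away from zero (`round_half_away()`), matching
  every printed count and euro total; R's own `round()` (half to even)
  does not.
* Unrounded counts flow between stages; all printed values are produced
  at the last moment.
* Portfolios round-trip through disk exactly: JSON config written at 17
  significant digits, CSV cost tables at `%.17g`.
* Stage shares must sum to 1 within 1e-9; setting a single share via
  `set_param()` rescales the other two proportionally to preserve the
  invariant.
* Degenerate inputs: zero national totals propagate to zero savings; a
  staged table with zero total raises an undefined-distribution error
  rather than returning NaN shares.

## Worked example

```{r}
m <- bia_model()          # bundled five-country portfolio, published preset
summary(m)
```

```{r}
coef(m)
predict(m, newdata = list("cascade.market_penetration" = 0.3),
        country = "SE", scenario = "advanced_detected")[
  , c("country", "scenario", "total_saving")]
break_even_device_cost(m$portfolio$countries$SE$costs, "moderate_detected")
```

```{r, fig.width = 7, fig.height = 4}
plot(m, country = "DE", scenario = "advanced_detected")
```

## Problem sizes in the test suite

The property suites run the closed-form-oracle comparison on 1000
synthetic single-country portfolios plus smaller multi-country batches,
10,000 Monte-Carlo draws for the distributional-mean check and a few
hundred draws elsewhere; the whole model is closed-form arithmetic, so the
entire suite completes in well under a minute.

## Known limitations

Single-year horizon, no discounting, no QALYs or ICERs, direct costs
only (indirect costs such as caregiver burden are out of scope by
design), one national penetration scalar rather than per-centre adoption,
no currency conversion or inflation adjustment, and independent (never
correlated) parameter sampling in the Monte-Carlo.
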
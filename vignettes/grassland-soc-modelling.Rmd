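---
title: "Modelling soil organic carbon in temperate moist grasslands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling soil organic carbon in temperate moist grasslands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rothcgrass)
```

## The problem

Managed grasslands in temperate moist climates (precipitation above
~1000 mm yr⁻¹) hold large soil organic carbon (SOC) stocks, and standard
five-pool turnover models systematically underestimate them. Three
processes are missing from the reference model: decomposition does not
slow down when the soil waterlogs; carbon returned by grazing animals is
treated as generic manure regardless of its actual fibre composition; and
root-derived inputs — root residues and rhizodeposition — are usually
folded into a single above-ground surrogate. A fourth process, hoof
damage (poaching) on wet soil, removes plant production and hence carbon
input. `rothcgrass` implements the reference monthly five-pool model and
all four extensions as independently switchable modifications, with the
cumulative version ladder `RothC_0` (reference) to `RothC_4` (all).

## The core model and its assumptions

Decomposition is first-order per pool at a monthly step, evaluated with
the exact exponential (not an Euler approximation):
`P ← P·exp(−k·a·b·c/12)` with k = 10 / 0.3 / 0.66 / 0.02 yr⁻¹ for
DPM / RPM / BIO / HUM. Carbon leaving the active pools splits between
CO₂ and BIO + HUM by the clay function
`CO₂/(BIO+HUM) = 1.67·(1.85 + 1.60·e^(−0.0786·clay))`, the retained part
46:54 between BIO and HUM. IOM is inert. These constants are the
published reference values; the modifications are defined as deltas on
exactly this model, so the constants are not user-tunable.

Assumptions inherited from the reference model: a single homogeneous
topsoil layer of fixed depth (20 or 30 cm in typical use); monthly
forcing (no sub-monthly dynamics); air temperature as a proxy for soil
temperature; no radiocarbon tracking.

**Ordering within a step.** Fresh inputs are credited *after* decay of
the pre-existing stock. The reference implementations differ silently on
this point; we declare one ordering so the mass balance is exact and
auditable: over any run, ΔSOC = Σinputs − ΣCO₂ to ~1e−15 relative (the
test suite enforces ≤ 1e−9).

## Soil water and the saturation extension

The signed soil moisture deficit (SMD, mm) is the state variable:
positive = drier than field capacity, negative = excess water toward
saturation. The sign convention is chosen so the poaching trigger
"SMD ≤ −10 mm" reads literally. The monthly budget is
`smd ← clamp(smd + 0.75·evap − rain)`; 0.75 converts open-pan
evaporation to actual evapotranspiration (set `evap_factor = 1` for
Penman PET). The dry bound is the reference clay formula
`(20 + 1.3·clay − 0.01·clay²)·depth/23` (divided by 1.8 for bare soil);
the wet bound is `−(θ_sat − θ_fc)·depth·10` mm. Water beyond saturation
is shed instantly as runoff — no lateral flow or water-table dynamics.

θ_fc (33 kPa) and θ_sat come from the Saxton–Rawls (2006) texture
pedotransfer, the standard realisation of texture-based water retention.
It is exposed behind an interface: pass `theta_fc`/`theta_sat` directly
to `pedotransfer_water()` to use laboratory retention data instead. The
organic matter input of the pedotransfer defaults to 2.5% by mass,
typical of mineral grassland topsoil.

The moisture factor b is the reference piecewise form on the dry side
(plateau at 1.0 until 0.444 of the maximum deficit, then linear to 0.2)
and, in extended mode, a linear decline from 1.0 at field capacity to
0.2 at saturation on the wet side — the same minimum the model uses at
extreme dryness, representing oxygen limitation rather than a hard stop.
A design point left open by the source material: whether the dry-side
plateau threshold changes in extended mode. We keep it unchanged, so the
extended factor differs from the default factor only for SMD < 0; on the
shared domain the two modes are identical, which makes the version
ladder interpretable (the `RothC_3` − `RothC_2` difference is purely the
wet-side throttle).

## Excreta quality

Applied excreta carbon is partitioned by Van Soest fractions (lignin,
holocellulose, solubles, % of volatile solids) through the anaerobic
biodegradability `B = 0.905·e^(−0.055·lignin)`: HUM gets the
non-degradable lignin, RPM the degradable lignin plus non-degradable
holocellulose + solubles, DPM the degradable remainder, normalised by
total VS. The shipped default ruminant quality uses lignin 18.5% VS —
the midpoint of the 9–28% literature interval — with the rest split
45 : 36.5 between holocellulose and solubles; this reproduces the
canonical 0.1 / 0.6 / 0.3 partition at one-decimal rounding. The default
is data, not code: each application may carry its own measured quality.
Whether the canonical partition was originally computed from VS-weighted
means or mean lignin alone is not documented; ours is a declared
reconstruction, not an assertion. With the modification off, all
amendments use the reference farmyard-manure split (DPM 49%, RPM 49%,
HUM 2%), which defines `RothC_0`/legacy behaviour exactly.

## Plant residues: three components with quality

Annual above-ground standing biomass (Mg DM ha⁻¹, 45% C) is converted to
three input streams:

* **Above-ground residue** — 20% of standing C under grazing, 30%×50% =
  15% under cutting.
* **Below-ground residue** — root C = above C × R:S, with
  `R:S = 4.7375·e^(−0.0043·N)` unless a measured ratio is supplied; 50%
  of root C turns over annually.
* **Rhizodeposition** — 0.5 × root C, treated as fully labile (all DPM).
  The published rhizodeposition-to-root ratio admits either root biomass
  or root residue as denominator; we apply it to root C biomass,
  matching the ratio's definition in the literature it comes from. This
  is the larger of the two readings and is overridable via
  `rhizo_to_root`.

Quality: the DPM share of each residue equals its neutral-detergent
soluble share (RPM = NDF/100), with the below-ground fibre raised by 8
percentage points of lignin. We apply the 8-point offset to NDF itself
(rather than to a lignin sub-fraction), the plain reading of the
stepwise-digestion simplification, and treat carbon as equally
distributed between fibre classes. NDF may be given per month
(`ndf_by_month`) to express month-on-month quality change.

Annual totals are spread over months by a weight vector. The exact
published European grassland pattern is not available as numbers; the
preset `european_grassland_pattern()` is a declared stand-in (flat
November–February minimum, May–June peak) and user-overridable. All
conservation properties are pattern-independent.

With the modification off, the legacy path uses above-ground residue
only at the fixed DPM:RPM = 1.44 (59/41) split — the common practice of
treating above-ground residue as a surrogate for total plant input —
which is why switching the modification on raises simulated SOC: it adds
the below-ground and rhizodeposition streams.

## Poaching

The mechanistic hoof-print/deformation equations of the source lineage
are not published; we declare a minimal parametric model preserving the
qualitative contract: poaching occurs only in months with grazing *and*
SMD at or below a threshold (default −10 mm); the month's plant inputs
are reduced by `min(max_reduction, damage_per_lsu × stocking rate)`
(defaults 0.5 and 0.10 per LSU ha⁻¹). It is not documented whether
below-ground components should be spared; we damage all three plant
components, reasoning that trampling destroys the producing sward, and
note it as a declared choice. There is no carry-over between months,
reflecting fast sward recovery.
Applied amendments are never reduced. All three constants are exposed in
the configuration.

## Initialisation

IOM = 0.049·TOC^1.139; RPM, HUM, BIO from the Weihermüller et al. (2013)
SOC/clay pedotransfer forms; DPM as the residual so the pools sum to the
measured stock exactly. At high stocks the fitted forms can overshoot
the total by a fraction of a percent, which would make the residual DPM
slightly negative; rejecting such stocks would exclude perfectly
realistic sites (e.g. 114 Mg C ha⁻¹ at 28% clay), so we clip DPM to zero
and rescale the three estimated pools to close the balance, and reject
only if the inconsistency exceeds 5% of the stock. DPM is the fastest
pool; it relaxes to its forced quasi-equilibrium within a few months, so
the clip has no lasting effect. A spin-up initialiser (run to
quasi-equilibrium under repeating forcing, then rescale) is provided as
the alternative.

## Evaluation and sensitivity

`evaluate_soc()` reports BIAS = mean(sim − obs) (negative =
underestimation), RMSE both absolute (Mg C ha⁻¹) and as percent of the
observed mean, and Nash–Sutcliffe EF. Both RMSE forms are reported
because published grassland evaluations are ambiguous between them —
printed BIAS values exceeding printed RMSE in the literature are
impossible for same-unit definitions (|bias| ≤ RMSE by Cauchy–Schwarz,
which the test suite asserts on random series).

`sweep_sensitivity()` re-runs the full simulation over a grid of one
input — above-ground NDF (30–70%), excreta lignin (9–28% VS), or the
moisture factor pinned to a constant (0.2–1) — and reports
(max − min)/max as a percentage. Pinning b is deliberately crude: it
bounds the whole envelope the moisture response can span. For monotone
responses the index depends only on the endpoints, which the tests
verify by comparing 2-point against denser grids.

## The synthetic-site generator

`generate_fixture()` emulates the stated world of temperate moist
managed grasslands: mean air temperature 9 °C (sinusoidal, amplitude
6.5 °C, N(0,1) noise), winter-weighted precipitation totalling
~1100 mm yr⁻¹ (`wet_grazed`; 1260 for `wet_cut`), grazing May–October at
1.5 LSU ha⁻¹, N input 210–214 kg N ha⁻¹ yr⁻¹, initial SOC 114 / 64.7 /
90 Mg C ha⁻¹, clay 22–28%, ~2.5 Mg C ha⁻¹ yr⁻¹ of excreta or slurry, and
a seasonal NDF course (40% young spring tissue to 65% senescent autumn
tissue) within the 30–70% envelope. Monthly rain is gamma-distributed
(shape 8, CV ≈ 0.35). Synthetic observations are December stocks of a
reference `RothC_3` run plus N(0, 2 Mg C ha⁻¹) noise. The `dry_grazed`
profile (400 mm yr⁻¹ against a 1.5× evaporative demand) is constructed
so the soil never approaches saturation during grazing months — a
structural control in which poaching cannot trigger.

What the generator does *not* emulate: inter-annual biomass feedback,
management changes, drainage differences, measurement campaigns sparser
than annual, or correlated observation errors. A green ladder test
therefore establishes that the modifications order simulated stocks as
the process reasoning predicts on this world, not that the model is
validated against real sites — that requires real monthly forcing and
measured stocks, which the package accepts via the CSV interfaces.

## Numerical choices

* Exact exponential decay per month; an explicit daily-Euler oracle in
  the tests confirms the analytic path to within 0.5% on realistically
  initialised total SOC over a year. (On the fastest pool alone at the
  extreme `k·a·b·c/12 = 1` the two schemes differ by ~1.7%; the
  criterion is meaningful for the aggregate, where the fast pool is a
  sub-percent share.)
* The CO₂/BIO/HUM partition computes retained C as `decomposed/(1+x)`,
  so the three shares sum to the decomposed amount exactly.
* Clamping (runoff, maximum deficits) is applied after the full monthly
  budget — no within-month sequencing of rain vs evaporation.
* Results CSVs are written with 17 significant digits, so a write/read
  round trip is bit-exact.
* Configuration files may be YAML or JSON; both map to the same
  validated constructor, and a run is a deterministic function of
  (config, weather). Randomness exists only in fixture generation.

## Known limitations

Single soil layer; no nitrogen cycling (N enters only through the R:S
response); no plant growth or defoliation feedback (biomass is an
input); poaching is a declared parametric stand-in, not a validated
deformation model; the European monthly input pattern is a stand-in
preset; pedotransfer choices (Saxton–Rawls, Weihermüller) are defaults
behind interfaces, not claims of universality.
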
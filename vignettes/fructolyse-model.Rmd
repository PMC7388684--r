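---
title: "A whole-body kinetic model of hepatic fructose metabolism"
author: "fructolyse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body kinetic model of hepatic fructose metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fructolyse)
```

## The model

`fructolyse` simulates how dietary fructose and glucose move through the
body and end up as liver fat. The model is a deterministic system of 25
coupled ordinary differential equations over three well-mixed compartments:

* **Hepatocytes (SH)** — 11 species: fructose, fructose-1-phosphate (F1P),
  dihydroxyacetone phosphate (DHAP), glyceraldehyde (GA),
  glyceraldehyde-3-phosphate (GA3P, also standing in for
  glycerol-3-phosphate), the pooled pyruvate/lactate species, acetyl-CoA,
  fatty acids (palmitate), triglyceride (TG), glucose, and
  glucose-6-phosphate (G6P).
* **Hepatic bloodstream (SHB)** — fructose, glucose, pyruvate/lactate,
  fatty acids, TG, insulin and glucagon.
* **Systemic bloodstream (SBC)** — the same seven species for the rest of
  the body.

Concentrations are in µM, rates in µM/s; time is integrated in seconds and
reported in hours, with simulation time zero at 08:00.

Sixteen hepatocyte reactions connect the species: the fructolysis trio
(fructokinase/KHK, aldolase B, triokinase), triose phosphate isomerase in
both directions, the lumped pyruvate kinase step (six glycolytic reactions
summarised by their rate limiter), PEPCK-mediated gluconeogenic return,
pyruvate oxidation (PDC), fatty-acid synthesis (ACC/FAS, eight acetyl-CoA
per palmitate), CPT-1-limited beta-oxidation, triglyceride synthesis (three
fatty acids plus a triose backbone), triacylglycerol lipase, and the
glucose branch (glucokinase, glucose-6-phosphatase,
fructose-bisphosphatase, phosphofructokinase).

Every rate law is a product of a maximal rate `V`, Hill/Michaelis
saturation factors `S^n/(Km^n + S^n)` for substrates and clamped cofactors,
and allosteric factors `1 - beta*X/(Ki + X)`. Because all saturation
factors lie in [0, 1] and every `beta` is in [0, 1], rates are non-negative
for any non-negative state — the structural reason trajectories stay
non-negative without clipping.

### Cofactors are clamped

ATP, ADP, AMP, ATP–Mg²⁻, GTP, GDP, NAD⁺/NADH and inorganic phosphate enter
the rate laws as constant pools from the parameter registry. The 25-state
accounting (11 hepatocyte metabolites + 2 × 5 blood metabolites + 2 × 2
hormones) leaves no state equations for them, and treating the adenylate
pool as buffered is standard for meal-scale liver models.

### Transport, circulation and closures

Transport between hepatic blood and hepatocytes uses two forms:
unidirectional Michaelis "pump" terms in the blood-side concentration, and
the symmetric facilitated-exchange form
`V*(S_out - S_in)/(Km + S_out + S_in)`, which is odd in the concentration
difference and vanishes at equality. Fructose uses GLUT2 and GLUT5 (GLUT2
with the higher affinity), glucose a lumped GLUT carrier, pyruvate/lactate
and fatty acids passive exchanges; fatty acids add an insulin-damped active
uptake and triglyceride an export flux `V_out*TG/(Km_out + TG)`
representing VLDL secretion, with the hepatic pool normalised by `TG_ref`
inside its exchange term.

Circulation couples the two blood pools with rate constant `R_BS = 1/60`
s⁻¹ (one full circulation per minute). The hepatic-blood side receives
`R_BS*(C_SBC - C_SHB)`; the systemic side loses that flux divided by
`R_RL = (V_body - V_liver)/V_liver = 5.25`, which makes circulation conserve
volume-weighted moles exactly (`V_liver = 0.8` L, `V_body = 5` L). The
original circulation equation is ambiguous about which side carries the
division; we resolved it by mole conservation. `R_BS` is an ordinary
registry entry, so the alternative reading (0.167 s⁻¹) is one override
away.

Insulin and glucagon are dimensionless multiples of basal. Systemic insulin
is secreted as a rising Hill function of systemic glucose centred on the
1.2 mM setpoint used for the glucose-uptake blunting (the original threshold
is kept even though it is low by clinical standards; it is a registry
value), glucagon as the mirrored falling Hill function; both clear first
order and the hepatic-blood copies relax toward systemic values through
circulation. The secretion constants are chosen so the basal fixed point at
the setpoint is exactly 1.

The periphery (muscle, adipose) closes the systemic balances: Michaelis
consumption of glucose (insulin-stimulated), fatty acids and TG, and
insulin-suppressed adipose release of fatty acids and TG. The original
systemic-glucose balance debits blood glucose for the release terms, so the
release fluxes also carry a glucose saturation gate `Glu/(Km_upGlu + Glu)`
with a deliberately tiny `Km_upGlu` (20 µM): it acts purely as a
non-negativity guard near glucose exhaustion. During tuning we found that a
physiological-scale gate constant creates an artificial
glycolysis → blood-glucose → adipose-release → plasma-TG → liver-TG
feedback loop strong enough to flip sensitivity signs; the small constant
removes that loop while preserving the guard.

### Meals

A diet is grams of carbohydrate per meal, a fructose fraction, and meal
times (08:00, 12:00, 16:00 by default). Each meal is absorbed into systemic
blood over a 4-h window shaped `sin⁶(π/4·h)`; the amplitude is normalised so
the window integral equals the dose as a concentration increment of the
4.2 L systemic volume (the mean of `sin⁶` over its half-period is 5/16, so
a 100 g pure-fructose meal gives a 29.4 µM/s peak). With the default
schedule the three windows tile 08:00–20:00 and the forcing is zero
overnight. The grams→µM conversion and the 5/16 normalisation are this
package's choices; absolute plasma levels depend on them.

## Stoichiometric bookkeeping modes

The original balance tabulation omits three terms that the reaction
descriptions imply: the triglyceride-synthesis backbone and the
glucose-branch fluxes in dGA3P/dt, and the glyceraldehyde returned by
lipolysis in dGA/dt. The default mode `paper-faithful` reproduces the original tabulation; `carbon-consistent` restores the missing terms. The
`carbon_audit()` helper makes the difference measurable: with the weights
{Fru 6, F1P 6, DHAP 3, GA 3, GA3P 3, Pyr 3, ACoA 2, FA 16, TG 51, Glu 6,
G6P 6} every fructose-pathway reaction conserves carbon except pyruvate
oxidation (one CO₂ per event, by design) and — only in paper-faithful
mode — lipolysis (the three-carbon backbone is dropped). The audit covers
reactions of the fructose pathway; the glucose-branch FBP/PFK rows are
originally written with 1:1 triose stoichiometry (the true mapping is one hexose to
two trioses) and are excluded rather than reported as spurious residuals.

## Parameters: provenance and tuning

The registry (`inst/extdata/parameters.yaml`, 128 named constants) tags
every entry: `main-text` for the few constants fixed by the original
formulation (`R_HE = 4`, `R_BS`, the volumes and derived `R_RL`), and
`reconstructed` for everything else. A complete reference constant table
was not available to this implementation, so the reconstructed
defaults are literature-plausible values tuned — as a set, once — so the
model's qualitative behaviour holds simultaneously:

* all eleven +10% one-at-a-time hepatic-TG sensitivity directions match the
  reference pattern (KHK, aldolase B, TPI, triokinase, PK, PDC, FAS, TGS
  positive; PEPCK, beta-oxidation, lipolysis negative);
* 12-h lipid endpoints rank fructose ≥ mixed ≥ glucose, with the glucose
  arm lowest in hepatic fatty acids;
* raising the fructose dose from 100 g to 150 g per meal produces a
  mild-steatosis-scale hepatic-TG increase (≈ +19% at the defaults) and
  graded KHK suppression reverses it monotonically;
* plasma TG stays in the low-mM range (pure-fructose maximum ≈ 1.6 mM).

Tuning exposed several structural requirements worth recording. Fructose
uptake must be exchange-dominated, so that hepatocyte fructose
backpressure links fructokinase capacity to throughput; aldolase B, TPI and
triokinase sit at mid-capacity (their transient substrate backlogs carry
their sensitivities); fructose-bisphosphatase is a genuine gluconeogenic
escape competing with pyruvate kinase for GA3P, which is what gives PK its
positive and PEPCK its negative sensitivity; the TG exchange coupling
`V_TGex` is kept small so hepatic TG is governed by synthesis and VLDL
export rather than by plasma exchange; and `Km_TGSGA3P` is tiny so the
backbone factor of triglyceride synthesis is saturated at any physiological
GA3P — otherwise the deep inter-meal dips of the triose pool dominate
every endpoint difference. Sensitivity *magnitudes* are therefore not
comparable to the reference values entry-for-entry; the directions and
orderings are the reproducible content.

## Experiments

All three runners start from `run_to_baseline()`: repeated 24-h days under
the mixed diet until the 08:00 state changes by less than 0.1% cycle-over-
cycle (converges in about a week of model time from the shipped initial
state). The endpoint convention is the state at t = 12 h (20:00), switchable
to time-averaged in `run_oat_sensitivity()`.

* `run_diet_comparison()` — fructose/mixed/glucose at 100 g per meal from
  the shared baseline.
* `run_oat_sensitivity()` — ±10% on the eleven maximal rates, one at a
  time, under the mixed diet; deltas against the shared unperturbed run.
  TPI is one enzyme with two directional maximal rates, scaled jointly.
* `run_khk_inhibition()` — `V_KHK` scaled by (1 − fraction) for fractions
  {0, 0.5, 0.7, 1} under the 150 g fructose diet, plus the steatosis-setup
  metric (percent hepatic-TG increase of 150 g over 100 g).

## Numerical choices

`deSolve::ode` with `lsoda` (stiff-capable, adaptive), `rtol = 1e-8`,
`atol = 1e-10`, dense output on a 1-min grid over the default 12-h horizon;
halving the tolerances moves 12-h endpoints by well under 0.5%. States are
never clipped; the right-hand side floors its *view* of the state at zero
so that solver round-off a hair below zero cannot raise domain errors, and
the non-negativity of reported trajectories is asserted in the test suite
(to 10⁻⁶ relative). The zero-input steady state can be found two ways —
cycle convergence of the integrator and a damped-Newton root of the
autonomous right-hand side — and the two agree to 0.1%, which is itself a
test. Everything is deterministic; there is no random number use anywhere
in the simulation path.

One boundary case is worth stating: at the all-zero state the 21 metabolite
derivatives vanish, but glucagon secretion is maximal there (a falling Hill
function of glucose), so the hormone coordinates are not at rest until
glucagon reaches its secretion/clearance balance. The zero-input
*equilibrium* — the state the stability tests use — therefore has basal-
normalised glucagon near 2, not 0.

## What the model does not capture

* **No glycogen store.** Overnight the liver has no buffered glucose
  source, so fasted blood glucose drains toward zero instead of plateauing
  near 5 mM. Fed-window dynamics, which all three experiments measure, are
  unaffected, but the 08:00 baseline is a post-absorptive state with low
  blood glucose.
* **Plasma fructose overshoots.** Meals enter systemic blood (per the original formulation)
  and circulation limits delivery to the liver, so plasma fructose
  transiently reaches the mM range rather than the tens of µM seen in
  vivo, where first-pass portal extraction dominates.
* **Lumped liver, acute horizon.** No zonation, no protein/fat intake, no
  chronic adaptation; 12-h acute responses only.
* **Hormone units are relative.** Insulin and glucagon are multiples of
  basal; absolute endocrine concentrations are outside the model.

## Problem sizes

The shipped configuration integrates 25 states over 12 h in about a second;
the full acceptance recomputation (baseline run-in, 3 diet runs, 23
sensitivity runs, 6 inhibition-related runs) takes under two minutes on one
CPU. The test suite generates all of its fixtures in code.
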
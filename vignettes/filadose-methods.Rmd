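---
title: "Methods: designing passively drug-loaded FDM filaments and tablets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing passively drug-loaded FDM filaments and tablets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filadose)
```

## The problem

Fused deposition modelling (FDM) prints solid dosage forms from drug-loaded
thermoplastic filaments. Hot-melt extrusion, the usual way to load a
filament, needs dedicated equipment and prolonged heating. Passive diffusion
— soaking a commercial filament in a saturated drug solution — is an
accessible alternative, but drug loadings are typically below 1–2 % w/w
unless the solvent/filament combination is chosen carefully. `filadose`
implements the computational workflow for making that choice and for
characterising the resulting tablets: Hansen-solubility screening, diffusion
kinetics, dissolution kinetics, accelerated-stability shelf-life prediction,
mechanical descriptors, and a multivariate predictive model of drug flux.
The worked case study bundled with the package is nifedipine (NFD, a
BCS class II antihypertensive) loaded into four commercial filaments (PVA,
a PVA-derivative sold as Hydrosupport/HS, PLA, TPU) from ethanol or ethyl
acetate.

## Hansen screening

Cohesive energy density is partitioned into dispersion, polar and
hydrogen-bonding components $(\delta_d, \delta_p, \delta_h)$, all in
MPa$^{1/2}$, with total $\delta_t = (\delta_d^2+\delta_p^2+\delta_h^2)^{1/2}$.
Miscibility of two materials is predicted by the scaled distance

$$R_a = \sqrt{4(\delta_{d1}-\delta_{d2})^2 + (\delta_{p1}-\delta_{p2})^2
+ (\delta_{h1}-\delta_{h2})^2},$$

smaller $R_a$ meaning greater miscibility. The screening rule for passive
loading is deliberately asymmetric: the drug should be *poorly* miscible
with the solvent (drug–solvent $R_a > T_{high}$, default 10), so that
partitioning out of solution is energetically favourable, while the solvent
should be *moderately* miscible with the filament
($|R_a^{sf} - T_{mid}| \le W$, defaults $T_{mid} = 10$, $W = 3$) — enough to
plasticise and carry drug into the polymer, not enough to dissolve it. All
three thresholds are configurable in `screen_combinations()`. The
`rank_score` ($R_a^{ds} - |R_a^{sf} - T_{mid}|$) is this package's own
convenience ordering; the raw distances are always reported beside it and
any serious decision should look at them.

HSP triples can be supplied from reference compilations (the bundled
`nfd_reference_hsp()` table carries the case-study values) or estimated
from functional-group counts with `estimate_hsp_from_groups()`, which uses
the Hoftyzer–van Krevelen forms
$\delta_d = \sum nF_d / V$, $\delta_p = \sqrt{\sum nF_p^2} / V$,
$\delta_h = \sqrt{\sum nE_h / V}$. The bundled group table combines standard
Hoftyzer–van Krevelen attraction constants with Fedors-style molar-volume
increments; the Fedors scheme is used because its increments are all
positive, which keeps $V = \sum n v$ well-defined for any group multiset
(classical van Krevelen volume increments include negative entries for
branched carbons). Group-contribution estimates are auxiliary: screening
uses whichever HSP source a `material()` carries. A note on the bundled
reference values: the published totals and distances were evidently computed
from unrounded components, so recomputing them from the one-decimal
components reproduces them only to within ~0.05–0.06 MPa$^{1/2}$, and the
published solvent–filament distances are not reproducible at all from the
printed components; the package therefore always reports recomputed
distances and never forces agreement with a published cell.

No Hansen-sphere interaction radius is fitted; `material()` objects may
carry one as an annotation but the screening rule does not use it.

## Diffusion kinetics

A filament section (default 1 cm × 1.75 mm) immersed in saturated drug
solution takes up drug with cumulative mass $M(t)$. The steady-state flux is

$$J_{ss} = \frac{dM}{S\,dt},$$

estimated by `fit_steady_state_flux()` as the ordinary least-squares slope
of replicate-averaged mass per unit nominal area against time over the
linear window, default 0–4 h. The intercept is left free: the flux is a
slope definition and an intercept absorbs any onset artefact. The section
area is the closed cylinder $S = 2\pi r^2 + 2\pi r h$ (0.598 cm² at nominal
dimensions). Permeability is $P = J_{ss}/C_{sat}$ with $C_{sat}$ the drug's
saturation solubility in the loading vehicle (31.6 mg/cm³ in ethanol,
71.2 mg/cm³ in ethyl acetate for NFD), and the enhancement ratio is the
flux ratio between the two solvents for the same filament. Units are fixed
throughout: hours, mg, cm; conversions happen at the I/O boundary.

`design_tablet()` closes the loop from loading to dose: a flat cylindrical
tablet of mass $dose/loading$, volume $mass/\rho$ and height
$V/(\pi r^2)$, matching the case study's 12 × 4 mm (0.452 cm³) and
12 × 4.8 mm (0.543 cm³) designs.

## Dissolution kinetics

Four release laws are fitted by `fit_release_models()`, each on its stated
scale so that $R^2$ matches the linearised convention of the dissolution
literature:

* zero order, $Q_t = K_0 t$ — least squares through the origin;
* first order, $\ln Q_t = \ln Q_0 + K_1 t$ — linear on the log scale;
* Hixson–Crowell, $Q_\infty^{1/3} - (Q_\infty - Q_t)^{1/3} = K_s t$ —
  through the origin on the cube-root scale;
* Korsmeyer–Peppas, $Q_t/Q_\infty = K_{KP} t^n$ — nonlinear least squares
  on the fractional scale (`kp_scale = "log"` selects the linearised
  log–log fit instead).

The Korsmeyer–Peppas fit is restricted to points below 60 % fractional
release by default (`kp_fraction_cap`), the conventional validity range of
the power law; set the cap to 1 to use a full profile. The release exponent
classifies the mechanism with geometry-specific Fickian thresholds (0.5
thin film, 0.45 cylinder, 0.43 sphere; $n \ge 1$ is zero-order transport).
Model selection is by maximum $R^2$, ties broken toward fewer parameters —
so exactly linear fractional data selects zero order over the
algebraically identical Korsmeyer–Peppas fit with $n = 1$.

Numerical choices: cumulative-release dips up to 0.5 % of $Q_\infty$
(assay noise) are clipped to the running maximum before fitting, larger
decreases are an error; $R^2$ is computed about the mean on the fitted
scale and floored at zero so it is a bounded ranking score (the raw value
is kept as an attribute); the nonlinear power-law fit is started from the
log–log regression and cross-checked in the test suite against a dense
grid-search oracle. Sample-withdrawal correction
(`correct_sample_withdrawal()`) is available but off by default, since
whether it was applied to the reference profiles is not stated.

## Accelerated stability and shelf life

Degradation at each temperature/humidity condition is fitted on the
percent-degraded scale by `fit_degradation()` with five kinetic forms
(zero, first, second order, square-root-of-time diffusion, Avrami with
exponent 2). The published equation set describes quantities rising from
zero while calling the variable "percent remaining"; the package resolves
this by always fitting percent degraded and converting
remaining → degraded at ingest (`convention` flag on
`stability_condition()`). The printed Avrami expression
($[\mathrm{drug}] = [\mathrm{drug}]_\infty - e^{-kt^2}$) is dimensionally
inconsistent at $t = 0$; the canonical form
$D = D_\infty(1 - e^{-kt^2})$ is the default, with the literal printed form
available behind `avrami_form = "printed"` for comparison. Rate constants
carry explicit unit strings because the unit depends on the model form
(%/day for zero order, day$^{-2}$ inside the Avrami exponential, and so
on). Single-parameter nonlinear fits use a coarse log-spaced bracket
followed by golden-section refinement, which is deterministic and
derivative-free.

Condition-wise constants feed the humidity-corrected Arrhenius surface

$$\ln k = \ln A - \frac{E_a}{RT} + B \cdot RH,$$

fitted by OLS with $R = 0.00198$ kcal K$^{-1}$ mol$^{-1}$ fixed, so $E_a$
is in kcal/mol and $B$ per %RH. The design must span at least two
temperatures and two humidities; rank-deficient designs are rejected with a
message naming the deficiency. `predict_shelf_life()` extrapolates $k$ to
storage conditions (default 25 °C / 60 % RH) and inverts the chosen kinetic
model in closed form at the specification limit (default 10 % degraded);
forward-simulating the model to the returned day reproduces the limit to
numerical precision, which the test suite asserts for every model.

## Mechanical descriptors

From a profilometry trace, `average_roughness()` is the mean absolute
deviation of heights about their mean and `max_height()` the peak-to-valley
range, both over the whole sampling length (not per ISO sub-lengths — the
whole-length convention matches how the case-study values are defined).
From a three-point-bend force–travel record, `toughness()` is the
trapezoidal area under the full curve and `bending_modulus()` the slope of
the initial linear region.

The linear region is delimited by greedy prefix growth: start from the
shortest prefix covering `linear_fraction` (default 15 %) of the travel,
extend point by point while the prefix's OLS fit keeps
$R^2 \ge$ `r2_threshold`. The default threshold is 0.999. This is
deliberately strict: for a curve that kinks at yield, a prefix guard at
$1-\varepsilon$ admits a post-yield slice of roughly
$(\varepsilon/4)^{1/3}$ of the elastic span regardless of sampling density
— at 0.99 that is ~13 % of the span and biases the slope several percent
low, while at 0.999 the detected window stops within a sample or two of
the yield point and the bias stays ~1 %. For noisy experimental records an
exact-linearity guard may reject every prefix, in which case the function
falls back to the initial fraction with a warning; lowering the threshold
is then the right manual choice.

## The predictive model

The feature table has one row per (solvent, filament) combination — eight
in the case study — and six variables: recomputed solvent–filament $R_a$,
average roughness, bending modulus, toughness, $J_{ss}$ and permeability.
The "stiffness" model input is mapped to toughness (area under the
force–travel curve); a config switch in `fit_flux_model()`'s `features`
argument allows substituting the bending modulus. Mechanical descriptors
are those of the blank filaments and are shared by both solvents.

`run_pca()` performs PCA on standardised columns and reports correlation
loadings (the correlation of each original variable with each score
vector). On the case-study table the flux variables load opposite in sign
to $R_a$, toughness and bending modulus on the dominant component: stiffer
filaments and poorly miscible solvent–filament pairs take up less drug.

`fit_flux_model()` regresses $J_{ss}$ on the four material descriptors by
multiple linear regression, PLS (NIPALS, 2 components by default, via
mixOmics) or $\varepsilon$-insensitive RBF-kernel support vector
regression. SVM hyperparameters are chosen by exhaustive grid search
(cost ∈ {0.1, 1, 10, 100}, γ ∈ {0.01, 0.1, 0.5, 1, 2},
ε ∈ {0.001, 0.01, 0.05}) maximising leave-one-out $R^2$, then refit on all
rows. With these row counts LOO is frequently uninformative: every grid
point can have negative LOO $R^2$ because each held-out row is an
extrapolation for the remaining three or seven. When that happens the
tuner falls back to maximising training $R^2$, and the result records
which rule applied (`tuning_criterion`). All reported fit statistics are
training-set values — with $n = 8$ no honest generalisation claim is
possible and the package does not make one; the SVM here is a descriptive
interpolator whose value is ranking candidate combinations, not an
externally validated predictor.

## The synthetic-data generator

No raw instrument data are published for the case study, so every pipeline
input can be generated with known ground truth:

* `gen_diffusion_timecourse()` — linear uptake $J_{ss} S t$ to a plateau
  time (default 4 h), then an exponential approach (time constant 2 h) to
  the ~8 h asymptote, emulating sharp-then-gradual loading. Sampling times
  default to 0, 2, 4, 8, 24 h; the origin belongs to the record because
  nothing has diffused at immersion time zero, and it anchors the 0–4 h
  regression.
* `gen_dissolution_profile()` — forward evaluation of any of the four
  release laws, clipped to $[0, Q_\infty]$.
* `gen_arrhenius_rates()` / `gen_stability_study()` — rate constants from
  the Arrhenius surface, degradation curves from the chosen kinetic model
  at the six-condition design (80/70/60/50 °C × 10–75 % RH, days
  14/28/48). Default truth $E_a = 23.38$ kcal/mol, $B = 0.008$ per %RH
  matches the case-study raw-material estimates; $\ln A$ is not published,
  and the default 32.5 was chosen once so the hottest condition stays below
  ~40 % degraded at day 48, i.e. inside a usable assay range.
* `gen_roughness_profile()` — zero-mean heights rescaled so the realised
  mean absolute deviation equals the target exactly;
  `gen_force_curve()` — linear loading to yield, then smooth exponential
  decline.

Noise families are declared, not incidental: `additive_gaussian` adds
perturbations with standard deviation proportional to the signal
(heteroscedastic, as assay noise is), `multiplicative_lognormal`
multiplies by $e^{N(0,\sigma^2)}$. Every generator is a pure function of
its seed and restores the caller's RNG stream. Every generator/estimator
pair is an exact inverse at zero noise, which the test suite asserts.

What the generators do **not** emulate: polymer swelling or solvent
transport physics, photodegradation of the loading solution, medium-switch
discontinuities in dissolution profiles, or correlated instrument drift.
Passing recovery tests therefore demonstrates that the estimators are
correct and stable under the declared noise families at the study's scales
— not that the underlying physical models are adequate for any particular
real formulation.

## Problem sizes used by the test suite

Simulation-based checks use 500 seeded runs for flux recovery (5 %
multiplicative noise), 200 for release-model selection (2 % noise), 500
for Arrhenius parameter recovery (2 % noise on $k$) and 100 for the
end-to-end shelf-life round trip (2 % observation noise). These sizes give
stable rates for the asserted thresholds while keeping the whole suite in
the tens of seconds on one core.

## Known limitations

* The screening rule and its thresholds encode one case study; they are a
  pre-screening heuristic, not a validated design space.
* The flux model is descriptive (training fit on 4–8 rows); treat
  `predict_jss()` on unseen materials as interpolation at best.
* Dissolution $R^2$ values computed on different fitted scales are
  compared directly when selecting a model, as is conventional in the
  dissolution literature; this mildly favours transformed-scale fits when
  noise is heteroscedastic.
* Shelf-life extrapolation inherits every assumption of the
  humidity-corrected Arrhenius form — notably log-linearity in $1/T$ and
  $RH$ far outside the accelerated design.
* No packaging or moisture-barrier modelling, no diffusion-PDE solving,
  no Hansen-sphere fitting, no f2 profile comparison.
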
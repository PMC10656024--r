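---
title: "Modelling transplacental IgG transfer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transplacental IgG transfer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igtransfer)
```

## The transport model

Maternal immunoglobulin G (IgG) reaches the fetus by crossing two
cellular barriers of the placenta: the syncytiotrophoblast (STB) layer
facing maternal blood, and the fetal capillary endothelium (EC) of the
villi. `igtransfer` models this as a five-compartment mass-action system
per IgG subclass (IgG1–IgG4): maternal blood, STB endosomes, villous
stroma, EC, and fetal blood. Within STB endosomes IgG binds the neonatal
Fc receptor (FcRn) at acidified pH; at the EC surface it binds the
low-affinity receptor FcγRIIb; either binding event commits the complex
to transcytosis toward the fetal side, while unbound endosomal IgG is
degraded in lysosomes. ECs additionally carry a smaller FcRn pool that
captures IgG after fluid-phase uptake from the stroma.

For subclass $i$ the states are maternal IgG ($M_i$, held constant by
default), free and FcRn-bound endosomal IgG in the STB
($S_i$, $C^{STB}_i$), stromal IgG ($R_i$), free and FcRn-bound IgG in
the EC ($E_i$, $C^{Rn}_i$), FcγRIIb-bound IgG at the EC surface
($C^{2b}_i$), and fetal IgG ($F_i$). Transport rates $k_{up}$,
$k_{trans}$, $k_{deg}$ and the fetal decay $\delta_{Ab}$ are volumetric
clearances (L/week): the molar flux leaving a compartment at
concentration $C$ is $kC$, and the receiving compartment divides by its
own volume. Binding follows mass action with association rates
$k_{on} = k_{off}/K_D$ ($k_{off} = 0.15\,\mathrm{s^{-1}}$ for every
receptor–subclass pair), converted to the weekly time base.

Two bookkeeping choices deserve comment:

* **Receptor conservation is algebraic.** Total receptor expression is a
  prescribed function of gestational age (below), and free receptor is
  computed as total minus the sum of bound complexes across all
  transported species. This is equivalent to integrating a separate
  free-receptor state with an explicit synthesis source (synthesis adds
  only free receptor) and removes a stiff conservation constraint from
  the integrator.
* **The FcγRIIb binding flux conserves moles.** The complex
  $C^{2b}$ is accounted in the EC volume (its transcytosis clearance is
  $k_{trans}/V_{EC}$), but it forms from stromal IgG. A bimolecular rate
  expressed in concentrations must be referred to one reaction volume —
  we use $V_{EC}$ — so the stromal equation carries the binding and
  unbinding terms scaled by $V_{EC}/V_{STR}$. Without this factor, total
  IgG moles would not be conserved whenever $V_{STR} \neq V_{EC}$; with
  it, the package's conservation test holds to $10^{-8}$ relative with
  degradation switched off.

Maternal subclass concentrations, volumes, and affinities are constant
across gestation. The packaged defaults take the midpoint of each
optimized parameter range (`default_parameters()`,
`default_parameter_ranges()`); maternal subclass concentrations and
affinities are literature-derived point values.

## Receptor expression schedules

Placental Fc receptor expression rises across gestation; rodent
expression data motivate a convex, parabolic increase. Each receptor
pool (STB FcRn, EC FcγRIIb, EC FcRn) is modelled as a quadratic in
gestational week with the default shape $R(t) = R_{end}(t/t_{end})^2$:
zero at conception, convex, monotone, and equal to the optimized term
expression at delivery. The exact rodent-derived coefficients are not
published, so the pure-quadratic-through-origin shape is the simplest
curve satisfying every stated constraint; custom coefficients are
accepted when they preserve convexity, non-negativity, monotonicity and
the terminal value.

## Numerical integration

Binding kinetics act on a per-second scale and transport on a per-week
scale, so the system is stiff; `deSolve::lsoda` integrates a
C-implemented right-hand side (an equivalent R implementation is kept
for inspection and cross-checking, and the two agree along trajectories
to solver tolerance). Defaults are `rtol = 1e-8` and `atol = 1e-14` M —
the absolute tolerance sits well below early-gestation fetal
concentrations (~$10^{-12}$ M). Free-receptor values are clamped at
zero inside the right-hand side; binding shuts off as free receptor
vanishes, so the clamp only guards against round-off undershoot.
Solver-tolerance refinement changes fetal IgG at term by well under
0.1%.

The fetal-to-maternal (F:M) concentration ratio per subclass at term is
the model's headline output; with default parameters the strict
ordering IgG1 > IgG3 > IgG4 > IgG2 emerges, driven by competition for
the scarce FcγRIIb pool (ties are treated as "hierarchy not
satisfied"). In receptor-variant sweeps the hierarchy threshold is
reported as the midpoint between the last passing and first failing
grid ratio.

## The Transwell (HUVEC) transcytosis model

The in vitro companion model tracks apical IgG1/IgG4, free FcRn, the
two complexes, and cumulative basolateral (transcytosed) IgG over a
120-minute assay, in nM and minutes. The printed kinetic equations are
implemented verbatim; they contain no degradation term even though the
optimized parameter table reports one, so `-k_deg * IgG` on the free
apical pools is available as an explicit variant
(`with_degradation = TRUE`) without asserting which produced the
published curves. Note the receptor balance regains
$(k_{off} + k_{trans})C$ per complex, so total receptor is exactly
conserved.

At quasi-steady state with ligand in excess, two-subclass competition
has the closed form
$C_4 = \mathrm{FcRn}_0 \frac{[IgG4]/K_{D4}}{1 + [IgG4]/K_{D4} + [IgG1]/K_{D1}}$,
which the package cross-checks against a direct linear solve of the
steady-state balance on 1000 random inputs.

**Saturation point.** "Saturation" is not operationally defined by a
formula in the source experiments, so the package defines it as the
breakpoint of the dose–response: the intersection of the low-dose
linear response with the high-dose plateau. Because essentially every
apical molecule finds free receptor below the breakpoint and the
receptor pool is the limiting reagent above it, the breakpoint sits
where apical IgG4 matches total FcRn — 0.33 mg/ml at 2200 nM receptor
and 150 kDa. An alternative marginal-slope criterion (first
concentration at which the marginal gain drops below 5% of the
low-dose slope) is provided; since occupancy approaches its ceiling
hyperbolically, that criterion necessarily triggers well above the
breakpoint (~0.53 mg/ml with default parameters), which is why it is
not the default.

## The vaccine-response model and its coupling

Maternal immunization is a linear cascade: an antigen bolus decays
exponentially while generating short-lived (fraction $\rho = 96\%$) and
long-lived antibody-secreting cells, which secrete antigen-specific IgG
(anti-pertussis-toxin IgG in the packaged parameterization, peaking
14–28 days post-dose). Simulated vaccination at gestational week
$t_{vax}$ feeds this time course into the maternal compartment as four
vaccine-induced sub-species — equal parts IgG1–4, each transported with
its own subclass affinities — competing with the constant baseline
subclass pool for free receptor. mg/ml titres convert to molar via a
fixed 150 kDa molecular weight; antigen units are opaque dose units
with 100 = one standard dose.

Two design choices matter here:

* **Fetal decay of vaccine-induced IgG.** The placental parameter table
  carries $\delta_{Ab} = 0.02$ L/week (a ~63-day concentration
  half-life with the clearance convention), while the immunization
  model assumes a 31-day fetal IgG half-life. Both constants are
  exposed; the baseline pool uses the table value everywhere, and the
  vaccine-induced sub-species default to the 31-day value
  (`apt_halflife_days = 31`). The faster decay penalises very early
  vaccination and places the optimal $t_{vax}$ for a term pregnancy in
  week 25, consistent with the second-trimester optimum; with the
  slower table value the optimum shifts ~4 weeks earlier.
* **Full competition, not a tracer.** The vaccine-induced species
  competes for receptor at its actual concentration. The post-booster
  titre is large enough to saturate the receptor pools, which produces
  the strong self-limitation visible in the affinity scenario (a
  10-fold FcRn affinity gain on the vaccine-induced species yields
  ~+33%, not the ~4-fold gain a trace species would enjoy, and the
  both-receptor gain exceeds the sum of the single-receptor gains). The
  same saturation makes *dose* compensation for a receptor deficiency
  ineffective: under a 10-fold STB FcRn or EC FcγRIIb deficiency,
  fetal vaccine-induced IgG plateaus near 19% / 35% of baseline no
  matter how large the dose, because additional antibody competes for
  the same diminished receptor pool. A hypothetical non-competing
  ("tracer") coupling linearises the dose response (8-fold and ~4-fold
  doses then restore baseline) but is inconsistent with the affinity
  results; the package keeps the mass-action coupling as the default
  and reports the dose–response curve so users can judge restoration
  against any criterion.

Scenario analyses (`fcr_deficiency_scenario()`, `dose_compensation()`,
`affinity_scenario()`) fix vaccination at week 25 of a 40-week
gestation and report changes relative to the unmodified simulation;
affinity changes apply a $K_D$ fold-decrease (implemented as a $k_{on}$
increase) to the vaccine-induced species only.

## Calibration

Calibration searches the 11 free parameters (three transport
clearances, three term receptor expressions, five volumes) by iterative
Latin hypercube sampling. A sampled set *passes* when, for every
subclass, the simulated fetal concentration at the first target week
does not exceed the data mean plus one standard deviation (one-sided,
because early-gestation fetal IgG is near zero), and at the final
target week lies within the mean ± 1.5 standard deviations.
Intermediate weeks are not part of the criterion. Each iteration
narrows every parameter's range to the 2.5th–97.5th percentile envelope
of the passing sets; iteration stops at a 95% pass fraction. The
envelope rule substitutes for the original tool's density-based
pruning, whose exact update is not published; it preserves the
pass/terminate semantics, is configurable, and recovers generating
parameters on synthetic targets. Runs are bit-reproducible given the
seed.

## Global sensitivity analysis

1000 parameter sets are drawn by Latin hypercube sampling from the
free-parameter ranges (plain stratified sampling, one draw per
stratum, random pairing). For each outcome — total fetal IgG at term,
fetal subclass entropy $E = -\sum_i P_i \log P_i$ at term, or the
optimal vaccination week — the forward model runs per row and an
orthogonalized PLS regression is fitted: predictors and outcome are
z-scored, a two-component PLS1 model is fitted by NIPALS, and the score
plane is rotated so that LV1 carries the composite predictive
direction and LV2 is orthogonal to it. The rotation leaves predictions
identical to the unrotated two-component model (verified against an
independent PLS implementation). VIP scores combine the squared
normalized weights of the two components, weighted by the y-variance
each explains, so that $\sum_j VIP_j^2 = p$; signs are applied from the
LV1 loadings for presentation. $Q^2$ comes from 5-fold cross-validation
($1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$ on held-out predictions),
and significance from refitting to label-permuted outcomes (ties count
for the null). X columns may optionally be log-transformed before
scaling (`log_scale = TRUE`); the linear default matches the narrow,
strictly positive parameter ranges.

With default ranges the total-IgG model reaches $Q^2 \approx 0.99$ with
$k_{trans}$, STB FcRn and EC FcγRIIb expression as the top three VIP
parameters. Two caveats: the maternal volume has no causal path while
maternal concentrations are held constant (its loading is noise), and
the entropy model ranks $k_{trans}$ and STB FcRn above EC FcγRIIb —
VIP weights depend on the sampled range widths, and the FcγRIIb range
is the narrowest.

## Synthetic data

`generate_cordocentesis_fixture()` emulates the kind of
gestational-age-indexed cohort summary used for calibration: means are
the fetal subclass trajectory of a known truth parameter set sampled at
weeks 17–41 (optionally perturbed by multiplicative lognormal noise),
and standard deviations are synthesised as a fixed coefficient of
variation times the mean (default 20%). It reproduces the *shape* of
such data — not inter-subject correlation structure, assay error,
sampling imbalance across gestational ages, or cohort selection
effects — so passing calibration tests on fixtures demonstrates
parameter recovery under the model's own dynamics, not performance on
real cordocentesis data. `generate_vaccine_response_fixture()` plays
the same role for the maternal titre curve; note the vaccine cascade is
linear, so dose and secretion rates are only jointly identifiable and
the refitting utility defaults to refitting the dose alone.

## Problem sizes and runtime

The compiled right-hand side integrates a default pregnancy in ~20 ms,
which sets the scale for everything else: receptor-variant sweeps use
50 grid points, calibration tests run 150–300 samples per iteration
(the full protocol uses 1000), and sensitivity analyses use the full
1000-row design with 1000 permutations. The complete test suite runs in
about a minute.

## Known limitations

* The placental ODE topology is reconstructed from the interface
  schematic and stated assumptions; the FcγRIIb pathway binds stromal
  IgG at the EC surface directly, and lysosomal degradation does not
  clear surface-bound FcγRIIb complexes.
* No IgG glycoform heterogeneity, immune-complex transport, FcγRIIIa
  pathway, or Fab–antigen interactions; volumes and maternal subclass
  concentrations do not grow with gestation.
* Vaccine antigen units are arbitrary; absolute vaccine-induced titres
  should be read comparatively, not as predicted clinical
  concentrations.
* The calibration pass rule is applied per subclass (the stricter
  reading); a pooled total-IgG variant is available via `rule =
  "total"`.
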
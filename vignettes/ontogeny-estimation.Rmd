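---
title: "Estimating enzyme ontogeny with a population PBPK model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating enzyme ontogeny with a population PBPK model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontopbpk)
```

## The problem

Predicting drug exposure in children requires knowing how the activity of
each drug-metabolising enzyme (DME) matures with age. For many enzymes the
published in vitro ontogeny data disagree — different tissue banks, small
and unbalanced paediatric samples, variable assay conditions — and an
incorrect maturation function propagates directly into clearance and dose
errors, most severely in infants. `ontopbpk` implements the alternative:
estimate the ontogeny *in vivo*, from sparse concentration data collected
in the paediatric patients themselves, using a reduced ("population") PBPK
model embedded in a nonlinear mixed-effects framework. The hepatic pathway
of interest keeps its physiological structure (so the estimated function
transfers to a whole-body PBPK platform); everything irrelevant to the
question — absorption, distribution — stays empirical.

The bundled example mimics an oral, low-hepatic-extraction drug eliminated
75% by a poorly characterised hepatic enzyme (an FMO3-like pathway), 20%
by hepatic CYP3A (well characterised, held fixed) and 5% renally, studied
in a sparse trial of 525 subjects from 2 months to 61 years of age.

## Structural model

Hepatic clearance uses the well-stirred liver model,

$$\mathrm{CL_H} = \frac{Q_H\, fu_B\, \mathrm{CL_{int}}}{Q_H + fu_B\,
\mathrm{CL_{int}}},\qquad F_H = \frac{Q_H}{Q_H + fu_B\,\mathrm{CL_{int}}},$$

with the whole-liver unbound intrinsic clearance scaled per pathway $p$ as

$$\mathrm{CL_{int},p}(a) = \mathrm{CL_{int,mg}}[p]\cdot
\mathrm{MPPGL}(a)\cdot W_{\mathrm{liver}}(a)\cdot F_{\mathrm{activity},p}(a),$$

where $a$ is postnatal age in years and $F_{\mathrm{activity},p}$ is the
pathway's ontogeny function (fraction of adult activity). Renal clearance
scales with absolute GFR (a maturation sigmoid times body surface area),
bioavailability is $F = F_aF_g \cdot F_H$ with $F_aF_g$ age-independent
(justified for high-bioavailability compounds; an intestinal ontogeny hook
is deliberately out of scope), volume is allometric in weight with
exponent 1.0, and disposition is one-compartment with first-order
absorption. One compartment suffices because distribution is declared
empirical: it absorbs what it must and leaves the hepatic physiology to
carry the age signal. Because drug configs specify the *adult* fraction
metabolised rather than intrinsic clearances, the loader back-calculates
per-pathway $\mathrm{CL_{int}}$ by inverting the well-stirred model
against the packaged adult physiology; a round-trip test pins this down.

The pathway partition at any age is computed at the clearance level:
competing hepatic pathways see the same unbound liver exposure, so
$\mathrm{CL_H}$ is split by intrinsic-clearance shares and
$fm_p = \mathrm{CL_{H}}s_p/(\mathrm{CL_H}+\mathrm{CL_R})$. A forward
mass-balance simulation with explicit pathway-flux bookkeeping (including
first-pass extraction) agrees with this partition to well under 0.5%
absolute for low-extraction drugs — both are computed in the test suite.

## Ontogeny model families

The registry holds eleven structural families: two monotonically rising
(sigmoid $E_{max}$ in age; Gompertz), two declining (sigmoid; exponential
toward `F_min`), six bell-shaped six/seven-parameter combinations of a
rising and a declining limb (for enzymes transiently *more* active in
children than adults), and a nine-parameter capped double-sigmoid. The
bell families are reparameterised so the adult asymptote is exactly 1:
`F_max` is derived as $1/(1-\mathrm{FRD})$ and is never a free parameter.
Choices worth recording:

* The exact algebra of each limb was an open design choice; we use a Hill
  rising limb $U(a) = F_{birth} + (F_{max}-F_{birth})
  a^{\gamma_u}/(\mathrm{Age_{up,50}}^{\gamma_u}+a^{\gamma_u})$, a
  (generalised) Gompertz rising limb, a Hill declining limb
  $D(a) = 1 - \mathrm{FRD}\cdot a^{\gamma_d}/(\mathrm{Age_{down,50}}^{\gamma_d}
  + a^{\gamma_d})$, and a Gompertz declining limb
  $(1-\mathrm{FRD})^{1-e^{-x}}$; `eq4e` is the additive up-plus-down
  variant and `eq4b` the capped variant.
* `Age_down,50` is implemented as the midpoint of the *decline* (the age
  at which half of the down-slope contribution has accrued), not as the
  age reaching 50% of `F_min` — the published symbol definition is
  ambiguous between the two readings.
* `AGECAP` pins the activity to exactly 1 at and beyond `AGECAP` (a hard
  cap). Continuity at the cap age then holds only when the parameters put
  the uncapped curve near 1 there, which admissible fits do.
* Adult normalisation is structural (the asymptote equals 1), not
  pointwise: a Hill tail decays polynomially, so a bell curve whose
  decline is still finishing at the 35-year reference age can sit a
  percent above 1 there. The normalisation property tests therefore use
  parameter sets whose limbs have converged by the reference age.

Fixed profiles for well-studied pathways (two divergent hepatic CYP3A
curves, GFR maturation) ship in an editable YAML constants file with
provenance notes: they are system inputs, never estimands. The bundled
`risdiplam_case` truth used by the simulator is a bell calibrated to peak
at ~3x the adult activity at 2 years of age, declining back to 1.

## Physiology defaults

The constants file `physiology.yaml` defines: weight- and height-for-age
(a saturating infancy term plus a pubertal sigmoid, fitted to standard
median growth tables), liver weight allometric in body weight
($45.5\,W^{0.86}$ g), MPPGL as the cubic log10-age polynomial of Barter
et al. (2008), body surface area by Haycock, hepatic blood flow as the
adult 90 L/h scaled by BSA, and GFR maturation as a sigmoid of postnatal
age (~35% of the size-adjusted adult value at term birth) multiplied by
the BSA ratio to give a fraction of *absolute* adult GFR. Plasma protein
binding and blood:plasma ratio are age-independent by default (the
property of the bundled example compound); an age-dependent binding
function can be swapped in through the constants file. The adult reference
age is 35 years and the adult constants are, by construction, the same
functions evaluated there — so the adult-identity invariant is exact.

## Estimation

The marginal likelihood integrates log-normal subject-level random
effects (by default on the intrinsic clearance and volume; maturation
parameters carry no between-subject variability, because sparse paediatric
data cannot support it) out of the joint density by the Laplace
approximation at each subject's conditional mode. The inner mode search is
a damped Newton iteration with finite-difference derivatives, implemented
in C++ for speed; a pure-R reference backend implements the identical
algebra and the two are cross-checked in the tests, as is the whole
engine against a closed-form linear-Gaussian marginal (exact for Laplace)
and 21-node adaptive Gauss–Hermite quadrature on small nonlinear cases.

Fixed effects are estimated on transformed scales: log for positive
parameters, a logit bounded to [0.1, 15] for Hill coefficients, logit for
FRD. The residual model is proportional CV plus an additive floor (1e-6
ng/mL) so that zero-variance observations cannot arise; below-limit
observations are simply excluded (`MDV = 1`). Optimisation uses `nlminb`
with five jittered starts by default (first start unjittered,
seed-controlled); standard errors come from the numerically
differentiated Hessian of the objective with a delta-method back-transform,
and the Hessian's condition number is reported as an identifiability
heuristic. The exact `ka = CL/V` degeneracy in the one-compartment
solution is handled by nudging `ka` by one part in 1e6.

## Qualification tools and the synthetic trial

`posthoc_age_scan()` fits the model with the target pathway's ontogeny
deliberately omitted and classifies the trend of the per-subject
empirical-Bayes clearance effects against age (flat / rising / falling /
bell, with a Spearman CI) — the step that tells you *whether* and *which*
ontogeny to estimate. `ontogeny_scan()` then estimates every requested
structural family from neutral starts and flags the age strata where the
fitted curves agree within 20% (configurable): near-degenerate families
agreeing where data are informative and diverging where they are not is
the expected, meaningful pattern. Bootstrap resampling is stratified by
age band (<2, 2–12, 12–18, ≥18 years) so that sparse paediatric strata
survive resampling; the VPC simulates replicate trials under the fitted
model and compares observed 5/50/95th percentiles with their simulated
95% bands, binned by time-after-dose within age strata or by age.

The trial simulator generates the study conditions the package is tested
under: 525 subjects (382 paediatric, 2 months–18 years; 143 adults to 61
years), once-daily weight-based oral dosing (0.20 mg/kg under 2 years,
0.25 mg/kg capped at 5 mg to 18 years, 5 mg in adults), three
steady-state visits with 2–4 samples each drawn uniformly from 0.5–24 h
post dose, 30%/20% log-normal between-subject variability on intrinsic
clearance/volume, and 15% proportional plus 0.1 ng/mL additive residual
error. Ages in the youngest arm are log-uniform to enrich infants. The
simulator does *not* model dropout, adherence, disease progression,
assay limits, or within-subject ageing over the study; passing tests
demonstrate correct behaviour under these idealised conditions, not
performance on real trial data.

## What is and is not identifiable

The test suite's recovery experiments (five replicate simulated trials of
the full design, refitting the generating bell family) show a sharp and
instructive split: the PK fixed effects, the down-slope parameters and the
fitted ontogeny *curve* above 4 months of age are recovered well (curve
mean absolute error of a few percent), while `F_birth` and the rising-limb
midpoint are not — they sit on a flat likelihood ridge, because the design
contains no subjects below 2 months and few below 4 months. Restarting
the optimiser at the generating values walks away to parameter sets whose
curves differ only below 4 months. This is a property of the design, not
of the optimiser, and it reproduces the motivating case study's behaviour
(consistent estimated trajectories above, variable below, 4 months). The
practical consequence is baked into the extrapolation API: predictions in
the unidentified age range should be carried across the *set* of retained
ontogeny models (lowest/medium/highest activity), not a single winner.

## Extrapolation

`ddi_auc_ratio()` computes static drug–drug-interaction AUC ratios by
dividing the perpetrated pathway's intrinsic clearance by the inhibition
factor and rebuilding both clearance and hepatic availability through the
well-stirred model, so bioavailability stays consistent; the textbook
$1/(1-fm+fm/\mathrm{IR})$ shortcut is retained as a low-extraction
cross-check and the two agree within 1% for the bundled compound. Because
a child with transiently elevated alternative-pathway activity has a
*smaller* CYP3A fraction metabolised, its AUC ratio under complete CYP3A
inhibition is below the adult's — an assertable monotone property.
`extrapolate_exposure()` evaluates typical-subject steady-state AUC
(Dose·F/CL) across retained ontogeny models against a reference exposure
interval; the default reference is the 5th–95th percentile of a simulated
older-infant population on the approved-style dose, since no percentile
convention is universal.

## Problem sizes and numerical settings

Test and acceptance runs use: the full 525-subject design for recovery
(five replicates, two optimisation starts each), scan/bootstrap/VPC
checks on 36–75-subject subsets with single starts, 200 VPC replicates,
and 21-node quadrature oracles on 3-subject cases. Convergence uses
`nlminb` defaults with a 400-iteration cap; inner Newton iterations stop
at a gradient norm of 1e-9 or a deviance change below 1e-11.

## Known limitations

* Elimination is linear; saturable kinetics and time-dependent inhibition
  are out of scope (static DDI only).
* The intestinal and renal-secretory ontogeny hooks are placeholders: a
  physiological gut/kidney submodel would be needed to estimate them.
* Omega is diagonal in the compiled path; correlated random effects are
  available only through the R reference engine.
* The bundled drug/design are *representative* of the motivating case,
  not replicas: the real dataset and model are proprietary, so all
  bundled truths are synthetic and labelled as such.
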
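---
title: "Simulating hip-fracture incidence in virtual cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hip-fracture incidence in virtual cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipfracsim)
```

hipfracsim is a desk-scale, patient-level simulator of hip-fracture
incidence in cohorts of postmenopausal women — the setting of in silico
clinical trials, where a treatment's effect is projected by simulating the
placebo (and, eventually, treated) arm of a trial in a computer-generated
population. This vignette describes each model in the pipeline, its
assumptions, the tunable parameters with their defaults and units, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Pipeline overview

One simulated trial chains five models:

1. a **statistical anatomy atlas** (PCA over femur geometry and density
   features) sampled to create virtual patients;
2. **cohort assembly** by accept/reject so the cohort's total-hip areal
   bone mineral density (aBMD) matches a clinical target distribution, plus
   correlated anthropometry and trochanteric soft-tissue thickness;
3. a **homogeneous Poisson fall process** (`lam` falls per patient-year);
4. a **side-fall impact model** turning each fall into an attenuated peak
   force on the greater trochanter, with a stochastic impact direction;
5. a **direction-dependent femur strength** evaluation; a fall fractures
   the hip when its impact force strictly exceeds the failure load in the
   sampled direction. Fracture is an absorbing state: the patient exits
   follow-up (the clinical-endpoint rule), and the follow-up is iterated in
   1-year steps over 3 years. The whole chain is repeated over independent
   realizations (10 by default) and summarised as mean ± SD fracture
   counts with a bootstrap convergence trace.

## Virtual cohorts from a statistical atlas

`fit_atlas()` performs an ordinary PCA (`stats::prcomp`) of a training
matrix of concatenated geometry coordinates (mm) and density features. A
full-rank training set of $n$ femurs yields $K = n - 1$ components; with
the conventional 94-subject training cohort that is 93 stochastic
variables. New subjects are synthesised by `sample_patient_features()`,
which draws each component score independently from the **inverse empirical
CDF** of that component's training scores (linear interpolation between
order statistics, i.e. quantile type 7). This reproduces each marginal
score distribution — including skewness — without assuming normality, at
the cost of never extrapolating beyond the training score range.

`build_cohort()` matches a Gaussian aBMD target `N(mean, sd)` by
accept/reject: a kernel density estimate (`stats::density`, default
bandwidth) of the proposal aBMD distribution is fitted to a 4000-draw
calibration batch, the envelope constant is 1.2 times the maximum
target/KDE ratio over the well-supported part of the grid, and each
proposal is accepted with probability `target / (envelope * kde)`, capped
at 1. Regions where the cap binds carry negligible target mass by
construction of the envelope. The accepted sample is statistically
indistinguishable from the Gaussian target at the cohort sizes used here
(pooled two-sample t-test, `cohort_equivalence()`).

Anthropometry follows a **Gaussian copula**: height and weight each
correlate 0.4 with femoral-neck aBMD, and 0.5 with each other. The 0.4
value is the empirically reported link between DXA neck aBMD and body
size in this population; the height–weight correlation is not reported
and is exposed as a parameter (`rho_hw`, default 0.5, a typical adult
female value). Marginals default to 1.60 ± 0.06 m and 66 ± 11 kg,
postmenopausal-women reference values, both configurable. The aBMD margin
enters through rank-based normal scores, so the copula correlation is
recovered for any continuous aBMD distribution. Trochanteric soft-tissue
thickness is linear in BMI, `STT = a + b·BMI` with defaults a = −10 mm and
b = 1.2 mm per kg/m² (literature-plausible magnitudes, configurable),
clipped below at 2 mm.

A DXA-style projection, `compute_abmd()`, is provided for voxelised
density volumes (mass in a region of interest over its coronally projected
area; for a uniform slab it reduces to density × thickness). In the cohort
pipeline aBMD is carried directly as an atlas feature, since the synthetic
training data injects it with a known link.

## Falls

Fall events follow a homogeneous Poisson process with
`lam = 0.65` falls/person-year, the median rate reported by systematic
reviews of trials with dedicated fall ascertainment — substantially higher
than adverse-event-based fall records, which are known to under-count
non-injurious falls. The model deliberately assumes no between-patient or
between-year variability in fall propensity; frailty heterogeneity,
fall-history feedback and covariate-driven rates are out of scope. Only
yearly counts are modelled; within a year, falls form an ordered sequence
in draw order.

## Impact mechanics

The body–floor impact is a single-degree-of-freedom mass–spring model.
Impact velocity is free fall from hip-centre height,
$v = \sqrt{2 g \, f_h \, H}$ with $f_h = 0.51$ of body height, times a
mean-one lognormal noise with coefficient of variation 0.1 (the only
stochastic term of the impact chain by default). Peak force is
$F = v \sqrt{k\, m_\mathrm{eff}}$ with contact stiffness
$k = 50$ kN/m and effective mass $m_\mathrm{eff} = 0.35 \times$ body
mass — standard side-fall biomechanics values, all configurable via
`impact_params()`. Muscle contraction is not modelled: falls complete
within a few hundred milliseconds, less than elderly reaction plus
activation time.

Soft tissue and flooring attenuate the transmitted force:
$F_\mathrm{att} = F \cdot c_\mathrm{floor} \cdot \max(1 - 0.02\,
\mathrm{STT}, 0.3)$ with STT in mm; attenuation can only reduce force, and
the transmission never drops below 30%. At the default anthropometry this
places the median attenuated force near 2.5 kN.

The impact direction is discretised exactly as in direction-dependent
femur-strength studies: intra-extra rotation $\alpha \in [-30°, 30°]$ and
abduction-adduction $\beta \in [0°, 30°]$ in 1° steps, giving
61 × 31 = 1891 equiprobable, mutually independent directions.

## Femur strength

Two backends provide the failure load as a function of direction.

**Exact strain-criterion evaluator.** Given a quadratic tetrahedral mesh
with nodal principal-strain magnitudes under a 1000 N reference load,
nodal strains are first averaged over a 3 mm sphere (inclusive radius,
surface nodes only — interior nodes are excluded from both the averaging
neighbourhood and the criterion, a choice made explicit because published
descriptions leave it open). Under linear elasticity the failure load is

$$FL = 1000 \cdot \min_{i \in \mathrm{surface}} \min\!\left(
\frac{0.0073}{\bar\varepsilon_{t,i}},
\frac{0.0104}{\bar\varepsilon_{c,i}}\right) \mathrm{N},$$

the load at which the femur surface first reaches the 0.73% tensile or
1.04% compressive principal-strain limit, whichever occurs first: under
linear scaling, the first-reached criterion is exactly the smaller ratio,
and ties between nodes are resolved by the global minimum (which is
order-independent). An all-zero strain field has no finite failure load
and is rejected as degenerate.

**Calibrated surrogate.** Solving ~2500 finite-element problems per
realization is what HPC pipelines do; at desk scale the package replaces
the per-direction solves with a log-linear aBMD model,
$S_0 = \exp(c_0 + c_1 \cdot \mathrm{aBMD})$, a patient-level mean-one
lognormal residual (CV 0.2), and a smooth separable directional modulation
$1 + A\,(2\cos(\pi\alpha/60)\cos(\pi\beta/60) - 1)$ with amplitude
$A = 0.2$ — strength is highest at the neutral impact direction and up to
40% lower at the grid corners, matching the reported strong direction
dependence of side-fall strength. The slope $c_1 = 3.4$ per g/cm² encodes
the steep aBMD–strength relationship; the residual CV captures
strength variance not explained by aBMD.

The intercept $c_0 = 6.5$ deserves its own paragraph, because it is the
one deliberately *systemic* calibration in the package. Fracture of the
hip is a rare clinical endpoint: placebo-arm trials of this population
observe roughly 0.5–1.5% 3-year incidence, and a follow-up whose
realizations each process essentially the full fall workload (≈ cohort ×
years × `lam` strength evaluations) implies that attrition by fracture is
negligible. The default intercept is therefore set so that the cohort's
strength distribution sits well above the attenuated-force distribution —
median $S_0 \approx 7.2$ kN at aBMD 0.722 g/cm², per-fall exceedance
probability of order 0.5% — placing the simulator in that rare-event
regime. It is a regime calibration, not a fit: no constant was tuned to
reproduce any published fracture count, and the plausibility checks in the
test suite assert only a broad incidence band (0.2–3%) and the ordering of
the two reference arms. Absolute strength magnitudes produced by the
surrogate are not individually meaningful; the surrogate's job is the
force–strength *relation* at cohort scale. Users with real strain fields
should prefer the exact backend.

## Follow-up as an absorbing chain

`run_trial()` iterates years within realizations. Per patient-year the
fall count is Poisson; per fall, a direction and an attenuated force are
drawn and one strength lookup is performed. A fall with force strictly
greater than the failure load fractures the patient (a force exactly equal
to the failure load does not — "exceeds" is read strictly); remaining
falls that year are discarded and the patient is excluded from later
years. The evaluation counter therefore counts exactly the strength
lookups an FE-backed pipeline would have solved.

**RNG architecture.** All randomness derives from one master seed. Each
(realization, patient) pair gets its own substream, and a patient's full
multi-year event sequence is drawn from it up front, regardless of
fracture. Consequences: (i) identical master seeds reproduce results
bit-identically; (ii) uniformly scaling all strengths can only shrink the
fracture set pathwise, so monotonicity holds per realization, not just in
expectation; (iii) two cohorts built with the same seeds share event
streams — common random numbers. Within a cohort, patient indices are
assigned in aBMD rank order, so patient *j* occupies the same aBMD
quantile in any cohort built with the same seed; cross-cohort comparisons
(e.g. two trial arms differing in target aBMD) are then comonotone in
aBMD, which removes most cohort-composition noise from paired contrasts.

## Convergence and equivalence diagnostics

`convergence_check()` follows the ensemble mean of fracture counts as
realizations accumulate. For each prefix length $k \ge 2$ it draws 10,000
paired bootstrap resamples of the first $k$ and first $k-1$ counts and
reports the mean relative difference
$|M_k^* - M_{k-1}^*| / M_{k-1}^*$ (zero-mean resamples skipped;
an all-zero prefix is defined as converged with relative difference 0).
Convergence is declared at the first $k$ at or below the threshold
(default 1%). Because published convergence figures are ambiguous about
whether they refer to bootstrap or plain cumulative means, both traces are
emitted; the plain trace is typically an order of magnitude smaller at
equal $k$. For i.i.d. counts both shrink like $1/\sqrt{k}$; with the
default 10 realizations and count CVs around 25%, the bootstrap trace
commonly does *not* reach 1% — an honest "not converged" that users should
read alongside the plain trace rather than as a failure.

`two_sample_ttest()` is the pooled (equal-variance) two-sample t-test —
matching the convention of the reference implementation this field uses —
with explicit handling of zero-pooled-variance degeneracies.

## The synthetic-data generator

No CT cohort ships with the package; `generate_atlas_training()` draws
training matrices from a Gaussian with a controllable eigen-spectrum
(default: geometric decay over 20 leading factors plus an isotropic floor,
giving full sample rank) around a deterministic mean, and injects total-hip
and neck aBMD columns as exact linear functions of the two leading latent
factors (defaults 0.72 ± 0.12 and 0.60 ± 0.11 g/cm², mutual correlation
0.9). The training aBMD spread is deliberately wider than the clinical
targets so both reference arms are inside the proposal support. Every
fixture carries its ground truth: the spectrum for explained-variance
checks, the aBMD link for correlation recovery, and for the toy strain
fields (`generate_toy_strainfield()`) a closed-form or brute-force failure
load computed by the generator itself, independent of the evaluator.

What the generator does **not** emulate: anatomically realistic femur
geometry, spatially structured density fields, non-Gaussian shape
variation, scanner noise, or the excluded-model bookkeeping of real
FE pipelines. Tests passing on these fixtures validate the *machinery*
(PCA round trips, inverse-CDF sampling, accept/reject matching, the strain
criterion, the chain dynamics) — they do not validate anatomical realism
or predictive accuracy on real patients.

## Reference bundles and problem sizes

`reference_configs()` returns two ready-to-run bundles emulating placebo
arms of concluded osteoporosis trials: LIFT-like (n = 1238, total-hip
aBMD 0.722 ± 0.096 g/cm²) and FREEDOM-like (n = 1225, 0.709 ± 0.099),
both with `lam` = 0.65, 3 years, 10 realizations. The package's own test
sizes — 10,000 patient-years for Poisson moments, 20,000 subjects for
copula recovery, 50 seeded cohorts for equivalence rates, 50,000
realizations of a 5-patient toy chain against its closed form — were
chosen so each statistical assertion sits at least 3 standard errors from
its boundary while a full suite run stays around a minute on one core.

## Known limitations

* The surrogate's absolute strength scale is a regime calibration (see
  above); only the exact strain-criterion backend yields
  patient-interpretable failure loads.
* Homogeneous fall risk overestimates faller prevalence relative to the
  observed ~30%/70% faller/non-faller split, and therefore tends to
  overestimate incidence.
* No osteoporosis progression, treatment arms, censoring, non-hip
  fracture sites, or protective responses; flooring and hip protectors
  are a single scalar factor.
* Inverse-CDF sampling cannot generate scores outside the training range,
  so extreme-tail anatomy is under-represented at small training sizes.
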
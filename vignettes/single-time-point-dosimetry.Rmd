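---
title: "Methods: standard and single-time-point dosimetry for Lu-177 PRRT"
author: "prrtdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standard and single-time-point dosimetry for Lu-177 PRRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrtdose)
```

## The problem

Peptide receptor radionuclide therapy (PRRT) with [177Lu]-DOTA-TATE is given
in up to four cycles of roughly 7.4 GBq. After each cycle the absorbed doses
to kidneys, bone marrow, liver, spleen and tumors are calculated so that the
treatment series can be stopped before the cumulative dose to the organs at
risk is expected to exceed 25 Gy (kidneys) or 2 Gy (bone marrow). The
standard workflow images the patient three times after the first cycle
(nominally 24, 96 and 168 h post-injection) and once after each later cycle,
fits mono-exponential time-activity curves, and converts cumulated
activities to dose with phantom dose factors. That is accurate but costs
three clinic visits after cycle 1.

`prrtdose` implements both that standard workflow and a trained regression
model that estimates the same doses from a *single* SPECT/CT study, plus the
management logic the doses drive, a synthetic cohort generator with analytic
ground truth, and the agreement statistics used to compare protocols.

## The standard dose engine

For each region the VOI measurement supplies a count rate $C$, volume $V$
and camera sensitivity $S$ (MBq/cps), so the measured activity is $A = S
\cdot C$. Mono-exponential kinetics $A(t) = A_0 e^{-\lambda t}$ are fitted
by unweighted ordinary least squares on $\ln A$ versus $t$ (`"nls"` is
available behind a flag; the weighting scheme of a clinical in-house code is
rarely published, and log-OLS is the simplest method consistent with
mono-exponential fitting). Non-decaying fits ($\lambda \le 0$) are rejected
with a typed error carrying the fit: their time integral diverges.

The cumulated activity is $\tilde A = A_0/\lambda$ (MBq h); for a single
time point with a decay-constant prior, $\tilde A = A(t_s)
e^{\lambda t_s}/\lambda$, the integral running from injection to infinity on
the same exponential. Subsequent cycles reuse the patient's *own* cycle-1
$\lambda$ per region (the protocol's unchanged-effective-half-life
assumption); if a region was missing at cycle 1 the calculation fails loudly
rather than borrowing a population value.

Organ dose follows the MIRD formalism,
$D(r_k) = \tilde A_k\,DF(r_k \leftarrow r_k) + \sum_{s \neq k} \tilde A_s\,
DF(r_k \leftarrow r_s)$, with dose factors in mGy/(MBq s) and an explicit
error for any missing source-target pair. In the full pipeline solid organs
and tumors are treated as self-dose only (cross-dose is negligible at
therapy geometries), tumors through a sphere-model coupling constant
$\Theta(m)$ interpolated piecewise-linearly in mass (extrapolation outside
the table is refused), and bone marrow as blood self-dose plus
remainder-of-body cross-dose:

$$D(\mathrm{BM}) = \frac{a_\mathrm{blood}(0)}{\lambda_\mathrm{blood}}
\Theta_\mathrm{BM,BM} + \frac{A_\mathrm{RM}(0)}{m_\mathrm{RM}
\lambda_\mathrm{RM}} \Theta_\mathrm{BM,RM}.$$

Any marrow-to-blood concentration ratio is folded into
$\Theta_\mathrm{BM,BM}$; the shipped coupling constants are opaque fitted
quantities, not first-principles constants.

## The single-time-point regression model

Because $\ln D = \ln c(t_s) + \lambda t_s + \mathrm{const}$ holds exactly
for self-dose with mono-exponential kinetics, dose prediction from one
study is posed as a log-log multiple linear regression:

$$\ln D = \alpha_0 + \alpha_1 \ln c(t_s) + \alpha_2 t_s$$

with $c$ the activity concentration in mCi/cc and $t_s$ the acquisition
time in hours. When the model family is exact, $\alpha_1 = 1$ and
$\alpha_2$ equals the effective decay constant; on real (and realistic
synthetic) cohorts the fitted $\alpha_2$ lands near the population mean
$\lambda$ and $\alpha_1$ shrinks below 1, absorbing between-patient
kinetic spread.

For bone marrow the concentration regressor is the composite term
$a_\mathrm{blood}(t_s)\Theta_\mathrm{BM,BM} +
c_\mathrm{RM}(t_s)\Theta_\mathrm{BM,RM}$. The $\Theta$ pair is estimated
*first*, by least squares through the origin of the standard-protocol
marrow dose on its two kinetic terms, constrained non-negative (a negative
energy coupling is unphysical; with two regressors the active set is
enumerated exactly). Whether the original analysis constrained the sign or
included an intercept is not documented; origin-through non-negative least
squares is this package's assumption. The same estimated pair is embedded
in the coefficient object and reused verbatim at prediction time.

Training uses each study's **actual** acquisition time, not the nominal
24/96/168 h. This matters: in a single-time-point training set the time
column would be exactly constant (rank-deficient) at nominal times, but
acquisition times vary patient to patient, which keeps the regression
identifiable. Plain OLS is used throughout — no regularization, no robust
loss. Zero-activity VOIs cannot be log-transformed and are excluded from
training with a warning.

### Units

Canonical internal units are MBq, cc, h, mGy. The regression's unit
contract is concentration in mCi/cc (time h, dose mGy); the MBq-to-mCi
division by 37 happens exactly once, at the regression boundary, and the
prediction functions take an explicit `conc_unit` argument so silently
mismatched units cannot occur. The remainder term of the marrow composite
is converted from the per-kilogram form of the dose equation to the
per-cc concentration form with the tissue density (default 1.0 g/cc),
once, when the coupling pair is attached to the coefficients.

## Management rules

- **Expected** next-cycle dose = cumulative dose + arithmetic mean of the
  completed per-cycle doses. The mean is the minimal faithful estimator of
  "estimated from previous treatments" and is isolated in one function for
  substitution (a clinic might instead scale by planned injected activity).
- Treatment stops when the expected dose **strictly** exceeds 25 Gy
  (kidneys) or 2 Gy (marrow); exactly 25.000 Gy continues.
- The early **predicted-total** classification projects the cumulative dose
  through the planned four cycles and maps it to
  `4_cycles_safe` / `3_cycles_safe` / `consider_4th` / `consider_3rd` /
  `stop_now`. The boundary between "3 cycles safe" and "consider a 4th" is
  resolved by how much of the course is already observed: while cycles
  remain, the projection plans for three; once three cycles are completed
  the fourth is the immediate question. This mapping reconstructs a
  published decision chart whose underlying algorithm is not public, and is
  flagged as an approximation.

Decisions are advisory outputs; multi-disciplinary overrides are out of
scope.

## The synthetic cohort generator

There is no public patient-level dataset for this workflow, so the
generator *is* the study population for every test:

- Per-region mean effective decay constants 0.0129 (kidneys), 0.0098
  (liver), 0.0095 (spleen), 0.0082 1/h (tumors) — the clinically reported
  population means — with 20% between-patient lognormal CV.
- Injected activity 7300 ± 500 MBq per cycle; imaging at 24 ± 2, 96 ± 8 and
  168 ± 12 h with per-patient jitter; cycle counts drawn from the reported
  completion pattern (4, 2, 9, 17 out of 32 patients completing 1–4
  cycles); a 72-patient cohort splits 40 train / 32 test.
- Multiplicative lognormal measurement noise, CV 5%, **unbiased in log
  space** (mean log ratio zero) — VOI-level SPECT count errors are
  approximately multiplicative.
- Uptake-fraction and VOI-volume variability are not reported clinically.
  Defaults of 40% and 20% lognormal CV were chosen once so that per-cycle
  kidney doses span the clinically observed 1–10 Gy range and a cohort
  contains both continue and stop decisions; they are placeholders, and
  labeled as such.
- All randomness flows from one integer seed; each patient's substream is
  derived deterministically from (seed, index), so cohorts are reproducible
  patient by patient.
- Later cycles reuse cycle-1 decay constants, with an optional per-cycle
  jitter (default 0) so the unchanged-half-life assumption can be violated
  deliberately in robustness experiments.

The generator records closed-form ground-truth doses alongside the noisy
measurements, giving every downstream module an analytic oracle.

### What "model-matched" means

The log-log family is *exact* only when, within a region, all patients
share one decay constant, one VOI volume and one dose-factor table, and —
for marrow — blood and remainder share a single decay constant.
`cohort_spec_model_matched()` constructs exactly that cohort (zero noise,
zero $\lambda$ and volume CV, one phantom, common marrow constant). On it,
closure is machine-exact: standard doses equal ground truth to $<10^{-9}$
relative error, training returns $r^2 = 1$, $\alpha_1 = 1$, $\alpha_2 =
\lambda$, and the standard and single-time-point protocols produce
identical management decisions (100% concordance). Passing those tests
shows the pipeline is internally consistent; it does **not** show that a
single time point suffices on real patients, where kinetic spread,
reconstruction artifacts and partial-volume effects (deliberately not
simulated) degrade the agreement. The realistic generator (noise and
population spread on) quantifies part of that gap: concordance drops to
the mid-90s percent and per-region relative differences acquire 10–25%
spread.

## Numerical choices

- Log-OLS mono-exponential fitting; exactly two points give exact
  interpolation. Strictly positive values are required before the log
  transform.
- Tissue density 1.0 g/cc converts VOI volume to mass (configurable; the
  value used clinically is rarely stated).
- Cumulated-activity integration runs from injection (t = 0) to infinity;
  back-extrapolation below the measurement time uses the same exponential.
- Piecewise-linear interpolation for tumor $\Theta(m)$; extrapolation is an
  error, not a clamp.
- Serialization uses 17 significant digits so coefficient round trips
  change no prediction at all; CSV bundles use `%.17g` for the same reason.
- The dose-factor and sphere tables shipped under `inst/extdata` are
  *synthetic stand-ins* with physically plausible magnitudes (derived from
  the Lu-177 mean beta energy); published phantom compilations are
  consumed as inputs in the same format, not redistributed. The published
  regression-coefficient table *is* shipped verbatim
  (`mlr_coefficients_published.json`) and is covered by a cell-for-cell
  transcription test.

## Problem sizes

The test suite and the acceptance script run cohorts of 72 patients
(40/32 split) for closure, concordance and training checks, 1000 patients
for the decay-constant population check, 10^4 random draws for the
algebraic-equivalence checks, and 200 replicates for the Monte-Carlo
fitting checks. These sizes make every stochastic check stable at fixed
seeds while keeping a full run in tens of seconds on one core.

## Known limitations

- No image-level simulation: reconstruction, scatter, partial-volume and
  delineation errors enter real data upstream of this package's inputs.
- Bi-exponential kinetics and trapezoid-plus-tail integration are out of
  scope; everything is mono-exponential.
- Marrow cross-dose from individual organs is not modeled (blood self-dose
  plus remainder only).
- The predicted-management category boundaries are a reconstruction, and
  the "expected dose" estimator is one defensible choice among several.
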
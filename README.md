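# prrtdose

Internal dosimetry for peptide receptor radionuclide therapy (PRRT) with
[177Lu]-DOTA-TATE.

After each PRRT cycle the absorbed doses to kidneys, bone marrow, liver,
spleen and tumor sites are calculated to decide whether another cycle can be
given safely: further treatment is withheld once the cumulative dose is
expected to exceed 25 Gy to kidneys or 2 Gy to bone marrow. The standard
protocol needs three SPECT/CT studies after the first cycle (≈24, 96 and
168 h post-injection). `prrtdose` implements that standard workflow **and** a
trained regression model that estimates the same doses from a single
SPECT/CT study, for medical physicists and researchers evaluating
single-time-point dosimetry protocols.

## What it computes

**Standard protocol** — mono-exponential time-activity fits per region
(log-space OLS), cumulated activities `Ã = A₀/λ`, MIRD organ dose

    D(r_k) = Ã_k·DF(r_k←r_k) + Σ_{s≠k} Ã_s·DF(r_k←r_s),

tumor self-dose through a sphere-model Θ(m), and blood-based bone-marrow
dose `D(BM) = (a_blood(0)/λ_blood)·Θ_BM,BM + (A_RM(0)/(m_RM·λ_RM))·Θ_BM,RM`.
Later cycles use one study and the patient's own cycle-1 effective
half-life.

**Single-time-point model** — a log-log multiple linear regression per
target,

    ln D = α₀ + α₁·ln c(t_s) + α₂·t_s        (organs, tumors)
    ln D = β₀ + β₁·ln[a_blood·Θ_BM,BM + c_RM·Θ_BM,RM] + β₂·t_s   (marrow)

with concentration `c` in mCi/cc and imaging time `t_s` in h, trained
against standard-protocol doses; the marrow Θ pair is estimated first by
non-negative least squares through the origin. Prediction is the closed
form `D = c^α₁·exp(α₂·t_s + α₀)`. The published coefficient table ships as
`inst/extdata/mlr_coefficients_published.json`.

**Management** — expected next-cycle dose (cumulative + mean per-cycle),
strict 25 Gy / 2 Gy stopping rules, hypothetic late-time activities for
cycles imaged only at 24 h, and an early classification of how many cycles
fit under the threshold.

**Synthetic cohorts** — a generator with clinically reported kinetics
(mean λ 0.0129/0.0098/0.0095/0.0082 1/h for kidneys/liver/spleen/tumors,
7.3 ± 0.5 GBq per cycle, 40/32 train/test split) and analytic ground-truth
doses, plus agreement statistics (relative differences, Bland-Altman
limits, Pearson r, angular coefficient, one-sided binomial power).

## Worked example

Predict a kidney dose from one study with the packaged coefficients
(pooled-time training), at 1 MBq/cc measured 163 h post-injection:

```r
library(prrtdose)
set <- read_coefficients(system.file("extdata",
        "mlr_coefficients_published.json", package = "prrtdose"))
co <- get_coefficients(set, "kidneys", "t1t2t3")
predict_dose_solid(co, 1.0, 163, conc_unit = "MBq/cc")
#> [1] 40135.63
```

That is 40.1 Gy for a whole-kidney VOI at an unusually high late
concentration — the closed form `(1/37)^0.85 · exp(0.0111·163 + 11.86)` mGy.

Run a full synthetic protocol comparison (simulate 72 patients, standard
dosimetry, train on 40, predict the 32 test patients from a single study at
168 h after cycle 1 and 24 h after later cycles, manage under both
protocols):

```r
res <- run_study(list(seed = 1, n_patients = 72, n_train = 40))
res$concordance$percent
#> [1] 93.06931
round(res$agreement$kidneys$relative$mean, 1)   # % vs standard protocol
#> [1] 3.8
round(res$agreement$kidneys$correlation$r, 3)
#> [1] 0.907
k <- res$coefficients$kidneys$t1t2t3
round(c(k$alpha0, k$alpha1, k$alpha2), 4)
#> [1] 11.3200  0.7200  0.0090
```

Here 93% of the 101 per-cycle continue/stop decisions agree between the
protocols under 5% measurement noise and 20% between-patient kinetic
spread; the fitted α₂ ≈ 0.009 h⁻¹ sits near the generating kidney decay
constants, as the model derivation predicts. On a model-matched cohort
(`model_matched = TRUE`: no noise, common kinetics) concordance is exactly
100% and training returns α₁ = 1, α₂ = λ, r² = 1.

A decision for one patient:

```r
h <- res$histories$standard[[1]]
decide_continuation(h)
#> $decision: "stop_kidney"  (expected kidneys 43.6 Gy > 25; marrow 0.62 Gy)
```

A thin CLI wraps the same functions
(`Rscript inst/cli/prrtdose.R power --n 32 --p-alt 0.10`, plus `simulate`,
`dose-standard`, `mlr-train`, `mlr-predict`, `manage`, `evaluate`).

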
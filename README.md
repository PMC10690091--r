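# serdpd

Quantitative analytics for preclinical studies of selective estrogen
receptor degraders (SERDs) in ER⁺ breast cancer models: plasma
pharmacokinetics → drug-stimulated ER degradation kinetics → xenograft
tumor growth inhibition, plus the in vitro potency and transcriptional
readouts that surround them. It is written for DMPK/pharmacology
scientists and computational biologists who need the full exposure →
biomarker → efficacy chain, together with a seeded synthetic-study
generator so every estimator can be validated against known ground truth
at desk scale.

## The models

**Exposure.** One-compartment oral PK with first-order absorption and
elimination, linear superposition over repeated doses,

C(t) = Σ_doses D·ka / [(V/F)(ka − ke)] · (e^{−ke·τ} − e^{−ka·τ}),

in nmol/L via the molecular weight; the active free concentration is
Cu = fu·C.

**ER turnover.** A stimulation-of-loss indirect-response model in which
the free drug multiplies the degradation rate through an Emax term:

dE/dt = kout·e0 − kout·(1 + Smax·Cu/(SC50 + Cu))·E,

so the basal half-life is ln2/kout, the steady state under constant
exposure is e0/(1 + Smax·Cu/(SC50+Cu)), and SC50 is the in vivo
degradation IC50. `fit_er_pkpd()` recovers (kout, Smax, SC50) from ER
time courses across dose arms; `average_suppression()` integrates
1 − E/e0 over a steady-state dosing interval.

**Tumor growth.** Per-animal exponential growth log10 V = a + b·t,
generalized to d log10 V/dt = b0 − bkill·(1 − E/e0)^γ so that ER
suppression translates into growth inhibition or regression. Efficacy
statistics follow xenograft practice: growth-rate fits on
log10(max(V, 15 mm³)), percent tumor-volume change from baseline,
geometric-mean TGI% = 100·(1 − (GM_T − 1)/(GM_C − 1)), and the one-tailed
unequal-variance (Welch) t test on log volume change versus vehicle.

**In vitro & transcription.** Day-0/endpoint proliferation normalization
with 4-parameter-logistic IC50/pIC50 fitting, and direction-weighted
z-score gene-signature scoring with one-way ANCOVA group comparison.

## Worked example

Simulate a two-arm efficacy study (vehicle vs 10 mg/kg once daily, 8
animals/arm, 21 days, 15% caliper CV) and compute TGI:

```r
library(serdpd)

design <- study_design(
  arms = list(vehicle = NULL, serd_10mgkg = dose_regimen(10, interval = 24)),
  n_per_arm = 8, duration_days = 21)
study <- simulate_study(design, default_truth(), noise_model(seed = 42))

vols <- study$volumes
tgi(vols[vols$arm == "serd_10mgkg", ], vols[vols$arm == "vehicle", ])
#> TGI at day 21: 142.4%
#>   GM V_end/V_base: treated 0.305, control 2.640
#>   one-tailed Welch p (treated < control, log change): 2.259e-09
```

TGI above 100% means the treated arm regressed below baseline (geometric
mean 0.305× start volume) while vehicle tumors grew 2.64-fold; the Welch
test on log change is strongly significant. The degradation model behind
this effect:

```r
truth <- default_truth()
average_suppression(truth$er, truth$pk, dose_regimen(10, 24, 21))
#> [1] 0.894507   # ~89% average ER loss over a steady-state dosing interval

estimate_half_life(
  simulate_decay_course(3, c(0, 1, 2, 4, 8, 12),
                        noise_model(er_cv = 0.1, seed = 1)))
#> Half-life estimate: 3.116 h (slope -0.2224 /h, 6 points used)
```

Fitting the degradation IC50 requires at least two non-vehicle dose
levels; with the packaged 4-arm design (1/3/10/30 mg/kg), `fit_er_pkpd()`
recovers SC50 within ±25% in ≥90% of replicate noisy studies (see the
acceptance script below).

The full pipeline — simulate, fit the PK/PD model, compute TGI per arm,
build the cohort waterfall — runs from one config:

```r
cfg <- system.file("extdata", "demo_study.yaml", package = "serdpd")
run_pipeline(cfg, "demo_out", seed = 1)
```

and writes `tgi.tsv`, `pkpd_fit.tsv`, `waterfall.tsv`, the raw bundle and
a plain-text run log (byte-identical for a fixed seed). A thin CLI wrapper
is in `inst/cli/serdpd.R`.

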
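---
title: "Models and methods: exposure, ER degradation and tumor growth inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: exposure, ER degradation and tumor growth inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(serdpd)
```

`serdpd` implements the quantitative chain used to characterize a selective
estrogen receptor degrader (SERD) preclinically: plasma exposure under repeat
oral dosing, drug-stimulated ER protein turnover, the link from ER
suppression to xenograft tumor growth, and the efficacy and transcriptional
statistics computed on top. A seeded synthetic-study generator with known
ground truth makes every stage testable without animal data. This vignette
explains each model, its assumptions, the defaults and the numerical
choices.

## Plasma exposure

Exposure follows a one-compartment model with first-order absorption and
elimination and linear kinetics. For a dose $D$ (mg/kg) given at time 0,

$$C(t) = \frac{D\,k_a}{(V/F)(k_a-k_e)}\left(e^{-k_e t}-e^{-k_a t}\right),$$

with the analytic limit $C(t) = D k_a t\, e^{-k_a t}/(V/F)$ when
$k_a = k_e$. Repeat dosing is the superposition of shifted single-dose
profiles. Concentrations are converted to nmol/L via the compound's
molecular weight, and the pharmacologically active free concentration is
$C_u = f_u C$ with free fraction $f_u$.

This is the simplest structure consistent with dose-proportional exposure;
multi-compartment and saturable kinetics are out of scope. `fit_pk()`
estimates $(k_a, k_e, V/F)$ by least squares on the log-concentration scale
(stabilizing a dynamic range of several orders of magnitude), with rate
bounds $(10^{-3}, 100)$/h. Absorption/elimination flip-flop is resolved by
reporting the faster rate as $k_a$ and rescaling the volume, which leaves
the concentration curve unchanged.

Default PK parameters of the synthetic generator — $k_a = 1$/h, elimination
half-life 5 h, $V/F = 5$ L/kg, $f_u = 0.01$, MW 452 g/mol — are package
choices typical of a lipophilic, highly protein-bound oral small molecule.
With once-daily doses of 1–30 mg/kg they give free troughs of roughly
0.16–4.8 nmol/L, bracketing the degradation IC50 below so that the dose
range is informative for fitting.

## ER turnover: stimulation-of-loss indirect response

ER protein level $E$ (as a fraction of the untreated baseline, $e_0 = 1$
after normalization) follows a turnover model in which the drug multiplies
the degradation rate through an Emax term:

$$\frac{dE}{dt} = k_{out}\,e_0 \;-\; k_{out}\left(1 + \frac{S_{max}\,C_u}
{SC_{50} + C_u}\right) E .$$

Basal synthesis $k_{syn} = k_{out} e_0$ is implied, so without drug the
model rests at $e_0$ and the basal half-life is $\ln 2 / k_{out}$. Under
constant exposure the steady state is
$E_{ss} = e_0 / (1 + S_{max} C_u/(SC_{50}+C_u))$ — the closed form used as
the integrator's oracle in the tests — and the suppressed fraction is
bounded by $S_{max}/(1+S_{max})$.

Defaults anchor the biology: basal half-life 3 h (ER is a short-lived
protein; reported basal values for these cell systems are in the 2.5–3.9 h
range), $S_{max} = 9$ (a ten-fold maximal acceleration, leaving a ~10%
residual floor of continuously resynthesized ER), and an in vivo free
$SC_{50}$ of 0.4 nmol/L. With these values a 10 mg/kg once-daily regimen
suppresses ER by roughly 87–90% on average over a dosing interval, the
regime in which maximal antitumor effect is expected.

Numerical choices:

* The ODE is integrated with `deSolve::lsoda`. The right-hand side and the
  superposition exposure are compiled (C), with a generic R-function path
  for arbitrary exposure inputs; both paths are cross-checked in the tests.
* `average_suppression()` doses the model for at least 10 elimination
  half-lives before averaging $1 - E/e_0$ over one interval by trapezoidal
  quadrature on a 201-point grid at `rtol = 1e-8`.
* `estimate_half_life()` regresses $\log E$ on time over the declining
  phase, defined as all points from the global maximum onward (at least 3
  required); non-declining series are rejected rather than extrapolated.
* `fit_er_pkpd()` estimates $(k_{out}, S_{max}, SC_{50})$ on the log scale
  by Nelder–Mead followed by a bounded quasi-Newton polish. Nelder–Mead is
  used first because the finite ODE tolerance leaves noise on the
  least-squares surface at the scale of gradient steps; standard errors come
  from the Hessian of the sum of squares at the optimum. At least two
  non-vehicle dose levels are required, otherwise $SC_{50}$ is structurally
  unidentifiable and the fit refuses.

The synthetic ER courses are sampled densely just after the first dose
(0.5, 1, 2, 4 h) and around the second-day trough. The early points pin
$k_{out}$ (the onset rate is $k_{out}(1+S_{max})$ at saturating drug); the
trough rebound at low doses carries most of the $SC_{50}$ information.

## Tumor growth and the ER link

Each animal's tumor follows the per-animal exponential model
$\log_{10} V(t) = a + b\,t$ used for growth-rate summaries, generalized to
a time-varying slope driven by ER suppression:

$$\frac{d \log_{10} V}{dt} = b_0 - b_{kill}\left(1 - E(t)/e_0\right)^{\gamma}.$$

At full ER ($E = e_0$) this reduces exactly to the exponential model; full
ER loss shifts the slope by $-b_{kill}$. The link is the simplest smooth
choice with these two limits; $\gamma$ (default 1) allows curvature. No
published efficacy-link equation exists for this setting, so the link is a
package design choice, echoed in the simulation ground truth so that
recovery tests are self-consistent.

Growth defaults: $b_0 = 0.02$ log10 mm³/day (volume doubling ≈ 15 days,
typical of ER⁺ breast xenografts) and $b_{kill} = 0.05$, so sustained ~90%
ER suppression reverses growth. Baselines are drawn uniformly from the
150–300 mm³ enrollment window and calipering follows a twice-weekly
schedule (days 0, 3, 7, 10, ...).

Efficacy statistics implemented:

* `fit_growth_rate()`: OLS of $\log_{10}(\max(V, 15))$ on day. Volumes
  below 15 mm³ are floored before the log transform (small caliper volumes
  are unreliable); at least 3 measurement days are required.
* `percent_tv_change()`: $(V_{end}-V_{base})/V_{base}\times 100$.
* `tgi()`: with $GM_g$ the geometric mean over animals of
  $V_{end}/V_{base}$, $\mathrm{TGI\%} = 100\,(1-(GM_T-1)/(GM_C-1))$. A
  static treated arm scores 100%; regression exceeds 100% and is reported
  unclipped; a non-growing control ($GM_C \le 1$) makes the ratio
  meaningless and the result is flagged undefined instead. The geometric
  mean (not arithmetic) is used because volume changes are
  multiplicative and the comparison statistic operates on log change.
* `compare_to_vehicle()`: Welch's unequal-variance $t$ on
  $\log(V_{end}/V_{base})$, one-tailed with the fixed alternative
  "treatment reduces growth" (two-tailed behind a flag). No
  multiple-testing correction is applied by default, matching
  per-comparison reporting practice.
* Endpoint rule: the comparison day is the last day measured in both arms;
  an animal missing that day is carried forward from its last observation
  only if it lies within 7 days of the endpoint, otherwise it is excluded
  with a message.

## In vitro proliferation and potency

`normalize_growth()` maps live-cell counts (total minus dead) onto a growth
scale where the day-0 plate mean is 0 and the untreated endpoint mean is 1;
values below 0 indicate net cell loss and are retained as cytotoxic
signal. `fit_4pl()` fits the four-parameter logistic on log10
concentration,

$$y = bottom + \frac{top-bottom}{1 + 10^{\,h\,(\log_{10} c - \log_{10} IC_{50})}},$$

reporting the curve-midpoint (relative) IC50, the Hill slope, whether the
IC50 lies inside the tested ladder, and $\mathrm{pIC}_{50} =
-\log_{10}(IC_{50}\ \mathrm{in\ mol/L})$. Initialization takes top/bottom
from the response extremes, the midpoint from the concentration nearest
half-range, and $h = 1$; a response range below 0.1 is declared degenerate
(flat plate) and no IC50 is reported. `bottom_of_curve()` returns the
saturating-drug plateau, flagged cytotoxic below zero (with a small
numerical tolerance).

## Signature scoring and group comparison

`zscore_normalize()` standardizes each gene across samples; the population
SD (divide by $n$) is the default convention, switchable to sample SD.
Constant genes carry no information on the z scale and are dropped with a
warning. A signature is a set of genes with directions ±1
(induced/repressed), and a sample's score is the mean of direction × z over
signature genes, so pathway activation raises the score. The packaged
ER-activity signature (`er_activity_signature_synthetic.tsv`) is an
illustrative list of well-known ER target genes, not a published signature;
scores on real data should use the user's own curated list.

`compare_scores_ancova()` fits `score ~ covariate + group` and reports the
F test of the group term; a missing or constant covariate reduces it to
one-way ANOVA. The default in vivo covariate is baseline tumor volume.

A subtlety the tests encode: when a shift of $s$ noise-SDs is planted in
the treated half of the samples, z-scoring over the pooled samples inflates
the per-gene SD by the group separation, so the expected score delta is not
$s$ but

$$\Delta = \frac{s}{\sqrt{(2n-1)/(2n) + s^2/4}},$$

about 1.42 for $s = 2$ and $n = 20$ per group. Recovery tests assert this
derived expectation.

## The synthetic-study generator

`simulate_study()` emulates the preclinical study designs the analytics are
meant for: dose arms with uniform 150–300 mm³ enrollment, twice-weekly
calipering, repeat oral dosing, western-blot-like ER time courses and an
arm-level composite plasma profile. Noise is multiplicative lognormal for
volumes and concentrations (caliper and bioanalytical error scale with the
measurement; a CV of $c$ maps to $\sigma_{\log} = \sqrt{\log(1+c^2)}$ with
median 1) and additive Gaussian on log expression. Default CVs — 15%
volumes, 10% concentrations, 15% ER — are package choices in the range
typical for these assay types; no published inter-animal variability was
available to anchor them. With all noise at zero every observable equals
its deterministic model value exactly, which the tests check to 1e-9.

Reproducibility: one global integer seed drives deterministic per-unit
substreams (one per animal, per arm-level concentration series, per ER
replicate), so the same seed gives a bit-identical bundle and per-arm
subsets are reproducible in isolation.

`simulate_cohort()` plants a known sensitive fraction across PDX-like
models: sensitive models carry the full ER-growth link, insensitive models
have no link ($b_{kill}=0$). The default 21-day study matters: at
$b_0 = 0.02$ an untreated tumor grows $10^{0.42} \approx +163\%$, safely
above the +100% sensitivity threshold, whereas a 14-day study (+91%) cannot
separate the classes at all. The waterfall's observed sensitive fraction
then equals the planted fraction exactly under the default noise.

What the generator does *not* emulate: western-blot imaging artifacts,
RNA-seq count noise (expression is simulated directly on the normalized log
scale), drop-out from tumor ulceration or toxicity, inter-animal PK
variability, and circadian or feeding effects on exposure. Passing
recovery tests on this generator therefore demonstrates correctness of the
estimators under the stated error model, not performance on raw
experimental data.

## Problem sizes and runtime

The shipped tests and the acceptance script use desk-scale sizes chosen so
the full chain stays interactive: 4 dose arms × 8 animals for PK/PD
recovery (20 replicate studies), 1000 seeds for the half-life and
calibration checks, 200 plates for the noisy-potency check, 400 genes × 40
samples for expression, and a 20-model cohort in the demo pipeline. These
sizes make the Monte-Carlo standard errors comfortably smaller than the
tolerances being asserted.

## Known limitations

* PK is one-compartment and linear; the fitted parameters are effective
  descriptors of a richer true profile.
* The ER→growth link and all generator variability magnitudes are package
  design choices; recovery results quantify estimator behavior under this
  model, not under model misspecification.
* `tgi()` is undefined for non-growing controls by construction; studies
  with regressing vehicle arms need a different comparator.
* The sensitivity threshold (≤100% change from baseline) is a single fixed
  rule; the per-arm Welch test is reported alongside but does not enter the
  classification.
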
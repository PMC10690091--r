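# Demo synthetic efficacy study: once-daily oral dosing of a SERD across
# four dose arms plus vehicle, with a PDX-like cohort for the waterfall.
study:
  n_per_arm: 6
  duration_days: 21
  enrollment_volume_range: [150, 300]
  interval_h: 24
  molecular_weight: 452
  arms:
    vehicle: 0
    serd_1mgkg: 1
    serd_3mgkg: 3
    serd_10mgkg: 10
    serd_30mgkg: 30
truth:
  pk: {ka: 1.0, ke: 0.13862944, vd_over_f: 5.0, fu: 0.01}
  er: {kout: 0.23104906, smax: 9.0, sc50: 0.4}
  growth: {b0: 0.02, bkill: 0.05, gamma: 1.0}
noise:
  volume_cv: 0.15
  conc_cv: 0.10
  er_cv: 0.15
cohort:
  n_models: 20
  sensitive_fraction: 0.6
alpha: 0.05
seed: 1
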
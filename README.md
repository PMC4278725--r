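# liverdce

Quantification chain for dynamic contrast-enhanced (DCE) MRI of the liver
built around a dual-bolus arterial input function (AIF) strategy. It is
aimed at perfusion-imaging researchers who have ROI-averaged signal-time
curves from a two-part protocol — a low-dose pre-bolus imaged in the
abdominal aorta at high temporal resolution (0.2 s saturation-recovery
TurboFLASH), followed by a full-dose main bolus imaged volumetrically at
~3.2 s (3D spoiled gradient echo) — and want hepatic perfusion parameters
with a trustworthy AIF.

The problem: the full-dose aortic first pass is clipped by the nonlinear
SPGR signal-concentration relationship (saturation) and blurred by the
slow volumetric sampling. The package's answer is the pre-bolus method:
under a linear-time-invariant assumption, the AIF of the main injection
(rate `r_m`, duration `T_m`) is reconstructed from the measured pre-bolus
response `C_p(t)` (rate `r_p`, duration `T_p`) as

    C_a(t) = (r_m / r_p) * sum_{k=0}^{n-1} w_k * C_p(t - k*T_p),
    n = ceil(T_m / T_p),

with a fractional final weight so the delivered dose is conserved.

Around that core the package provides:

* `spgr_signal()`, `sat_recovery_signal()`, `signal_to_concentration()`,
  `blood_to_plasma()` — forward signal models and monotone model-based
  inversion to gadolinium concentration, with M0 calibrated from the
  pre-contrast baseline;
* `reconstruct_aif()`, `injection_protocol()` — the LTI reconstruction;
* `detect_trise()`, `shape_parameters()` — bolus descriptors Cpeak, TTP,
  upslope, AUC60, FWHM;
* `simulate_liver()`, `fit_dual_input()`, `derive_perfusion()` — the
  dual-input single-compartment liver model
  `dC_L/dt = k1a C_a(t−τa) + k1p C_p(t−τp) − k2 C_L`, fitted by a delay
  grid plus bounded Levenberg–Marquardt, and converted to
  Fa, Fp, Ft, ART, PV, DV, MTT;
* `cv_pair()`, `bland_altman()`, `test_retest_cv()` — between-method and
  test-retest reproducibility statistics;
* `subject_truth()`, `generate_subject()`, `generate_cohort()` — a
  synthetic two-protocol cohort generator with known ground truth;
* `run_pipeline()` and a thin CLI (`inst/scripts/liverdce`) with
  `run-all`, `simulate`, `convert`, `reconstruct`, `metrics` and `fit`
  subcommands driven by a YAML/JSON config.

## Worked example

Simulate one subject at the study's acquisition settings, reconstruct the
AIF from its pre-bolus, and fit the liver model:

```r
library(liverdce)

pro <- injection_protocol(weight = 70)
pro
#> <injection_protocol>
#>   pre-bolus : 1.30 mL @ 4.10 mL/s  (T_p = 0.317 s)
#>   main bolus: 7.00 mL @ 5.00 mL/s  (T_m = 1.400 s; 0.05 mmol/kg x 70 kg)

subj <- generate_subject(subject_truth(seed = 42), pro)

conv <- signal_to_concentration(subj$prebolus_si, n_baseline = 25,
                                acquisition_defaults()$pre,
                                relaxation_params(T10 = 1.2, r1 = 6.3))
conv
#> <dce_conversion> M0 = 1004; 25 clamped to 0; 0 saturated
#> <dce_ts> 301 samples, t in [0, 60] s (uniform 0.2 s grid), values in mmol/L

aif <- reconstruct_aif(blood_to_plasma(conv$series, 0.42), pro)
shape_parameters(aif, detect_trise(aif, n_baseline = 25))
#> <aif_shape> Cpeak 8.073 mmol/L @ 15.40 s | Trise 9.03 s | TTP 6.37 s |
#>   upslope 1.267 mmol/(L s) | AUC60 95.76 mmol s/L (truncated) | FWHM 8.92 s

res <- process_subject(subj$prebolus_si, subj$mainbolus_aorta_si,
                       subj$portal_si, subj$liver_si, hematocrit = 0.42,
                       protocol = pro)
res$fit_pre
#> <dce_fit> sse = 0.009372 (converged, 5 iter at winning node)
#> <kinetic_params> k1a 0.008965 /s | k1p 0.07651 /s | k2 0.05483 /s |
#>   tau_a 1.50 s | tau_p 4.00 s
#> <perfusion_params> Fa 53.8 | Fp 459.1 | Ft 512.9 mL/min/100mL |
#>   ART 10.5% | PV 89.5% | DV 155.9% | MTT 18.2 s
```

Reading the numbers: the 25 pre-arrival samples clamped to zero are
sub-baseline noise; the reconstructed AIF shows the tall, narrow first
pass the pre-bolus method is designed to preserve (peak ~8 mmol/L plasma,
FWHM ~9 s; AUC60 is flagged because the 60 s pre-bolus window ends before
`Trise + 60 s`). The fitted rates sit within a few percent of this
subject's simulated truth (`k1a` 0.009, `k1p` 0.07, `k2` 0.053 s⁻¹) and
convert to a portal-dominant flow pattern typical of liver parenchyma.

The same chain runs from the shell:

```sh
Rscript inst/scripts/liverdce run-all --config cfg.yaml --out results/
```

See `vignettes/liver-perfusion-methods.Rmd` for the models, numerical
choices, generator design and limitations.

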
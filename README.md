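# qmriresp

Quantitative MRI parameter mapping and treatment-response prediction for
nasopharyngeal carcinoma (NPC) treated with induction chemotherapy (IC).

Clinical question behind the pipeline: can functional-MRI parameters
measured *before* chemotherapy tell responders from non-responders, so
that patients unlikely to benefit can be switched to other treatment
early? The package is for imaging scientists and biostatisticians who
want that analysis as tested, reusable code rather than vendor-console
output: voxel-wise model fitting, ROI change metrics, RECIST 1.1
labelling, and the diagnostic-statistics layer, plus a seeded synthetic
cohort so everything runs end to end without patient data.

## Models

Four signal models are fitted voxel-wise to produce parameter maps, each
reported on its conventional scale:

* **DWI** — mono-exponential diffusion, `S(b) = S0·exp(−b·ADC)`;
  ADC (×10⁻⁶ mm²/s) by linear least squares on log-signal.
* **DKI** — diffusion kurtosis, `S(b) = S0·exp(−b·D + b²D²K/6)`;
  MD (×10⁻⁶ mm²/s) and MK (×10⁻³) by bounded nonlinear least squares
  (D ≤ 4×10⁻³, 0 ≤ K ≤ 3), seeded by the exact log-linear solution.
* **IVIM** — bi-exponential intravoxel incoherent motion,
  `S(b)/S0 = (1−f)·exp(−b·Dslow) + f·exp(−b·(Dslow+Dfast))`;
  Dslow (×10⁻⁶ mm²/s), Dfast (×10⁻⁴ mm²/s) and perfusion fraction
  (×10⁻⁴) by the segmented algorithm (b-threshold 200 s/mm²), with a
  joint four-parameter fit as reference oracle.
* **DCE** — standard Tofts two-compartment model,
  `Ct(t) = Ktrans·∫ Cp(τ)·exp(−Kep(t−τ))dτ`, `Ve = Ktrans/Kep`
  (all ×10⁻³), fitted by variable projection under a Parker population
  AIF.

The statistics layer mirrors the clinical analysis: normality-gated
paired and two-group tests, categorical tests by expected-count rules,
logistic combination of the significant pre-treatment markers into a
single score, empirical ROC with DeLong CIs, Youden-optimal cutoffs,
likelihood ratios and predictive values at the cohort prevalence
(36 responders / 20 non-responders), and pairwise DeLong comparison of
correlated ROC curves. See `vignette("qmri-response-pipeline")` for the
models, assumptions, and design choices.

## Worked example

The analysis is staged under `analysis/` (simulate → fit → group tables
→ diagnostic performance), each stage writing under `results/`. The same
computations are available directly:

```r
library(qmriresp)

cfg <- cohort_config(seed = 42, voxel_mm = 4, fov_mm = 48, n_slices = 6)
cohort <- generate_cohort(cfg)                    # 56 patients, 36 RG / 20 NRG
tab <- fit_cohort(cohort, cfg,                    # render + voxel-wise fits +
                  models = c("adc", "dki", "ivim"),  # largest-slice ROI means
                  timepoints = c("pre", "post"))
report <- run_stats(cbind(tab, age = cohort$age, sex = cohort$sex))
print(report)
```

Running the staged version (`Rscript analysis/01_simulate.R` … `04_…`)
prints, for the default seed:

```
<cohort_report>
  significant pre-treatment markers: adc_pre, md_pre, dslow_pre
  adc_pre      AUC 0.900 (0.814, 0.986) cutoff 1238 sens 80.6% spec 90.0%
  md_pre       AUC 0.868 (0.754, 0.982) cutoff 1155 sens 97.2% spec 70.0%
  dslow_pre    AUC 0.781 (0.651, 0.910) cutoff 906.8 sens 80.6% spec 70.0%
  pre_score    AUC 0.968 (0.931, 1.000) cutoff 0.8192 sens 86.1% spec 100.0%
```

Reading: on this synthetic cohort, pre-treatment ADC fitted from the
rendered images separates responders from non-responders with AUC 0.90;
tumours below the ~1238 ×10⁻⁶ mm²/s cutoff are called responders with
80.6% sensitivity and 90% specificity, and the logistic combination of
the significant markers does better than any single one. Lower
ADC/MD/Dslow (and higher MK) predicting response matches the direction
expected from tumour cellularity: densely cellular tumours restrict
water diffusion and respond better to cytotoxic chemotherapy.

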
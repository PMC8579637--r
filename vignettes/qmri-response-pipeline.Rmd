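---
title: "Quantitative MRI parameter mapping and response prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI parameter mapping and response prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmriresp)
```

## Scope and shape

`qmriresp` reimplements, as a tested pipeline, the analysis used to ask
whether pre-treatment functional-MRI parameters predict the response of
locoregionally advanced nasopharyngeal carcinoma (NPC) to induction
chemotherapy (IC): voxel-wise fitting of four signal models to produce
parameter maps, ROI summaries and change metrics, RECIST 1.1 responder
labelling, and a diagnostic-statistics layer (group tests, a logistic
combination score, ROC analysis with Youden cutoffs, pairwise DeLong
comparison). Because patient images from such studies are not publicly
deposited, the package ships a seeded synthetic-cohort generator whose
defaults encode the published cohort structure, so that every stage can
be exercised end to end.

The repository is organised as an analysis workflow: numbered drivers
under `analysis/` narrate the stages (simulate, fit, summarize, test) and
write their tables under `results/`, while all computation lives in the
package so the test-suite and the acceptance script call the same code.
The stages are also exposed as functions (`run_simulate()`, `run_fit()`,
`run_stats()`); there is deliberately no separate command-line binary.

## Signal models

All four forward models live in `signal_models` and are the ground truth
for every fitting test.

**Mono-exponential diffusion (DWI).** \(S(b) = S_0 e^{-b\,\mathrm{ADC}}\).
ADC is reported in units of \(10^{-6}\,\mathrm{mm^2/s}\) (a typical NPC
tumour value prints as ~1240).

**Diffusion kurtosis (DKI).**
\(S(b) = S_0 \exp(-b D + \tfrac16 b^2 D^2 K)\), a truncated cumulant
expansion of non-Gaussian diffusion. The quadratic term makes the
exponent non-monotone for large \(b D K\); the expansion is a valid decay
model only while \(b < 3/(D K)\) over the fitted range. The fitting
bounds (\(D \le 4\times10^{-3}\), \(K \le 3\)) keep the model decaying on
the default \(b \in [0, 2000]\) grid; forward evaluation is deliberately
unrestricted.

**Intravoxel incoherent motion (IVIM).**
\(S(b)/S_0 = (1-f) e^{-b D_{slow}} + f e^{-b (D_{slow}+D_{fast})}\): a
tissue water compartment and a perfusing blood compartment of fraction
\(f\) whose pseudo-diffusion adds \(D_{fast}\) to the decay rate.

**Tofts two-compartment pharmacokinetics (DCE).**
\(C_t(t) = K^{trans} \int_0^t C_p(\tau) e^{-K_{ep}(t-\tau)} d\tau\), with
\(V_e = K^{trans}/K_{ep}\) the extravascular-extracellular fraction. The
pipeline operates on concentration series directly; converting scanner
signal intensity to concentration (T1 mapping, flip-angle models) is out
of scope, as is the extended-Tofts plasma-volume term. No arterial input
function is printed in the source study, so the package defaults to the
Parker population AIF (two Gaussians plus a sigmoid-gated exponential,
onset at the first post-baseline frame); a constant step AIF is provided
because its convolution has the closed form
\(C_t(t) = V_e (1 - e^{-K_{ep} t})\) used for exact testing. The
convolution itself is evaluated with the exact update for a
piecewise-linear \(C_p\) between frames, so the step-AIF solution is
reproduced to well below \(10^{-6}\) on a 1 s grid.

**Noise.** Rendered diffusion series receive Rician noise
(\(\sqrt{(s+\epsilon_1)^2+\epsilon_2^2}\)), the magnitude-MRI
distribution whose floor has mean \(\sigma\sqrt{\pi/2}\); concentration
series receive Gaussian noise, since concentration is a derived (signed)
quantity. All noise is seeded and restores the caller's RNG stream.

## Map fitting

Fitting is voxel-wise, vectorized across voxels, with unweighted least
squares throughout (the behaviour of the vendor tool being emulated is
not documented; robust/weighted variants are out of scope). Log-linear
estimates seed every nonlinear fit — deterministic, derivative-friendly
starts with no random restarts.

* **ADC**: ordinary least squares of log-signal on \(b\); with two
  b-values this is the exact two-point formula.
* **DKI**: log-signal is linear in \((\log S_0, D, D^2K)\), giving an
  exact noise-free initialization; a damped Gauss-Newton iteration in the
  signal domain then enforces \(D \in [10^{-5}, 4\times10^{-3}]\),
  \(K \in [0, 3]\).
* **IVIM (segmented, default)**: mono-exponential fit of the
  \(b \ge 200\) tail gives \(D_{slow}\) and the tissue intercept; \(f\)
  is the relative excess of the measured \(b=0\) signal over that
  intercept (clipped into \([0,1]\) with a flag); \(D_{fast}\) is a
  bounded one-parameter golden-section fit on the low-b segment,
  \(D_{fast} \in [D_{slow}, 0.5]\). The b-threshold default of
  200 s/mm² is the standard choice. A full joint four-parameter fit
  (`fit_ivim_joint()`, Levenberg-Marquardt per voxel) is provided as the
  reference oracle; on noise-free tumour-like data the two agree within
  1%. The segmented algorithm assumes the perfusion compartment has
  decayed by the threshold: for \(D_{fast} \lesssim 25\times10^{-3}\)
  mm²/s residual perfusion signal above \(b = 200\) biases \(D_{slow}\)
  beyond the stated tolerances, which is why the recovery tests draw
  \(D_{fast}\) from \([25, 80]\times10^{-3}\) — bracketing the published
  tissue values (\(410.59 \pm 181.5 \times 10^{-4}\) mm²/s).
* **Tofts**: for fixed \(K_{ep}\) the model is linear in \(K^{trans}\),
  so the fit is solved by variable projection — a log-spaced grid over
  \(K_{ep} \in [10^{-3}, 10]\)/min plus golden-section refinement, with
  the optimal \(K^{trans} \ge 0\) in closed form. \(V_e\) is reported as
  the exact ratio and flagged when above 1.

Voxels with non-positive signals (or too few of them) are excluded from
the fitted mask rather than imputed; masked-out voxels never influence
fitted ones. Maps store natural units plus the reporting scale
(\(10^{-6}\) mm²/s for ADC/MD/Dslow, \(10^{-4}\) for Dfast and the
perfusion fraction, \(10^{-3}\) for the kurtosis and the DCE parameters),
and the scale round-trips exactly.

## ROI metrics and response labels

ROI statistics (mean, SD, median, IQR) are computed over the intersection
of the ROI with the fitted mask, on the reporting scale. Quartiles use
linear interpolation between order statistics (R's type-7 default) —
recorded explicitly because published IQRs depend on the convention.
Following the emulated protocol, parameter statistics use the single
largest axial slice of the lesion while volumes use all slices; both
masks are explicit inputs. Change metrics are
\(\Delta = \mathrm{post} - \mathrm{pre}\) and
\(\Delta\% = 100\,\Delta/\mathrm{pre}\). Tumor volume is
area × (slice thickness + interstice gap), summed over slices — the
single-line published formula read as per-slice and summed for
multi-slice lesions. RECIST 1.1 labels the single target lesion PR at a
diameter decrease of 30% or more, PD at an increase of 20% or more that
is also at least 5 mm absolute (the guard is enforced even though the
emulated study does not restate it), CR on disappearance, SD otherwise;
responders (RG) are CR/PR.

## Cohort statistics

Pre/post comparisons use a paired t test when Shapiro-Wilk (α = 0.05; no
test is named in the emulated protocol, Shapiro-Wilk is the default
choice) accepts normality of the differences, otherwise the Wilcoxon
signed-rank test. Group comparisons use the pooled-variance Student t
test when both groups pass normality and Levene's test (mean-centered)
accepts homogeneity, otherwise Mann-Whitney U. Categorical tables use
chi-square, continuity-corrected chi-square or Fisher's exact test by the
usual expected-count rules; for 2×2 tables Fisher is used whenever the
total count is below 40, which is what reproduces the published gender
comparison and the exact-test worked example simultaneously. No
multiple-testing correction is applied (none was applied in the emulated
analysis; p < 0.05 throughout).

Significant pre-treatment markers are combined by maximum-likelihood
logistic regression, all features entered simultaneously; the per-patient
combined score is the fitted responder probability. Complete separation
is flagged and handled by refitting with a tiny ridge penalty
(\(10^{-6}\), standardized features, intercept unpenalized) so a usable
score always exists; aliased features get coefficient zero.

ROC analysis is empirical: AUC as the concordant-pair fraction
\(U/(n_1 n_0)\) (ties half, equal to the trapezoid area), DeLong
structural-components variance for the 95% CI, Youden-optimal cutoff
chosen among midpoints between adjacent observed values, ties broken
toward the smallest cutoff — deterministic, and an achievable operating
point. Marker orientation is auto-selected so AUC ≥ 0.5 and recorded
explicitly (lower ADC/MD/Dslow predict response; higher MK does) rather
than silently sign-flipping. Likelihood ratios are computed from the
selected operating point; predictive values from integer confusion
counts reconstructed at the cohort prevalence (36 responders / 20
non-responders), which reproduces every published predictive value
exactly. Pairs of markers are compared with the paired DeLong test on
the oriented scores; rank-equivalent markers give a zero difference with
p = 1 by construction.

## The synthetic cohort

The generator draws per-patient ground truth from the published group
summaries, then renders images from it, so the pipeline's statistical
behaviour can be checked against known truth.

* **Group structure**: 36 responders, 20 non-responders. Markers with
  published group differences (ADC, MD, MK, Dslow pre-treatment) use
  group-specific distributions; the rest (Dfast, PF, Kep, Ve) are shared.
  Parameters published as mean ± SD are truncated normals; those
  published as median (IQR) — MD, PF, Kep — are log-normals matched to
  median and IQR (positivity and skew). \(K^{trans}\) is derived as
  \(V_e \times K_{ep}\) per patient so the pharmacokinetic identity holds
  exactly; the implied \(K^{trans}\) mean (~0.99/min) sits close to the
  published 0.92/min.
* **Treatment effect**: post = pre × (1 + Δ%/100), with group-specific
  Δ% normals where published (diameter −49.24 ± 15 vs −18.62 ± 10;
  volume −64.98 ± 17.77 vs −30.35 ± 14.94; ΔADC%, ΔMD%, ΔMK% from the
  group table) and whole-cohort pre→post shifts otherwise (Dslow +20.4%,
  Dfast −11.6%, PF +22.4%, Kep −35.1%, Ve +22.1%). The published ΔMK
  magnitudes are used with a negative sign, since kurtosis falls after
  treatment. Diameter changes are truncated to each group's
  RECIST-consistent range and labels are then *derived* from the
  simulated diameters via `recist_classify()`, so labels, categories and
  geometry are mutually consistent by construction.
* **Correlation**: a single latent "response aggressiveness" factor with
  loading 0.5 ties the response-linked markers (and the size changes)
  together; independent markers would make the combined logistic score
  unrealistically easy. The true inter-parameter correlations in NPC are
  unknown; the loading is a declared knob, not an inference.
* **Geometry**: lesions are ellipsoids (axis ratios 0.8 in-plane, 0.7
  through-plane) sized from a log-normal diameter (median 2.4 cm,
  consistent with the published post-treatment diameters plus their
  changes). Recorded volumes apply the slice-sum formula to analytic
  cross-section areas at slice centers; rendered masks voxelize the same
  ellipsoid, so mask-derived volumes converge to the recorded ones as
  voxels shrink. Post-treatment in-plane axes follow the diameter change
  and the through-plane axis absorbs the remaining volume change — the
  published diameter and volume reductions are not consistent with
  isotropic scaling, so the aspect ratio must move.
* **Rendering**: lesion voxels carry the patient's parameters with 5%
  multiplicative within-tumour variability; the background is a fixed
  healthy-tissue parameter set; S0 is 100 with SNR 50 Rician noise
  (0.03 mM Gaussian for concentration). Per-patient noise seeds are
  derived from the cohort seed, so patients are independent and every
  render is repeatable.

What the generator does **not** emulate: scanner physics (coil profiles,
EPI distortion, motion — pre/post scans are perfectly co-registered by
construction), irregular tumour shapes, intra-tumour spatial structure
beyond i.i.d. variability, signal-to-concentration conversion, and any
real biological coupling between the four models' parameters beyond the
single latent factor. Passing tests therefore demonstrate correctness of
the estimation and statistics machinery under the published cohort
structure, not performance on real images.

## Problem sizes and numerical choices

The test-suite and the acceptance script render at 4 mm in-plane voxels
(48 mm field of view, 6 slices), giving lesions of tens to a few hundred
voxels — enough for stable ROI means while keeping a full 56-patient
render-and-fit cycle near a second per modality; the package default is
2 mm. Direction-consistency checks use 20 seeded replicates of the full
generate→render→fit→summarize path; the DeLong size check uses 500
replicates at the cohort's 36/20 split. Golden-section refinements run a
fixed 50–60 iterations (bracket shrink < 1e-10); the DKI Gauss-Newton
runs at most 60 damped iterations with per-voxel step acceptance.
Degenerate inputs are handled explicitly: all-zero concentration fits
return \(K^{trans} = 0\) with rate parameters unfit, perfusion-free
voxels leave \(D_{fast}\) unfit, constant paired differences short-cut
to a zero t statistic, and sub-voxel lesions at coarse resolution keep
their nearest voxel so a lesion never vanishes from a rendered volume.

## Known limitations

* The segmented IVIM estimator is biased when pseudo-diffusion is slow
  relative to the b-threshold (see above); the joint fit is available
  where that matters.
* DeLong CIs are the only interval method (no bootstrap), matching the
  emulated analysis.
* The generator's marginal distributions are faithful to the published
  summaries, but the joint distribution (one latent factor) is a modeling
  choice; combined-score AUCs on synthetic data should be read with that
  in mind.
* Predictive values assume the study prevalence; they do not transport to
  other prevalences.
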
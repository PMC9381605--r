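---
title: "Threshold versus probabilistic classification of ischemic regions on CT perfusion maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold versus probabilistic classification of ischemic regions on CT perfusion maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctprob)
library(dplyr)
```

## The problem

CT perfusion (CTP) imaging of acute ischemic stroke yields four co-registered
parameter maps per patient: cerebral blood flow (CBF, mL/100g/min), cerebral
blood volume (CBV, mL/100g), mean transit time (MTT, s) and time to peak
(TTP, s). Clinical software outlines the irreversibly damaged core and the
salvageable penumbra by thresholding a *single* parameter map, and every
vendor uses a different rule (`preset_rules()` collects the common ones).
An alternative is a voxelwise multivariable logistic model that folds all
four parameters into one probability of tissue being ischemic,

$$P = \frac{1}{1 + e^{\,c_\mathrm{int} + c_\mathrm{CBF}\cdot\mathrm{CBF} +
c_\mathrm{CBV}\cdot\mathrm{CBV} + c_\mathrm{MTT}\cdot\mathrm{MTT} +
c_\mathrm{TTP}\cdot\mathrm{TTP}}},$$

with the sign convention that reduced perfusion (low CBF/CBV) and delayed
transit (high MTT/TTP) both push $P$ up, so $c_\mathrm{CBF}, c_\mathrm{CBV} > 0$
and $c_\mathrm{MTT}, c_\mathrm{TTP} < 0$ for well-formed data.

`ctprob` implements both classification routes end to end — training,
map-level prediction, volumetry and evaluation — driven by a digital phantom
cohort generator with exact ground truth, so that the two routes can be
compared under controlled conditions. Patient scenarios follow the
recanalization logic: after successful recanalization (REC) the follow-up
infarct equals the admission core, under persistent occlusion (OCC) it equals
the whole hypoperfused region (core plus penumbra). The REC arm therefore
trains and tests core classification, the OCC arm the hypoperfused region.

## The synthetic cohort

`phantom_spec()` / `build_phantom()` rasterize a bilateral brain-shaped
ellipsoid with a unilateral spherical core nested in a penumbra; the
mid-sagittal plane of the grid splits the hemispheres (with an odd first
axis the single midline column is assigned to the right hemisphere).
`generate_cohort()` draws per-case lesion radii, location and side and
jitters the class means by ±10%, then splits each scenario 2:1 into
training and test cases — the same design as a clinical training/test
split. All draws are reproducible from one master seed; per-case seeds are
derived deterministically.

Class-conditional parameter distributions (`default_tissue_params()`) are
normal with means seeded from published clinical cutoffs: core CBF well
below the 9–14 mL/100g/min range where core thresholds live, core CBV near
1.2 mL/100g, hypoperfused TTP above ~6 s, healthy CBF around
50 mL/100g/min. The standard deviations are deliberately wide (e.g. healthy
CBF 50 ± 20). Narrow spreads make the classes nearly separable, which
produces trained voxelwise AUCs of ~1.0 and a quasi-separated logistic fit
— nothing like the published voxelwise regime, where AUCs sit around
0.7–0.8 and Youden indices around 0.3–0.5. The wide defaults put trained
AUCs in the 0.85–0.95 band on the default cohort: still cleaner than
clinical data, but in a regime where thresholds and logistic fits behave
the way they do on patients.

Two features of real deconvolved maps that the generator reproduces on
purpose:

* **Spatially correlated noise.** Sampled maps draw their within-class
  deviates from a unit-variance Gaussian random field smoothed to a 4 mm
  correlation length (`noise_correlation_mm`). With strictly independent
  voxel noise, false-positive voxels are isolated specks and the 5 mm
  morphological opening removes every one of them, which would make
  threshold volumetry artifact-free by construction — the cleaning step
  and the hemisphere-difference volume exist precisely because real maps
  carry correlated artifacts. Setting the correlation to 0 restores
  independent truncated-normal draws.
* **Non-negativity.** Parameters are truncated (independent draws) or
  clipped (correlated field) at zero; means are far enough from zero that
  this matters only for the core class tails.

What the phantom does **not** model: anatomically realistic geometry,
partial-volume effects, vessels, motion or beam-hardening artifacts, and
any mismatch between the follow-up segmentation and the admission lesion
(the scenario masks are exact by construction). Passing results on this
cohort therefore demonstrate correctness of the pipeline and the *relative*
behaviour of the two classification methods under controlled noise — not
clinical performance.

## The forward CTP model and the deconvolution

`simulate_ctp()` and `bsvd_deconvolve()` share one discrete indicator-
dilution model, built around the block-circulant convolution matrix of the
arterial input function (AIF) zero-padded to twice the scan length — the
standard delay-insensitive formulation. The forward model generates each
tissue curve as

$$C_t = \kappa\,\frac{\mathrm{CBF}}{6000}\, A\,R, \qquad
\kappa = \rho / k_H,$$

with $A$ the circulant AIF operator (elements $\Delta t\,C_a$), $R$ a
sampled exponential residue, $\rho$ = 1.05 g/mL tissue density and
$k_H$ = 0.73 the hematocrit correction; the AIF itself is a gamma-variate
(`aif_model()`, onset 2 s, peak ≈ 6 s, ≈ 300 HU peak). Three numerical
choices deserve explanation:

* **Residue decay.** On a 2-s grid the pointwise-sampled exponential
  $e^{-t/\mathrm{MTT}}$ has discrete area
  $\Delta t/(1 - e^{-\Delta t/\mathrm{MTT}})$, which overshoots MTT by 27%
  at MTT = 4 s — the sampled curve would encode the wrong CBV. The
  simulator instead uses $e^{-t/\tau}$ with
  $\tau = -\Delta t / \log(1 - \Delta t/\mathrm{MTT})$, whose *discrete*
  area equals MTT exactly, so the residue peak encodes CBF and the curve
  area encodes CBV = CBF·MTT/60 simultaneously. This requires
  MTT > $\Delta t$; classes violating that are rejected.
* **Delays quantized to whole samples.** TTP is encoded by delaying the
  curve an integer number of frames so it peaks at the class TTP
  (sub-sample shifts would interpolate and damp the peak, biasing CBF).
  Target TTPs earlier than the undelayed peak are clamped to zero delay
  with a warning. The block-circulant inverse is insensitive to these
  delays by construction.
* **Truncation at 10%.** Singular values below
  `svd_truncation_fraction` × the largest are zeroed. The default is 0.10:
  at 0.15 the truncation cuts into the spectral components of smooth
  residue functions and biases noise-free CBF by up to −33% at short MTT,
  while at 0.10 noise-free recovery is exact to <0.1% and recovery under
  ~1 HU tissue noise remains stable (≈ +5% mean bias). The fraction is a
  `deconv_settings()` field for users who want heavier smoothing on
  noisier data.

CBV is computed from the trapezoidal tissue/AIF area ratio, MTT from the
central volume principle (CBV/CBF × 60, zero where CBF is zero, flagged),
and TTP as the earliest argmax of the tissue curve in seconds from scan
start. TTP here is the *tissue-curve* peak time, absolute from scan start;
vendor tables use "TTP" and "Tmax" (residue peak time) interchangeably
without defining either, and this package standardizes on the tissue-curve
convention throughout, so trained TTP cutoffs are only comparable to vendor
Tmax rules up to an AIF-arrival offset.

## Training

The training sample space per scenario pools, over the training cases, the
parenchymal voxels of the lesion-bearing hemisphere on axial slices where
the follow-up infarct segmentation is non-empty
(`assemble_voxel_table()`); this is the standard guard against extreme
class imbalance. Rows with an outlier in any parameter are removed by the
1.5 × IQR rule with quartiles by linear interpolation
(`remove_outliers()`). The fence scope matters: computed over the pooled
table (`by = "table"`, the default, matching the textbook form of the
rule), the fences sit inside the healthy majority and — at the percent-level
ischemic prevalence of this sample space — delete essentially the whole
ischemic class. The rule's purpose, however, is to remove *high-leverage*
voxels: normally perfused voxels inside the segmented region and
hypoperfused voxels outside it, which is a within-class notion. The
pipeline therefore applies the fences per outcome class
(`by = "label"`), which trims exactly those label-inconsistent tails and
leaves both classes intact.

Thresholds: `roc_curve()` fixes the classification direction a priori
(ischemic below the cutoff for CBF/CBV, above for MTT/TTP — published
rules are all one-sided), takes candidate cutoffs at midpoints between
consecutive sorted unique values (a fixed grid is available via the
`cutoffs` argument), and computes AUC by trapezoidal integration of the
monotone ROC path; this equals the pairwise concordance probability with
ties counted ½, which the test suite verifies by brute force.
`select_threshold()` keeps the parameter with the largest AUC (ties broken
in the fixed order CBF, CBV, MTT, TTP) and maximizes the Youden index
J = sensitivity + specificity − 1; ties in J break toward the cutoff that
classifies fewer voxels as ischemic, the clinically conservative choice.

Probability models: `fit_logistic()` is maximum-likelihood logistic
regression (IRLS via `stats::glm`, up to 100 iterations) of the voxel
label on the four parameters, with the fitted coefficients negated into
the sign convention above. Perfect separation and collinear designs are
rejected with diagnostics rather than silently returning divergent
coefficients. Published coefficient sets for three processing methods
(ISP, bSVD, NLR) ship as `reference_coefficients()` /
`reference_model()`, and published threshold rules as
`reference_thresholds()`; they serve as regression fixtures and as
ready-made models for new maps.

## Classification and volumetry

`apply_threshold()` produces a binary summary map with strict
inequalities, inside the parenchyma only, and refuses rules whose units
disagree with the map metadata. `predict_probability()` evaluates the
logistic form through `plogis`, which saturates instead of overflowing for
|z| beyond ~700, and returns 0 outside the parenchyma.

Threshold-based volumes (`threshold_volume()`) count flagged voxels times
the voxel volume after morphological cleaning: binary opening then closing
with a 5 mm-diameter spherical element (`morphological_clean()`). The
element is rasterized in physical coordinates — a voxel belongs to it iff
its centre lies within 2.5 mm of the element centre — so with 5 mm slices
it flattens to an in-plane disc, and if the spacing exceeds the radius on
every axis it degenerates to a single voxel and a warning is issued. The
closing's erosion treats out-of-grid space as foreground (the complement
duality), which keeps closing extensive; the opening's erosion treats it
as background, so boundary islands cannot survive.

Probabilistic volumes (`probabilistic_volume()`) sum probability × voxel
volume over each hemisphere and take the absolute difference. No
morphology is applied: symmetric noise cancels between hemispheres, which
is the method's own noise control. A warning flags the (miscalibrated)
case where the contralateral sum exceeds the ipsilateral one. Because
healthy voxels on the lesion side are slightly outnumbered by those on the
contralateral side, the estimator carries a small negative bias of order
(lesion volume) × (mean healthy-voxel probability); on the default cohort
this is a few mL for OCC lesions and negligible for REC.

## Evaluation

`precision_recall_curve()` scores pooled test-split voxels of the ischemic
hemisphere on fixed printed grids (CBF 1–20 by 1, CBV 0.1–2.0 by 0.1, MTT
25–5 by 1, TTP 15–5 by 0.5, probability 95–5% by 5%; an alternative
coarser grid for commercial-style maps via `pr_grids("isp")`). Probability
classifies at P ≥ cutoff (inclusive, so both grid ends are attainable);
parameters use their fixed strict directions. Precision with an empty
positive set is recorded as missing, never as zero. Voxels are pooled
across test cases rather than averaged per case; per-case curves can be
built by calling the function per case.

`pr_dominance_fraction()` compares a parameter curve against the
probability curve at matched recall: parameter grid points whose recall
falls inside the recall range attained by the probability grid are
matched by linear interpolation; points outside that range have no
probability operating point on the printed grid and are excluded rather
than extrapolated.

`volume_difference_stats()` summarizes per-case predicted-minus-true
volumes (median, interpolated quartiles, IQR, mean), and
`paired_t_test()` compares the two methods' mean volume differences with a
standard two-tailed paired t-test (significance at p < 0.05; identical
series give a no-difference result, zero-variance non-zero differences
give p = 0). `run_experiment()` orchestrates the whole comparison —
training on the training split only, with an explicit leakage check — and
returns rules, models, PR curves, per-case volumes and differences, the
distribution summaries and the paired tests. `run_pipeline()` wraps it
behind a YAML config and writes CSV/JSON reports.

On the default cohort (30 REC + 30 OCC, 96×96×12 voxels at 2×2×5 mm,
default class spreads, 4 mm noise correlation) the probability map
dominates every single-parameter precision-recall curve at every matched
recall point, and probabilistic volumes land within a few mL of truth
while Youden-threshold volumes overestimate by tens of mL — the same
qualitative ordering reported for clinical data. These are the problem
sizes used by the test suite and the acceptance script; they run in well
under a minute each on one CPU.

## Known limitations

* The phantom's four parameters are conditionally independent given the
  class; real maps have strong inter-parameter correlation (MTT and TTP
  derive from the same curves), which weakens multivariable models —
  dominance margins here are optimistic.
* The "sampled" map mode bypasses deconvolution; the "ctp" mode simulates
  and deconvolves but uses spatially uniform class-mean kinetics.
* Published coefficients and thresholds are tied to their processing
  methods and acquisition protocols; applying them to maps produced by
  other software transfers that calibration error.
* Relative (contralateral-normalized) vendor rules are represented but not
  evaluated; no standard definition of relative values exists.
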
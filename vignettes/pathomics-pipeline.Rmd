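---
title: "Contrastive-clustering pathomics: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive-clustering pathomics: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the places where the design was genuinely open and a decision had to be
made. Code chunks are illustrative and not evaluated at build time; every
empirical claim made here is one the test suite or the worked examples
actually compute.

## 1. The pipeline at a glance

1. **Tiling and tissue masking** — images are cut into non-overlapping
   224 × 224 tiles on a regular grid anchored at the origin; partial border
   tiles are dropped. Each tile's BT.601 luminance histogram is
   Otsu-thresholded and pixels strictly darker than the threshold count as
   tissue (stained tissue is darker than the white background). Tiles with
   coverage ≥ 60% are retained.
2. **Self-supervised contrastive clustering (DL-CC)** — two augmented views
   of each tile pass through a shared-weight encoder; three losses are
   optimized jointly (Section 3).
3. **Featurization** — a slide's feature vector is the proportion of its
   tiles assigned to each of the M clusters (a point on the simplex).
4. **Signature** — univariate Cox screen (p < 0.05), multivariate Cox fit,
   retained coefficients form a linear risk score; a 5-year time-dependent
   ROC fixes the slide-level threshold.
5. **Stratification and evaluation** — slide labels (high iff score >
   threshold) are aggregated per patient by voting (all high → high, all
   low → low, mixed → intermediate); groups are compared with Kaplan–Meier
   curves, log-rank tests and covariate-adjusted Cox models.

## 2. Tiling, masking, augmentation

The tiling rule is pure grid arithmetic: `floor(H/224) * floor(W/224)`
tiles, 0-based `(row, col)` indices, tile `(r, c)` covering the half-open
pixel block starting at `(r·224, c·224)`. Images smaller than one tile
yield an empty set with a warning rather than an error, so manifests with
the occasional undersized core do not abort a run.

Two boundary conventions had to be fixed:

- **Coverage boundary.** Retention is *inclusive* at the 60% threshold
  (coverage ≥ 0.60). The inclusive rule makes the filter idempotent and
  the monotonicity property exact (raising the threshold can only shrink
  the retained set).
- **Otsu tissue polarity.** Tissue = pixels strictly *below* the
  threshold. Constant-intensity tiles have no separable foreground and are
  assigned coverage 0 — an all-white (or any flat) tile can therefore
  never pass the filter.

Six augmentation operators build view pairs: horizontal/vertical flips
(p = 0.5 each), rotations from {0°, 90°, 180°, 270°} (right angles keep
tiles square without interpolation), contrast gain in [0.8, 1.2] about
mid-gray, scaling in [0.9, 1.1] with bilinear resampling followed by
center crop or white padding back to shape, HSV jitter (hue ± 0.05
wrapping, saturation/value ± 0.2), and Gaussian noise with σ drawn from
[0, 8] 8-bit units. The ranges are conventional mild-augmentation choices
for histology tiles — strong hue shifts would destroy stain identity —
and all are exposed in `augment_params()`. Every draw is seeded;
identical `(seed, ops, input)` reproduce the output bit-exactly, which the
trainer relies on for run-to-run determinism.

## 3. The DL-CC objective

Let `z_a, z_b ∈ R^{N×d}` be the encoder outputs of the two views.

**Representation loss.** Columns are batch-standardized (mean 0, biased
variance 1, ε = 1e-8 inside the square root) and cross-correlated:
`c = (1/N) BN(z_a)^T BN(z_b)`, then

`L_rep = Σ_i (c_ii − 1)² + λ Σ_{i<j} c_ij²`, λ default 0.005.

Two printed-formula ambiguities were resolved as follows. First, the
*scaling*: with per-feature batch standardization, only a 1/N scaling makes
the diagonal a true correlation with attainable target 1; a literal 1/d
mode (`normalization = "paper_1_over_d"`) is retained for fidelity
experiments but is not the default, since with 1/d the diagonal target is
unreachable for N ≠ d and the loss would never vanish. Second, the
*off-diagonal sum* runs over the strict upper triangle (i < j) exactly as
printed, not over both triangles.

**Instance loss.** A two-layer projection head maps z to h; rows are
L2-normalized and the 2N projections form an NT-Xent stack: each sample's
sole positive is its counterpart view, cosine similarity / τ_instance
(default 0.5) are the logits over the remaining 2N − 1 candidates, and the
per-sample cross-entropies are averaged. At N = 1 the only candidate is
the positive and the loss is exactly 0. The per-sample terms of the
printed average are not defined in the source formulation; NT-Xent is the
form used by the contrastive-clustering literature that formulation cites,
and is adopted here.

**Cluster loss.** The cluster head ends in a softmax, so each tile's soft
label is a probability vector over M clusters. Each cluster's N-vector of
assignment probabilities (a *column* of the soft-label matrix) is the
contrastive unit: the 2M columns from both views form the same NT-Xent
stack (τ_cluster default 1.0), and the entropy
`H(Y) = −Σ_i [P_a(i) ln P_a(i) + P_b(i) ln P_b(i)]` of the mean assignment
probabilities is subtracted. Natural logarithms, `0·ln 0 := 0`. The −H(Y)
term is the anti-collapse pressure: assignments concentrated in few
clusters lower H(Y) and raise the loss; the loss is bounded below by
−2 ln M.

**Total.** `Loss = (L_inst + L_clu)(1 − α) + L_rep · α`, α default 0.5
(the balance parameter is not specified in the source; 0.5 weights both
objectives equally and is exposed in the configuration).

All three losses and the full composite are implemented with exact
analytic gradients (the batch-standardization backward accounts for the ε
term), and the test suite checks every gradient against central finite
differences and every loss against brute-force double-loop oracles.

## 4. Backbones: published-scale contract vs desk-scale implementation

The published-scale profile — ResNet50 twin encoder, d = 2048, M = 50,
224-pixel tiles, 60% coverage, six augmentation operators — is kept as
the default `dlcc_config()` so that configuration-level fidelity is
testable. It is a *contract*: no pretrained convolutional stack is bundled,
and `dlcc_init()` refuses it with an informative error.

The trainable profile is `dlcc_desk_config()`: block-mean pooling of the
(augmented) tile to an 8 × 8 × 3 grid, then a two-layer perceptron to
d = 64, with 2-layer instance (→ 32) and cluster (→ M = 5) heads. The
choice of a pooled-pixel MLP rather than a small convolutional network is
deliberate: the package trains in plain R matrix arithmetic with exact
manual backpropagation, and dense matrix products are the operation R does
at native speed. On texture classes distinguished by color and blob
statistics, pooled-pixel features are sufficient for the cluster structure
to be learnable, which is what the desk-scale profile exists to
demonstrate; it makes no claim of matching a convolutional encoder on real
histomorphology.

Training follows the seeded loop: one augmented pair per tile per epoch,
Adam (learning rate 3e-4, weight decay 1e-5), last-epoch checkpoint,
per-epoch loss logs, and a hard abort naming the component if any loss
turns non-finite. Mini-batches need at least 2 samples because the
representation loss standardizes over the batch. For the desk profile,
augmentation happens at the 32 × 32 working resolution (tiles are
block-mean downscaled once): augmenting before downscaling would cost ~50×
more per epoch for no change in the pooled statistics the encoder sees.

The 4:1 training:testing split is applied at the *patient* level — all
slides and tiles of a patient land on one side — matching the cohort
design it reproduces and preventing leakage of intra-patient correlation.

## 5. From clusters to a survival signature

Slide features are HPC proportions (`slide_features()`), exactly summing
to 1. The Cox stages operate on a generic feature matrix so callers choose
the row unit; two conventions matter:

- **Feature scaling.** The default is z-score standardization of each HPC
  proportion (fitted on the training rows and stored inside the signature,
  so scoring is reproducible); per-unit-proportion hazard ratios would be
  astronomically scaled otherwise, and published per-HPC hazard ratios in
  the 0.7–1.3 range are only plausible on a standardized scale. A
  raw-proportion (`"identity"`) mode is available, and the bundled
  published signature uses it since its original scale is not stated.
- **Row unit.** Slide-level rows repeat a patient's outcome and slightly
  understate Cox standard errors; patient-level rows (slide-mean features)
  are independent. The package's calibration tests use patient-level rows;
  the slide-level design remains available and is what slide scoring uses.

The univariate screen fits one proportional-hazards model per feature and
selects p < 0.05 (Wald); constant features are skipped with a warning. The
multivariate stage jointly fits all selected features (exact collinearity
is rejected up front via a rank check), retains terms with multivariate
p < 0.05, and their fitted log-hazard ratios are the signature
coefficients. Both thresholds default to 0.05, the conventional screen
level consistent with every retained term's reported significance.

**Threshold selection.** "5-year ROC" under censoring is implemented as
the cumulative/dynamic time-dependent ROC with inverse probability of
censoring weights: cases are subjects with an observed event by the
horizon, weighted 1/Ĝ(T−); controls are subjects still at risk past the
horizon, weighted 1/Ĝ(horizon); Ĝ is the Kaplan–Meier estimate of the
censoring distribution. Candidate thresholds are the observed scores under
the rule *high iff score > threshold*; the returned threshold maximizes
Youden's J, with exact ties resolved to the lower threshold (labelling
more slides high-risk — the conservative direction for a screening tool).
With zero censoring all weights are 1 and the procedure reduces exactly to
the plain binary-label Youden cutoff, which the acceptance suite verifies
against an independent oracle. Whether the original cutoff was
Youden-based is not stated; Youden is the standard optimality criterion
for a single-threshold ROC rule and is used here.

**Stratification.** Slide labels use the strict boundary (score equal to
the threshold is low risk, as the printed rule classifies only scores
*above* the threshold as high risk). Patient voting is exact: unanimity
gives the shared label, any conflict gives intermediate — so an
intermediate patient label can only arise from conflicting slides, never
from a single slide. Patients whose slides were all filtered out at the
coverage stage simply have no score rows and surface as unassessable
rather than being silently dropped.

**Evaluation.** Kaplan–Meier curves and log-rank tests come from the
`survival` package; the adjusted Cox model encodes the printed contrasts —
risk with low as reference (intermediate and high indicators), sex male vs
female, age > 60 vs ≤ 60, smoking yes vs no, stage III–IV vs I–II — with
Efron tie handling (the source is silent; Efron is the better
approximation and R's default).

## 6. The synthetic cohort generator

`gen_tile()` renders a texture class as dark elliptical "nuclei" blobs of
a characteristic hue on a white background with Gaussian pixel noise. The
default five-class panel spaces hues ≥ 0.13 apart so the ± 0.05 HSV
augmentation jitter cannot move one class onto another, and blob density
is set so tissue coverage is ≈ 0.75–0.8 — representative of tiles that
survive the 60% filter. A plain nearest-centroid color classifier
separates the default classes essentially perfectly (≥ 95% is asserted in
the tests), which is by construction: the fixture validates the clustering
machinery, not the difficulty of histology.

`gen_cohort()` generates: 1–4 slides per patient (mirroring 1–4 cores per
case), per-slide class-proportion vectors from a symmetric Dirichlet
(α = 2 per class, giving realistically variable compositions), tile-class
assignments by multinomial sampling (50 tiles/slide), clinical covariates,
and survival from an exponential proportional-hazards model — the simplest
PH-consistent choice — with linear predictor β·(patient slide-mean
proportions, centered at the uniform composition) plus covariate effects
(log-HRs: sex 0.2, age > 60 0.4, smoking 0.3, stage III–IV 0.7). Baseline
hazard log(2)/4 puts median survival at 4 years, matching the median
follow-up of the cohorts the structure mimics. Censoring is independent
uniform on [0, u], with u calibrated by root-finding so the expected
censoring fraction equals the requested rate (default 0.35, i.e. ≈ 65%
death events).

The default effect vector is β = (8, −8, 0, 0, 0) on proportions. The
patient-level feature (slide-mean of Dirichlet(2) proportions) has a
standard deviation near 0.07 after averaging 1–4 slides, so this realizes
≈ ± 0.5 log-hazard per feature SD — one hazardous and one protective
class, as in the published two-term signature — and a predicted high- vs
low-risk hazard ratio around 3–4.5, inside the range the validation
cohorts report. Note the deliberate attenuation chain: the hazard is
driven by *true* compositions, while the pipeline sees 50-tile multinomial
estimates of them, so fitted coefficients are expected to sit slightly
below the generating values; the recovery tests therefore compare against
a correctly specified joint fit (features plus covariates) on the true
compositions, and the end-to-end tests work with the noisy features.

What the generator does **not** emulate: real nuclear morphology, stain
variation and batch effects, spatial correlation of phenotypes within a
slide, inter-slide correlation beyond the shared patient composition,
non-proportional hazards, and informative censoring. Passing tests
therefore demonstrate the correctness of the machinery under a known
generating model — not performance on real H&E cohorts.

## 7. Numerical choices and degenerate inputs

- Pixel arrays are numeric in [0, 1] throughout; 0–255 inputs are detected
  and rescaled on entry. Cluster ids are 0-based everywhere
  (`hpc_0 … hpc_{M-1}`).
- Batch standardization uses biased variance with ε = 1e-8; the diagonal
  of a self-correlation is then 1 up to O(ε).
- Soft-label rows must sum to 1 within 1e-6 or the cluster loss refuses
  the input; softmax output satisfies this by construction.
- Argmax ties in cluster assignment resolve to the lowest index;
  assignment is per-tile with no batch coupling at inference.
- Zero-norm rows/columns in the NT-Xent stacks are guarded (treated as
  zero vectors rather than dividing by zero).
- Constant features are skipped in the screen; exact collinearity aborts
  the multivariate fit with a clear error rather than a silent singular
  fit.
- Sub-seeds for view pairs and fixtures are derived with a fixed integer
  recurrence and stay below 2^31; all library code restores the caller's
  RNG state.

## 8. Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions: the clustering
recovery fixture uses 2,000 tiles (400 per class, rendered at 224 then
pooled to 32), trained for 12 epochs at batch 128 for each of three seeds,
with adjusted Rand index ≥ 0.8 required in at least two; screen
calibration uses 200 replicate null cohorts of 300 patients; end-to-end
recovery uses one 300-patient cohort with an 80/20 patient split. The full
suite runs in roughly 7–8 minutes on one CPU.

## 9. Known limitations

- The published-scale ResNet50 profile is a configuration contract only;
  training it requires an external pretrained encoder stack that is
  neither bundled nor emulated, and the desk-scale encoder makes no claim
  to its representational power on real tissue.
- Proprietary whole-slide formats, TMA de-arraying, stain normalization
  and magnification resampling are out of scope; inputs are plain PNG/TIFF
  at a fixed nominal magnification.
- The slide-level risk rule is a hard threshold; patients with slides
  straddling it land in a (sometimes large) intermediate group, a known
  rigidity of clear-cut slide voting.
- Univariate screening on slide-level rows treats repeated patient
  outcomes as independent; use patient-level rows where calibrated error
  rates matter.
- The published signature's feature scale is ambiguous in its source; it
  is bundled verbatim with identity scaling, so its absolute scores are
  comparable only within a consistently processed cohort.
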
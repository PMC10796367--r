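# pathoclust

Unsupervised pathomics for H&E-stained tissue images in R: contrastive
clustering of image tiles into histomorphological phenotype clusters (HPCs),
per-slide HPC-proportion features, Cox-derived linear risk signatures, and
three-tier patient risk stratification with survival evaluation.

The package is aimed at computational-pathology researchers who want a
self-contained, CPU-friendly implementation of the
tile → cluster → proportion → signature → risk-group pipeline used in
histopathology prognosis studies (the bundled published signature targets
small cell lung cancer), together with a synthetic texture-and-survival
cohort generator so every stage can be exercised and validated without
access to clinical slides.

## The method

**Preprocessing.** Slide or core images are cut into non-overlapping
224 × 224 tiles on a regular grid. Each tile's grayscale (BT.601 luminance)
histogram is Otsu-thresholded; pixels darker than the threshold count as
tissue, and tiles with tissue coverage ≥ 60% are retained. Six seeded
augmentation operators (flip, rotation, contrast, scaling, HSV jitter,
noise) generate view pairs.

**Contrastive clustering (DL-CC).** A shared-weight twin encoder maps the
two augmented views of each tile to representations z_a, z_b ∈ R^d. Three
losses are optimized jointly:

- *Representation (redundancy-reduction) loss.* With batch-standardized
  columns, the cross-correlation matrix is c = (1/N) BN(z_a)^T BN(z_b), and

      L_rep = Σ_i (c_ii − 1)² + λ Σ_{i<j} c_ij²

  pulling each feature's cross-view correlation to 1 while decorrelating
  distinct features. (A literal 1/d scaling mode is also available.)
- *Instance-level NT-Xent.* A projection head maps z to h; over the 2N
  L2-normalized projections, each sample's sole positive is its counterpart
  view, with cosine similarity / τ as logits:
  L_inst = (1/2N) Σ_i (φ_i^a + φ_i^b).
- *Cluster-level NT-Xent with entropy.* A second head produces soft labels
  y ∈ R^M (softmax rows). Treating each cluster's N-vector of assignment
  probabilities as a unit, the same contrastive form runs over the 2M
  columns, minus the entropy H(Y) of the mean assignment probabilities
  (anti-collapse): L_clu = (1/2M) Σ_i (ψ_i^a + ψ_i^b) − H(Y).

The total objective is
`Loss = (L_inst + L_clu)·(1 − α) + L_rep·α`. The published-scale profile
(ResNet50 backbone, d = 2048, M = 50) is kept as the default configuration
contract; the trainable desk-scale profile (`dlcc_desk_config()`: pooled
pixel features + two-layer perceptron encoder, d = 64, M = 5) trains in
minutes on one CPU with exact manual backpropagation (verified against
finite differences in the test suite).

**Pathomics signature.** Tiles are assigned to clusters by the soft-label
argmax; a slide's feature vector is its HPC proportion profile. A
univariate Cox screen (p < 0.05) followed by a multivariate Cox fit yields
a linear signature `score = Σ_k β_k · feature[hpc_k]`. The slide-level
cutoff is chosen by 5-year time-dependent ROC analysis (cumulative/dynamic,
IPCW-weighted under censoring) maximizing Youden's J; slides above the
threshold are high risk. Patients are labelled by voting: all slides high →
high, all low → low, conflicting → intermediate. Risk groups are evaluated
with Kaplan–Meier curves, log-rank tests and covariate-adjusted Cox models
(sex, age > 60, smoking, stage III–IV; Efron ties).

The published two-term SCLC signature
`PathoSig = 0.2398·HPC39 − 0.3393·HPC19` ships as
`published_signature()`.

## Worked example

A fully synthetic end-to-end run (no images needed for the survival half —
tile-class assignments come from the generator's ground truth):

```r
library(pathoclust)

co   <- gen_cohort(sim_cohort_spec(n_patients = 300, seed = 42))
clin <- co$clinical
sp   <- split_patients(clin$patient_id, ratio = 0.8, seed = 1)

X  <- feature_matrix(co$assignments, M = 5)              # slide-level HPC proportions
Xp <- apply(X, 2, function(col) tapply(col, co$slides$patient_id, mean))
Xp <- Xp[clin$patient_id, ]                              # patient-level features
tr <- clin$patient_id %in% sp$train

scr <- univariate_screen(Xp[tr, ], clin$os_time[tr], clin$os_event[tr])
fit <- multivariate_fit(Xp[tr, ], clin$os_time[tr], clin$os_event[tr],
                        scr$selected, scaling = scr$scaling)
fit$signature
#> Pathomics signature: (+0.4709 * hpc_0) + (-0.4403 * hpc_1)
#>   scaling: zscore  threshold: NA
```

The screen finds exactly the two truly prognostic classes (hpc_0 hazardous,
HR 1.75 per SD; hpc_1 protective, HR 0.59 per SD) and drops the three null
classes. Scoring slides, fitting the cutoff on the held-out patients and
voting:

```r
scores <- data.frame(slide_id = rownames(X), patient_id = co$slides$patient_id,
                     score = signature_score(X, fit$signature))
te  <- scores$patient_id %in% sp$test
ord <- match(scores$patient_id, clin$patient_id)
thr <- optimal_cutoff(scores$score[te], clin$os_time[ord][te],
                      clin$os_event[ord][te])          # 5-year IPCW ROC
risk <- stratify_patients(scores, as.numeric(thr))
table(risk$risk)
#> high intermediate          low
#>   57          164           79

ev <- evaluate_risk_groups(merge(risk, clin, by = "patient_id"), outcome = "os")
ev$logrank$p                 #> 4.84e-11
ev$adjusted
#>               term       hr        lo       hi            p
#> 1 riskintermediate 2.077052 1.4227469 3.032264 1.528256e-04
#> 2         riskhigh 4.528944 2.9088435 7.051372 2.279807e-11
#> 3          sexmale 1.042184 0.7660526 1.417849 7.924878e-01
#> 4           age>60 1.520948 1.1387904 2.031350 4.507608e-03
#> 5       smokingyes 1.278674 0.9414414 1.736705 1.155639e-01
#> 6      stageIII-IV 1.896900 1.4196728 2.534548 1.491095e-05
```

Predicted high-risk patients carry a 4.5-fold adjusted hazard relative to
low-risk patients, with the intermediate group in between — the generated
effect (one hazardous and one protective texture class) is recovered through
the full pipeline. For the imaging half, `gen_texture_dataset()` +
`dlcc_train()` + `assign_clusters()` recover the five texture classes with
adjusted Rand index ≥ 0.8 (usually ≈ 1.0) in minutes; see the methods
vignette.

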
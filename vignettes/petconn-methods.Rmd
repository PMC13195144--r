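---
title: "Methods: individualized whole-body PET connectomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized whole-body PET connectomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters, what the synthetic
phantom does and does not emulate, the numerical choices, and the design
decisions taken where the method description left the design open.

## 1. The model

A subject's PET scan is reduced to a labeled voxel point cloud: world-space
positions (mm), voxel-wise standardized uptake values (SUV, dimensionless),
and fine anatomical labels from an automated segmenter, grouped into 13
meta-organ ROIs (`roi_schema()`).

**Per-organ compression.** Each organ's cloud (possibly millions of
voxels) is reduced to at most `target = 3500` weighted points. Voxels are
embedded in a joint feature space — positions scaled by
`lambda / bounding-box diagonal`, SUV scaled by a robust spread estimate
(MAD, falling back to IQR/1.349, then SD) — and the currently closest pair
is merged into a weight-summed, weighted-centroid point until the target
size is reached. This conserves total mass exactly and the weighted mean
SUV to machine precision, and it preserves heavy SUV tails far better
than random decimation (tested: 99.5th percentile within 5%, weighted
energy distance to the source below 1% of the SUV standard deviation at
50,000 → 3,500). `lambda` (default 1) balances spatial against intensity
influence; `lambda = 0` makes compression purely distributional.

**Pairwise organ distance.** The energy distance
\(\mathcal{E}(P,Q) = 2E|X-Y| - E|X-X'| - E|Y-Y'|\) between two weighted
SUV samples, computed through the one-dimensional identity
\(\mathcal{E} = 2\int (F_P-F_Q)^2\,dt\) on the pooled sorted sample
(O(n log n); the O(n²) double loop is kept as a test oracle). It is zero
iff the weighted empirical distributions coincide, scales linearly under
affine maps, and is dominated by location/scale differences rather than
tail noise — the property that motivates it for PET.

**Mutual-information correction.** \(D^*_{ij} = D_{ij}(1-\alpha\,
\mathrm{MI}_{ij})\): organ pairs with statistically dependent uptake
fields are pulled closer, encoding the classical assumption that
correlated organs are physiologically linked. \(\alpha \in [0,1)\)
controls the strength; \(\alpha = 0\) disables the correction, making the
connectome a pure function of the marginal distributions (tested by
pairing-shuffle invariance).

**Similarity and ROI reduction.** \(C_{ij} = \exp(-D^*_{ij})\) maps
distances into (0, 1] with fast decay, after which the organ-level graph
is reduced to 13 ROIs by averaging all cross-ROI organ-pair similarities
(within-ROI pairs contribute only to the unit diagonal).

## 2. Residual networks

For each of the 78 ROI edges, a Gaussian-kernel KDE \(\hat f_l\) is fitted
to the control cohort's edge values; a subject's edge value \(c\) receives
the signed extremeness score
\[ r_l(c) = \mathrm{sign}(m_l - c)\,\bigl(1 - p^\kappa\bigr), \]
with \(m_l\) the control mean and \(p\) the extremeness probability.
\(\kappa \in (0,1]\) (default in analyses: 0.25) relatively emphasizes very
rare values; no arbitrary residual threshold is applied.

Two deliberate choices:

* **Two-sided extremeness.** The literal one-sided CDF would assign
  near-zero scores to high-side outliers, contradicting the stated
  semantics of "how extreme". Default:
  \(p = 2\min(\hat F_l(c), 1-\hat F_l(c))\), clipped to [0, 1]; the
  one-sided literal form is available via `two_sided = FALSE`.
* **Leave-one-out control scoring.** Scoring a control against a KDE that
  includes it underestimates its extremeness; at desk-scale cohort sizes
  (10 fitting controls) this optimism is large enough to make the
  control-vs-held-out Welch test reject for the wrong reason. In
  three-group analyses, fitting controls are scored leave-one-out
  (`control_residuals_loo()`), making their residuals exchangeable with
  held-out controls; patients and held-out controls are scored against the
  full fitted model.

Note an arithmetic subtlety: \(p^\kappa\) decreases in \(\kappa\) on
\(p\in(0,1)\), so smaller \(\kappa\) *shrinks* every \(|r|\) while
*increasing* the ratio of rare-value to typical-value scores. The package
tests assert the ratio property (the substantive claim) and the correct
elementwise direction.

KDE bandwidth: Silverman's rule \(1.06\,\hat\sigma\,n^{-1/5}\) with
\(\hat\sigma = \min(\mathrm{sd}, \mathrm{IQR}/1.34)\), floored at 1e-6
(degenerate edges warn).

## 3. Classification

**GCN.** Two graph-convolution layers (16 and 32 channels, tanh, L2
penalty) on \(\hat A = \tilde D^{-1/2}(A+I)\tilde D^{-1/2}\), dropout 0.4
after the second layer, global mean pooling, a 32-unit tanh perceptron and
a sigmoid output; fixed-epoch full-batch Adam on binary cross-entropy
(the two-class case of categorical cross-entropy), no validation split.
Evaluation: stratified 3-fold cross-validation repeated 9 times (27
splits); edge importance by ablation (zero one symmetric edge pair,
record the absolute change in predicted probability; absent edges score
0), averaged over test subjects per split and aggregated with
test-accuracy weights.

Two implementation decisions matter enough to spell out:

* **Node features are the identity matrix** — one-hot node indicators,
  identical for every graph and carrying no subject information, the
  standard "featureless" mode of the GCN literature. The alternative
  reading (a constant all-ones feature) makes the mean-pooled
  representation of dense similarity graphs provably uninformative: the
  degree normalization cancels edge-weight scale, row sums of
  \(\hat A\) are ≈ 1, and a linear probe on the pooled features of any
  random initialization classifies at exactly the base rate — training
  then collapses to the constant-output solution from any hyperparameters
  we tried. With identity features the first layer sees \(\hat A\) itself
  and the model recovers the seeded disease effect reliably. Permutation
  invariance is preserved by canonicalizing named adjacencies to sorted
  node order before inference (and is tested).
* **Initialization gains and epochs.** \(\hat A\) entries are O(1/n), so
  plain Glorot initialization leaves activations (and therefore the
  class-relevant signal) tiny, and the optimizer settles into the
  constant-output plateau. The two graph layers are initialized with
  Glorot gains 5 and 2 (restoring O(1) pre-activation spread) and the
  default epoch budget is 600; learning rate 0.01, L2 5e-4 and dropout
  0.4 are kept at their conventional values. All of these are `gcn_config()`
  fields, logged with every result.

**Logistic baseline.** Ridge or lasso logistic regression (glmnet) on the
standardized 78-edge vector, cross-validated under the same 27-split plan
(balanced accuracy = mean of per-class recalls), with an optional
label-permutation p-value. The stability-weighted lasso scales each
edge's L1 penalty by \(1/\max(\bar\rho_l, 0.1)\), where \(\bar\rho_l\) is
the edge's mean Spearman stability from the robustness module — unstable
edges are penalized more. Inner lambda selection uses stratified 3-fold
`cv.glmnet`; cohorts too small for nested selection (fewer than 4 of a
class in training) fall back to a fixed mild penalty (s = 0.05).

## 4. Robustness to segmentation noise

Boundary voxels are those whose spatial k-nearest neighborhood (k = 15,
Euclidean, ties at the k-th neighbor broken by voxel index) contains a
foreign label. Each boundary voxel independently, with probability B
(0.5 "moderate", 0.75 "severe"), receives a label drawn uniformly from
its foreign neighbor labels. Decisions use the *original* label field —
a single pass, no cascading — so the perturbation is order-independent,
and positions/SUVs are untouched (the multiset of (position, SUV) pairs
is conserved exactly). The full pipeline is re-run per subject;
stability is the Spearman correlation of upper-triangle adjacencies
(per subject), and per-edge stability is the across-subject Spearman per
replicate, averaged over replicates (default 5 replicates; the
single-replicate design is a config choice away).

## 5. The synthetic phantom: what it does and does not establish

No clinical data are distributed with the study this package
re-implements, so the phantom is the package's test bed. It generates:

* 17 axis-aligned organ boxes on a 4 mm lattice covering all 13 ROIs, in
  a crude body plan; the left/right heart boxes share the
  interventricular face so boundary noise can leak uptake between them.
* Per-organ lognormal SUV distributions with organ-typical medians
  (brain ≈ 6, left ventricle ≈ 3.2, kidney ≈ 2.8, liver ≈ 2.4 … fat
  ≈ 0.35) and shape parameters 0.25–0.40 — heavy-tailed and
  organ-separable. These are generator defaults, not claims about any
  clinical dataset.
* Per-subject variability: multiplicative lognormal jitter on each
  organ's location (sd 0.15) and scale (sd 0.10) parameters.
* Disease effects: multiplicative location shift and scale inflation on
  designated organs (reference experiment: Heart Right, shift 1.5,
  inflation 1.5 — chosen once as a realistic right-heart hypermetabolism
  analogue); optional latent coupling, implemented as a shared smooth
  random function of the normalized cranio-caudal coordinate (4 Fourier
  modes) added to both coupled organs' log-SUV fields. A per-subject
  scalar factor cannot induce *within-subject* positional dependence —
  and hence no mutual information — which is why the field-valued
  coupling replaces it.

The phantom reproduces the statistical structure the pipeline assumes
(heavy tails, organ separation, inter-subject variability, touching
interfaces, localized disease effects) but not anatomy, scanner physics,
partial-volume blur or reconstruction artifacts. A green parameter-
recovery test therefore establishes that the pipeline detects the kind of
localized distributional shift it was designed for at realistic
signal-to-noise — not that it reproduces any clinical effect size.

## 6. Numerical choices

* Mutual information estimator: both organs are resampled at 1,024
  matched quantiles of their weighted axial CDF (a subject-internal
  spatial correspondence that assumes neither equal voxel counts nor
  shared absolute coordinates), rank-transformed, binned into a 16×16
  equal-mass histogram; plug-in MI with Miller–Madow bias correction,
  normalized by the smaller marginal entropy and clamped to [0, 1]. The
  estimator is invariant to strictly monotone marginal transforms;
  calibration (≤ 0.05 on independent pairs, ≥ 0.9 on comonotone pairs at
  n = 3,500) is part of the acceptance suite. Fewer than 32 points per
  organ is an error.
* \(\alpha = 1\) (used by the group-average analyses) is accepted only
  with MI clipped to \(1 - 10^{-6}\) so that corrected distances stay
  positive; `allow_alpha_one = FALSE` enforces the strict \([0,1)\)
  domain.
* Compression determinism: merge ties are broken by lowest point index;
  candidate neighbors for merged centroids come from a static k-d tree
  over the original points mapped through union-find, with a brute-force
  refill if the candidate queue empties. The output is a deterministic
  function of the input.
* Degenerate inputs: zero-variance control edges floor the KDE bandwidth
  at 1e-6 (warning); organs missing from a subject are dropped with a
  warning rather than zero-filled; per-subject pipeline failures in
  robustness re-runs are recorded and skipped, never fatal to the cohort.
* Seeds: every stochastic stage takes an explicit seed; the pipeline
  derives per-subject/per-stage child seeds from the master seed with a
  counter scheme (no hidden global RNG coupling), and generators
  save/restore the caller's RNG state.

## 7. Known limitations

* The per-edge stability reading of the noise analysis (Spearman across
  subjects per edge, then averaged over replicates) is one of several
  defensible readings of an ambiguous description; it is the one that
  yields a well-defined correlation at n ≥ 3 subjects.
* At \(\kappa = 0.25\) the residuals of strongly affected edges saturate
  near 1, so the *ordering* among the top contrast edges is noise-driven
  even when the affected block is unambiguous. The acceptance suite
  shows this concretely: under boundary noise at B = 0.5 the contrast
  argmax remains a Heart-Right edge in 10/10 seeds (block persistence),
  but the specific winning edge is preserved in only 7/10 — the strict
  edge-identity check is deliberately kept, and fails, at its stated
  threshold.
* The featureless GCN ties its first-layer weights to the node count, so
  a trained model applies only to graphs over the same 13-ROI set (the
  intended use).
* NIfTI support covers the common single-file subset (uint8/int16/int32/
  float32/float64, scl slope/intercept, sform affine); qform quaternions
  are not interpreted. Point-cloud interchange is CSV + JSON manifest;
  no Parquet.
* The energy distance operates on scalar SUV samples; spatial information
  enters only through compression and the MI pairing, not the distance
  itself.
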
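# petconn — individualized whole-body PET connectomics

`petconn` builds **subject-level organ-interaction networks** from a single
whole-body FDG-PET scan. Conventional PET connectomics infers inter-organ
"metabolic crosstalk" from correlations of mean SUV across a cohort, so an
individual's network is always entangled with cohort composition. `petconn`
instead treats each organ as a *distribution* of voxel-wise standardized
uptake values (SUV) and scores every organ pair of one subject by a
distance between those distributions — no other subject is needed to build
a connectome.

It is aimed at researchers in quantitative PET imaging who want
per-patient network phenotypes of systemic disease (the motivating case is
pulmonary arterial hypertension, whose right-heart signature the synthetic
benchmark reproduces), and at methodologists who need a fully testable,
self-contained implementation of the pipeline.

## The model

For organs *i, j* of one subject with SUV distributions *P*, *Q*:

- **Energy distance**
  `E(P,Q) = 2 E|X−Y| − E|X−X′| − E|Y−Y′|`,
  estimated as the weighted V-statistic on compressed samples (for scalar
  samples this equals `2 ∫ (F_P − F_Q)² dt`, computed in O(n log n)).
- **Mutual-information correction**
  `D*_ij = D_ij (1 − α MI_ij)`, `α ∈ [0,1)` (α = 1 allowed with MI clipped
  below 1), where `MI_ij` is a normalized mutual information between the
  two organs' SUV fields paired along the cranio-caudal axis — dependent
  organs are pulled closer.
- **Exponential similarity** `C_ij = exp(−D*_ij)`, giving a fully
  connected weighted graph on 13 anatomical meta-organs (ROI reduction by
  averaging organ-pair similarities).

Downstream analyses: kernel-density **residual networks**
`r_l = sign(m_l − c) (1 − p^κ)` (how unlikely each edge is under a control
cohort, `κ ∈ (0,1]` emphasizing rare values), Welch tests on the sum of
absolute residuals, a featureless **graph convolutional classifier** with
edge-ablation saliency, a regularized **logistic baseline**, and a
**segmentation-noise stress test** (stochastic label swapping of boundary
voxels at blur ratio *B*, stability measured by Spearman correlation of
adjacencies).

Because the original clinical cohort is not public, the package ships a
seeded **synthetic phantom** (lattice organs, lognormal SUV, per-subject
jitter, configurable disease effects and latent couplings) so every stage
is testable offline.

## Worked example

```r
library(petconn)

coh   <- generate_cohort(cohort_spec(n_controls = 20, n_patients = 10, seed = 1))
conns <- lapply(coh$subjects, \(s) reduce_to_roi(build_connectome(s, alpha = 1)))
conns[[1]]
#> <connectome> roi level | subject: ctrl_01 | nodes: 13 | alpha: 1
round(conns[[1]]$C[c("Heart Right","Heart Left","Liver","Brain"),
                   c("Heart Right","Heart Left","Liver","Brain")], 3)
#>             Heart Right Heart Left Liver Brain
#> Heart Right       1.000      0.274 0.133 0.000
#> Heart Left        0.274      1.000 0.727 0.035
#> Liver             0.133      0.727 1.000 0.005
#> Brain             0.000      0.035 0.005 1.000
```

Similar uptake distributions (left heart / liver) give strong edges;
brain uptake is far from everything, so its edges are near 0.

```r
ctrl  <- which(coh$groups == "control"); pat <- which(coh$groups == "patient")
model <- fit_control_model(conns[ctrl])
residual_network(conns[[pat[1]]], model, kappa = 0.25)
#> <residual_network> subject: pat_21 | kappa: 0.25 | sum |r|: 21.085
```

A patient's connectome is far less likely under the control model than a
control's (sum of |r| over the 78 edges). The group contrast and the
GCN's accuracy-weighted ablation saliency both point at the right heart,
the seeded disease site:

```r
ctr <- group_residual_contrast(
  lapply(conns[pat], residual_network, model = model, kappa = 0.25),
  control_residuals_loo(conns[ctrl], kappa = 0.25))
#> top edges: Kidney|Heart Right (0.771), Appendicular Skeleton|Heart Right
#> (0.484), Axial Skeleton|Heart Right (0.419)

cv <- cross_validate(conns, coh$groups == "patient",
                     cv_plan(seed = 11), gcn_config(seed = 11))
cv
#> <cv_result> 27 splits | accuracy: 0.964 +/- 0.061
aggregate_saliency(cv$saliency, cv$accuracy)
#> top edges: Heart Right|Spleen (0.070), Heart Right|Kidney (0.066),
#> Appendicular Skeleton|Heart Right (0.064)
```

Robustness to segmentation noise:

```r
pert <- rerun_pipeline(coh$subjects, perturbation_config(blur_ratio = 0.5, seed = 9))
mean(mapply(subject_stability, conns, pert$connectomes))  # Spearman rho ~ 0.97
```

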
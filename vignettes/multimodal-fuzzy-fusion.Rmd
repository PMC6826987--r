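---
title: "Hybrid fuzzy-possibilistic segmentation and multimodal fusion: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid fuzzy-possibilistic segmentation and multimodal fusion: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyfuse)
```

# The problem

Quantifying cerebrospinal fluid (CSF), grey matter (GM) and white matter
(WM) volumes from brain images is complicated by three effects: additive
acquisition noise, smooth spatial intensity inhomogeneity (the "bias
field" left by scanner coils), and the partial-volume effect (PVE) — voxels
at tissue interfaces contain a mixture of tissues and show intermediate
intensities. When both an anatomical volume (T1-like, high spatial detail)
and a co-registered functional volume (FDG-PET-like, metabolic contrast) are
available, their per-tissue evidence can be *fused*, and the resulting
tissue fractions turned into volumes, labels and a synthesis image whose
subject-level summaries feed a one-class classifier separating a target
population from outliers.

`fuzzyfuse` implements that chain end to end: clustering kernels
(FCM, PCM, FPCM, BCFCM, PFCM), a genetic-algorithm (GA) refinement of the
initial partition, possibility-theoretic fusion operators, the decision
stage, a support vector data description (SVDD) classifier with
divide-and-conquer training, overlap/classification metrics, and a phantom
generator providing ground truth for every stage.

# Models

## Clustering kernels

All kernels act on voxel intensity vectors $x_j$ and alternate closed-form
block updates of an objective; every trace the package returns is
non-increasing, and iteration stops when $|J^{(k+1)} - J^{(k)}| < \varepsilon$
(default $\varepsilon = 0.005$, cap 200 iterations).

**FCM.** Memberships $u_{ij} \propto d_{ij}^{-2/(m-1)}$ sum to 1 over
clusters per voxel; centroids are $u^m$-weighted means. The fuzzifier
defaults to $m = 2$, the conventional choice. A voxel exactly on a centroid
receives full membership there (split equally over coincident centroids).

**BCFCM.** Adds (i) a per-voxel additive bias estimate $\beta_j$
compensating smooth inhomogeneity, and (ii) a neighbourhood term weighted by
$\alpha$ (default 0.7, 3×3 window in 2D, 3×3×3 in 3D) that averages the same
distance over each voxel's neighbours, steering the solution towards
piecewise-homogeneous labelings. Each voxel carries exactly $N_R$ neighbour
slots; off-grid offsets are reflected and off-mask neighbours fall back to
the voxel itself, which keeps the closed-form centroid update exact at the
borders. The bias update is the exact minimiser of the objective for its
block, *including* the terms where a voxel appears as its neighbours'
neighbour — the commonly quoted simpler form ignores those cross terms and
is recovered exactly at $\alpha = 0$.

A design point discovered during development deserves emphasis: an
**unconstrained per-voxel bias field is degenerate**. Iterated to
convergence it absorbs genuine tissue contrast and collapses the centroids
(a perfect fit sets $\beta_j = x_j - b_{\text{nearest}}$). The package
therefore models the field on a low-order polynomial basis in the voxel
coordinates and updates its coefficients by exact weighted least squares —
still the exact block minimiser over the constrained class, so monotonicity
is untouched. The default degree is 1 (a plane): on phantoms whose tissue
layout is itself smooth and radial, any quadratic term ($x^2 + y^2$) is
confounded with true structure, while a plane cannot be. Raise
`bias_degree` (2–3) for data whose tissue geometry is spatially rough
relative to the inhomogeneity — the identifiable regime, as a test on a
striped fixture demonstrates (field correlation with truth > 0.98). The
free per-voxel update remains available as `bias_model = "voxel"` for
diagnostic use.

**PFCM.** Produces relative memberships $u$ (as FCM), absolute
typicalities $t_{ij} = (1 + (b\,d_{ij}^2/\gamma_i)^{1/(\eta-1)})^{-1}$, and
centroids weighted by $a\,u^m + b\,t^\eta$. Typicalities discount atypical
voxels in the centroid update, which is where the robustness to noise and
PVE comes from. Defaults: trade-offs $a = b = 1$ (the balanced choice, both
exposed), possibilistic exponent $\eta = 4$ (midpoint of the sensible 3–5
band; below 3 typicalities become needle-sharp, above 5 nearly flat), and
per-cluster penalties $\gamma_i$ estimated from the initialising partition
as the fuzzily weighted within-cluster spread (multiplier $K = 1$). PCM and
FPCM are provided as baselines for the benchmark grid; PCM estimates each
cluster independently and can produce coincident centroids (reported as a
warning), FPCM normalises typicalities over observations.

## GA refinement

Repeated BCFCM runs from distinct seeds form a population of centroid-set
chromosomes (default $\Omega = 10$). Evolution runs 20 generations of
fitness-proportional selection on $1/(1+w)$, one-point crossover at centre
boundaries ($P_c = 0.8$), per-gene Gaussian mutation ($P_m = 0.01$, s.d. 5%
of the feature range) and elitism of one. The merit function assigns each
voxel to its nearest candidate centre and sums weighted squared distances to
the *gravity centres* of the induced clusters. Because chromosomes inducing
the same assignment therefore share a fitness value, the returned winner is
polished to the gravity centres of its own assignment — a single Lloyd step
that provably never increases the merit and removes the selection-blind
drift mutation would otherwise leave in the winning centres.

## Modeling stage and tissue identity

Per modality: normalize to $[0,1]$ (min–max on the foreground mask) → BCFCM
population → GA → PFCM initialised with the winner's centres and induced
partition. By default the stage refits BCFCM from the GA centroids and hands
PFCM the bias-compensated intensities $x - \beta$ (`bias_correct = TRUE`);
with the planar field this is a no-op on bias-free input and is the step
that makes the chain robust to inhomogeneity. The PFCM typicality matrix,
reshaped per tissue, becomes the possibility maps $\pi_T(v) \in [0,1]$ used
downstream ($u$ is retained for inspection — fusion combines *possibilistic*
distributions, and typicality is the absolute degree suited to that role).

Cluster indices carry no anatomy, so converged centroids are sorted by
intensity and matched to a per-modality tissue order: anatomical images
rank CSF < GM < WM (T1-like), functional images CSF < WM < GM (FDG-like,
GM brightest). Both orders are configuration fields.

## Fusion

For each tissue the two modality maps are combined voxel-wise by one of four
operators driven by the global agreement
$h = 1 - \operatorname{mean}_v|\pi_1(v) - \pi_2(v)|$, computed per tissue
over the foreground mask. At $h = 1$ all four reduce to the conjunctive
T-norm $\min(\pi_1, \pi_2)$; as agreement drops, the $1-h$ branches make the
combination cautious. The default is the fourth operator
$\max(\min(\pi_1,\pi_2)/h,\ \min(\max(\pi_1,\pi_2), 1-h))$, which behaves
conjunctively between reliable sources and falls back to the more confident
source under conflict. $h$ is floored at $10^{-6}$ before division (at such
low agreement the cautious branch dominates anyway), and outputs are clamped
to $[0,1]$ because the renormalised T-norm can exceed 1 as written. The CSF
fused map is always the anatomical CSF map: functional images carry no
reliable CSF signal.

## Decision

Labels follow the maximum-possibility rule with exact ties broken by the
fixed priority CSF, GM, WM (tie counts are recorded); voxels whose
possibilities are all zero are background. Partial-volume fractions
normalise the fused possibilities per voxel, so they sum to 1 on foreground
and preserve the argmax. The synthesis image mixes per-tissue mean
functional activity (functional PFCM centroids) with the fractions,
$v = \sum_T b_T\,p_T(v)$ — anatomical geometry carrying functional
intensity levels. Volumes are reported both hard (label counts × voxel
volume) and soft (integrated fractions), the soft ones summing to the
foreground volume by construction.

## SVDD classification

The classifier encloses the target class in a minimum-volume kernel
hypersphere. The dual — maximise
$\sum_i \alpha_i K_{ii} - \sum_{ij}\alpha_i\alpha_j K_{ij}$ subject to
$\sum\alpha_i = 1$, $0 \le \alpha_i \le C$ — is solved by a deterministic
SMO-style pairwise coordinate ascent (most-violating pair, exact line
search, KKT tolerance $10^{-6}$). The RBF kernel is
$K(x,y)=\exp(-\|x-y\|^2/\sigma^2)$; a width of 0 selects the linear kernel.
$R^2$ is the mean squared centre distance of the unbounded support vectors;
points with $\alpha_i = C$ may lie outside, and since $\sum\alpha = 1$ at
most $1/C$ of them can. Acceptance uses $\|z-a\|^2 \le R^2$ with a
$\mathrm{tol}\,(1+R^2)$ numerical slack; the signed score
$\|z-a\|^2 - R^2$ serves as the continuous ROC statistic — the hard
decision alone cannot produce a curve.

Hyper-parameters $(\sigma, C)$ are chosen by exhaustive grid search under
k-fold one-class cross-validation (held-out target accept rate, plus
outlier reject rate when outliers are supplied; ties towards smaller $C$
then smaller $\sigma$). Divide-and-conquer training partitions the target
set with seeded multi-start k-means, trains a local expert per cluster, and
retrains on the union of local support vectors; a subproblem whose size
makes $C$ infeasible uses $\max(C, 1/n_c)$ locally, and the final retrain
reuses the original $C$. The model records the work estimate
$kN + k(N/k)^3 + (\bar\alpha k)^3$ against the plain $N^3$.

## Evaluation

Tanimoto coefficient $v_{ART}/(v_{AT}+v_{RT}-v_{ART})$ and Jaccard
similarity for segmentation overlap (the same formula on single-tissue
masks — a property the tests assert); sensitivity, specificity and accuracy
with zero-denominator cases reported as missing rather than zero; ROC by
threshold sweep with trapezoid AUC, which equals the pairwise concordance
statistic with ties counted ½; EER by linear interpolation of the
$FPR = FNR$ crossing. The cross-validation harness implements the described
protocol — 10 independent *stratified random 70/30 partitions* — rather than
disjoint folds (offered as an option), and summarises each metric with
mean, s.d., the five-number statistics and mild/extreme outlier counts at
1.5·IQR / 3·IQR.

# The phantom: what it emulates, and what it does not

The generator builds nested tissue regions — a CSF core, a GM ring, a WM
exterior inside a circular (or spherical) brain mask, radii at 15/30/45% of
the smallest grid dimension — with linear partial-volume mixing across a
band of `pv_width` voxels (default 2), an additive bias field (a smooth
off-centre Gaussian bump rescaled so its maximum magnitude is
`bias_amplitude` × dynamic range, default 20%, mirroring a 20% intensity
non-uniformity), and additive white Gaussian noise with standard deviation
`snr_noise` × dynamic range (the package's reading of "x% noise", applied
consistently everywhere). Anatomical means default to CSF 0.15 / GM 0.50 /
WM 0.85, functional means to CSF 0.05 / GM 0.85 / WM 0.45 — bright-GM,
mid-WM, dark-CSF, the FDG pattern.

What passing tests on this phantom do *not* show: real cortical geometry
(the phantom's structure is smooth and radial, which is the *hard* case for
bias-field identifiability — see the BCFCM discussion), MR physics (no
Rician magnitude statistics, no slice-thickness effects), PET kinetics, or
registration error (modalities are generated perfectly aligned). Results on
real acquisitions depend on preprocessing quality (skull stripping,
registration, residual inhomogeneity) that is outside this package's scope.

# Study conditions used by the tests and the acceptance script

Problem sizes were chosen so the full suite runs in well under a minute of
compute per check: objective monotonicity on 16–20² phantoms over 20
seeds × 3 specs; parameter recovery on a 64² phantom in the noiseless
pure-tissue limit (noise 0, bias 0, `pv_width` 0 — with mixing on, voxel
population means differ from the pure tissue means *by construction*, so
"recover the true means" is only well-posed in the pure limit; robustness
to PVE and noise is what the monotonicity and noise-ordering checks cover);
noise robustness on 32² phantoms at 20% noise and default 20% bias over 10
seeds, each image hybrid-median filtered before segmentation for every
scheme — the stated preprocessing order (noise injection, then filter). In
that protocol the hybrid BCFCM/GA/PFCM chain reaches a mean Tanimoto
overlap of ~0.64–0.67 against ~0.53–0.57 for plain FCM; the margin comes
jointly from the bias compensation and the possibilistic modeling, and
shrinks to nothing if the bias field and filter are removed — pure
voxel-independent Gaussian noise affects all intensity-only clusterers
almost equally.

The acceptance script's synthetic cohort consists of 30 subjects (24²
phantom pairs, 5% noise): 18 controls with the default functional means and
12 subjects emulating the disease pattern — reduced GM functional activity
(0.85 → 0.55, hypometabolism) and a widened partial-volume band (2 → 3
voxels, interface blurring). Each subject is segmented end-to-end; features
are the three soft volume fractions plus the three per-tissue mean
synthesis intensities, standardised. SVDD is trained on controls only, with
$(\sigma, C)$ grid-searched inside each training split, and evaluated by
the 10 × 70/30 protocol.

# Numerical conventions collected

- Distances are squared Euclidean throughout.
- Zero-distance membership: full membership on the touched centroid, split
  equally over coincident ones.
- Degenerate $\gamma$ estimates (vanishing cluster spread) are floored at
  $10^{-12}$ with a warning.
- Convergence is $|\Delta J| < \varepsilon$ with a 200-iteration safety cap.
- Image borders: reflection for both the hybrid median filter and the
  BCFCM neighbourhood; 3D volumes are filtered slice-wise along the last
  axis with a 3×3 window (no window size is canonical; 3×3 is the smallest
  that preserves edges and corners).
- NIfTI artifacts are written uncompressed, making CLI runs byte-identical
  under a fixed master seed.

# Known limitations

- BCFCM bias estimation assumes the inhomogeneity is smoother than the
  tissue structure; when both are smooth the field is not identifiable and
  the planar default deliberately under-fits rather than absorbing
  contrast.
- PFCM's per-cluster $\gamma_i$ skew the typicality decision boundaries
  away from the centroid midpoints when cluster spreads differ; on
  low-contrast data this costs a little boundary accuracy relative to
  membership-based labeling.
- The GA operates on 1-D intensity centroids by default; multi-feature
  voxels are accepted by the kernels but the pipeline wires scalar
  intensities.
- The SVDD solver materialises the full kernel matrix; divide-and-conquer
  is the intended route beyond a few thousand target points.
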
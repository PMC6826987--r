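# fuzzyfuse

Tissue quantification from paired anatomical/functional brain images with a
hybrid fuzzy–genetic–possibilistic segmentation chain, possibility-theoretic
multimodal fusion, and one-class SVDD classification — plus a synthetic
phantom generator so every stage is testable with known ground truth.

**Who it is for:** researchers quantifying CSF / grey-matter / white-matter
volumes from co-registered image pairs (e.g. T1 MRI + FDG-PET) who need
segmentation robust to noise, smooth intensity inhomogeneity and
partial-volume mixing, and who want a subject-level one-class classifier on
top of the segmentation output.

## The method

Per modality, the **modeling** stage computes per-tissue possibility maps:

1. **BCFCM** — bias-corrected fuzzy c-means. Minimises
   `J = Σ u_ij^m ‖x_j − β_j − b_i‖² + (α/N_R) Σ u_ij^m Σ_{k∈N(j)} ‖x_k − β_k − b_i‖²`,
   a fuzzy clustering of bias-compensated intensities with a neighbourhood
   regulariser; the smooth additive field `β` is estimated on a low-order
   polynomial basis by exact weighted least squares.
2. **GA** — a genetic algorithm (population 10, 20 generations, crossover
   0.8, mutation 0.01) refines the BCFCM centroid sets under the merit
   `w = Σ_l Σ_{x∈C_l} p_i d²(x_i, g_l)` (dispersion about the gravity
   centres of the nearest-centre assignment).
3. **PFCM** — possibilistic fuzzy c-means initialised by the GA winner,
   producing memberships `u`, typicalities
   `t_ij = (1 + (b d²/γ_i)^{1/(η−1)})^{-1}` and centroids; the typicality
   matrix becomes the possibility maps `π_T(v) ∈ [0,1]`.

**Fusion** combines the two modalities per tissue with context-dependent
operators driven by the agreement `h = 1 − mean|π₁ − π₂|` (default
`FOP4 = max(min(π₁,π₂)/h, min(max(π₁,π₂), 1−h))`); CSF always passes through
from the anatomical modality. **Decision** yields the maximum-possibility
label map, normalised partial-volume fractions `p_T = π_T / Σ π`, hard and
soft tissue volumes, and the synthesis image `v = Σ_T b_T p_T(v)` mixing
functional activity into anatomical geometry.

**Classification** encloses target subjects in a minimum-volume kernel
hypersphere (SVDD): maximise `Σ α_i K_ii − Σ α_i α_j K_ij` subject to
`Σα = 1, 0 ≤ α ≤ C`, solved by a deterministic SMO-style ascent, with
`(σ, C)` grid search and k-means divide-and-conquer training for large
target sets. Evaluation provides Tanimoto/Jaccard overlap, SE/SP/CA,
ROC/AUC/EER, and a stratified 10 × 70/30 cross-validation harness.

## Worked example

```r
library(fuzzyfuse)

# a 48x48 multimodal phantom: 5% noise, 20% bias field, 2-voxel PV band
ph  <- generate_phantom(phantom_spec(shape = c(48, 48), snr_noise = 0.05, seed = 11))
res <- run_full(ph$anat, ph$func, pipeline_config(seed = 42))

res$volumes
#>   tissue n_voxels hard_volume soft_volume
#> 1    csf      180         180    375.7311
#> 2     gm      471         471    480.0378
#> 3     wm      817         817    612.2312

round(res$fused$h, 3)
#>   csf    gm    wm
#> 0.801 0.894 0.874

sapply(1:3, function(ti) tanimoto(res$labels, ph$truth_labels, ti))
#> 0.911 0.949 0.989
```

`res$volumes` reports per-tissue voxel counts and volumes in mm³ — hard
(label counts) and soft (integrated partial-volume fractions; note the soft
CSF volume is about double the hard one because boundary voxels carry CSF
fractions without winning the argmax). `res$fused$h` is the inter-modality
agreement per tissue (1 = identical evidence), and the Tanimoto
coefficients compare the fused label map with the phantom's ground truth
(1 = perfect overlap).

The one-class classifier:

```r
m <- svdd_train(matrix(rnorm(80), 40, 2), svdd_config(C = 0.2, sigma = 2))
m
#> <svdd_model> rbf kernel (sigma = 2), C = 0.2, 8/40 SVs, R^2 = 0.6655
svdd_predict(m, c(0, 0))   # accept
svdd_predict(m, c(9, 9))   # reject
```

A thin command-line wrapper over the same functions ships in
`inst/cli/fuzzyfuse.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fuzzyfuse.R", package="fuzzyfuse"))')" \
  phantom --shape 64,64 --noise 0.1 --seed 1 --out ph/
```

with subcommands `phantom | preprocess | segment | fuse | decide | run |
classify | evaluate | benchmark`, all NIfTI/CSV/JSON in and out and fully
reproducible under `--seed`.

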
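---
title: "Multimodal connectopic gradient mapping: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal connectopic gradient mapping: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Connectopic gradient mapping asks how a brain structure is organized when
its subdivisions are continuous rather than discrete. For a voxel domain
such as the pulvinar, each voxel carries a feature profile — its functional
connectivity to a set of cortical parcels, its streamline (tract-density)
counts to the same parcels, or its receptor/transporter density across a
panel of PET tracers. Voxels whose profiles change smoothly along one or
more spatial axes define *gradients*: low-dimensional embedding coordinates
in which the anatomy's connectional or molecular organization becomes
explicit. `pulvigrad` implements the full analysis chain for three
modalities, together with the statistics needed to compare gradients
without being fooled by spatial autocorrelation, and the reliability
analyses needed to trust them.

## The embedding model

Each modality yields a voxel-by-feature matrix. The functional route
applies three stages before embedding: negative correlations are zeroed
and each voxel row is thresholded at its 90th percentile
(`sparsify()`, retaining the top 10% of connections), values are Fisher
r-to-z transformed (`fisher_z()`), and subject matrices are averaged into a
group connectome (`group_average()`). Structural tract-density matrices are
only group-averaged — counts are neither thresholded nor Fisher-
transformed. Receptor maps are z-scored per tracer over the analysis mask
(`zscore_columns()`).

The feature matrix is converted to a voxel-by-voxel affinity,
`1 - cosine distance` between feature rows (`cosine_affinity()`). Cosine
similarity can be negative for z-scored receptor features; negative
affinities are rectified to 0 because the diffusion operator requires a
nonnegative kernel. This rectification is a genuine modelling choice (the
alternative, shifting the kernel, distorts all pairwise relations) and is
exposed through `rectify = FALSE` for sensitivity analysis.

`diffusion_embedding()` implements the anisotropic diffusion map. With
degrees $q_i = \sum_j A_{ij}$ and anisotropy exponent $\alpha$, the kernel
is renormalized as $\tilde A_{ij} = A_{ij}/(q_i^\alpha q_j^\alpha)$, the
row-stochastic Markov operator $M = D^{-1}\tilde A$ is formed, and its
spectrum is computed through the symmetric conjugate
$S = D^{-1/2}\tilde A D^{-1/2}$, which keeps the eigenproblem symmetric and
numerically stable. The trivial constant eigenvector ($\lambda_0 = 1$) is
dropped. With `diffusion_time = 0` (the default, following the multiscale
convention of the reference diffusion-map implementations) component $k$ is
scaled by $\lambda_k/(1-\lambda_k)$; positive `diffusion_time` $t$ scales
by $\lambda_k^t$. The default $\alpha = 0.5$ balances geometry against
sampling density and is the standard choice in gradient mapping; $\alpha$
is a parameter of every embedding function.

Two conventions are deliberately pinned by tests rather than left to the
solver:

* **Explained variance** is $\lambda_i / \sum_{j \ge 1, \lambda_j > 0}
  \lambda_j$, the retained eigenvalue over the sum of *all* positive
  non-trivial eigenvalues of the full spectrum. Retained fractions
  therefore sum to at most 1.
* **Sign**: each component is flipped so its first non-negligible loading
  is positive, making embeddings reproducible before any cross-set
  alignment. `align_signs()` then aligns target components to a reference
  by correlation sign, and `procrustes_align()` resolves full rotational
  indeterminacy with the least-squares orthogonal transform (no scaling).

**Choosing the number of gradients.** `elbow_select()` automates the scree
inspection: on the *cumulative* explained-variance curve it returns the
index with maximum distance to the chord joining the first and last
points. The cumulative form is used because the raw scree's chord distance
is dominated by the first drop and systematically selects one component
too few on plateau-then-cliff profiles; the cumulative rule reproduces the
intended reading of the scree in the cases we pin in tests, e.g.
`(0.50, 0.15, 0.14, 0.01) -> 3` and `(0.90, 0.05, 0.05) -> 1`. An exactly
linear cumulative curve is degenerate and returns 1 with a warning.

## Gradient-weighted cortical projection

`gradient_weighted_map()` projects a voxel gradient back onto the cortex:
parcel $p$ receives $\frac{1}{V}\sum_v g(v)\,F(v,p)$, the average dot
product of gradient values with voxel-to-parcel connectivity. By default
the *raw* (un-thresholded, pre-Fisher) group connectome is weighted: the
dot product of a gradient with actual correlation values has a direct
interpretation, whereas thresholded z-values re-weight parcels through the
sparsity pattern. The processed matrix can be supplied instead — the
function is agnostic to stage. Hemispheric maps are combined by
`hemiflip_average()`, either plainly or through a mirror correspondence so
ipsilateral structural connectivity accumulates on one side.

## Spatial-autocorrelation-corrected statistics

Brain maps are spatially smooth, so correlations between independent
smooth maps are far from zero and naive permutation tests reject wildly.
`generate_surrogates()` builds variogram-matched nulls: each surrogate is
a random permutation of the map, kernel-smoothed over the `knn = 100`
nearest neighbours at each of 8 log-spaced candidate bandwidths; the
affine recombination of smoothed map and white noise whose variogram best
matches the target variogram (nonnegative least squares over 25
equal-width distance bins up to 50% of the maximum distance) is kept, and
with `resample = TRUE` the original values are rank-mapped onto it so
every order statistic is preserved exactly. None of the binning or kernel
hyperparameters are critical; all are arguments. `sa_permutation_pvalue()`
compares an observed correlation to the surrogate null two-sided on $|r|$
(gradient signs are indeterminate) with the add-one estimator, so $p \ge
1/(n_{\rm surrogates}+1)$ and is never zero. The package default is 1000
surrogates. `bh_fdr()` applies Benjamini–Hochberg step-up control across a
family of tests.

The key property, asserted in the acceptance suite, is *calibration*: for
independent pairs of fields with matched correlation length, the SA test
rejects at the nominal rate while the naive permutation test's rejection
rate is inflated several-fold.

## Gradient-space clustering

To ask whether continuous gradients conceal discrete compartments, the
selected components are min-max normalized to $[0,1]$ and concatenated
(`minmax_concat()`, optionally across modalities), swept with k-means for
$k = 2..30$ (Euclidean, best of `n_init = 10` starts per $k$), and scored
by mean silhouette on all points (`kmeans_sweep()`); `select_k()` takes the
maximum-silhouette solution, breaking ties toward the smallest $k$.
`dice_overlap()` quantifies correspondence with atlas nuclei as
$2|A\cap B|/(|A|+|B|)$ per cluster–nucleus pair, summarized per nucleus by
the maximum across clusters. On planted blob data the pipeline recovers
the true $k$ and labels; on planted *continuous* gradients the maximum
Dice against contiguous nuclei-like slices stays visibly lower — the
qualitative signature distinguishing genuine compartments from
discretized continua.

## Reliability

`split_half_stability()` repeatedly splits the cohort into disjoint,
exhaustive halves (odd cohorts drop one subject per split, with a
warning), embeds each half's group connectome, Procrustes-aligns the
second to the first and records per-gradient $|r|$; the median and IQR
(Results-style) and the mean (Methods-style) are both reported.
`test_retest()` does the same for two sessions. `snr_gradient_association()`
correlates each gradient with a voxel-wise SNR map (`snr_map()`,
mean/standard-deviation along the series axis, undefined voxels flagged
and excluded pairwise) with SA-corrected p-values, flagging gradients that
might be noise artefacts. The sample standard deviation ($n-1$) is used
everywhere a standard deviation appears.

## What the synthetic data emulate — and what they do not

The generators plant every structure the pipeline is supposed to find:

* `make_voxel_domain()`: a bilateral ellipsoidal blob with contiguous
  nucleus labels, mirrored by negating x across the mid-sagittal plane.
* `plant_cortical_connectivity()`: a symmetric parcel connectome
  $C=\sum_j w_j g_j g_j^\top$ + noise, with smooth orthonormal gradients
  $g_j$ (low-order polynomials of centroid coordinates, Gram–Schmidt
  orthonormalized — analytically controllable smoothness).
* `plant_pulvinar_connectivity()`: voxel profiles that mix the cortical
  gradients with monotone spatial scores along chosen axes, with
  geometrically decreasing per-axis amplitude (ratio 0.6) so the spectrum
  orders the axes; `snr` is sd(signal)/sd(noise).
* `make_timeseries()`: latent-factor series whose voxel-parcel sample
  correlations converge to a feasible target; `make_structural_counts()`:
  negative-binomial counts (tractography streamline counts are
  overdispersed); `make_receptor_maps()`: tracer maps loading on the
  planted axes; `make_sa_field()`: Gaussian random fields with
  squared-exponential covariance and known correlation length.

These fixtures have realistic *structure* but not realistic *physics*: no
haemodynamics, no diffusion signal model, no registration error, no
anatomy beyond a labelled blob, and Gaussian noise throughout. Passing the
recovery tests therefore shows the pipeline is a faithful estimator of the
structures it models, not that those structures exhaust real data.

One scale choice deserves note: the recovery analyses embed the synthetic
group connectome directly (raw route). Row-wise sparsification exists to
suppress the noisy tail of *subject-level empirical correlations*; applied
to an already-clean low-rank connectome with few parcels it discards
signal instead, which is visible as degraded recovery of the second
planted axis. Both routes are available everywhere
(`embed_config(sparsify = )`), and the subject-level pipeline in
`run_pipeline()` uses the full functional route.

## Problem sizes and numerical choices

The test and validation suites run at deliberately small scale, chosen as
the smallest sizes at which every planted structure is comfortably
recoverable: ~300-voxel domains, 60–100 parcels, cohorts of 8 subjects,
500-point fields with 99–1000 surrogates, and 20-seed clustering sweeps.
Full-scale runs (400 parcels, 1000 surrogates, $k$ up to 30, 100
split-half iterations) use the same code paths and are the package
defaults in `pipeline_config()`.

Degenerate inputs are errors, not silent repairs: disconnected affinity
graphs (listing component sizes), constant maps, zero-variance tracers
(named), empty masks. The two exceptions are Fisher z at $|r| \ge 1$,
clamped to $1 - 10^{-7}$ with a warning (it occurs only on noise-free
synthetic data), and empty variogram bins, merged with a warning.

## Known limitations

* Group-level embeddings only; no individual-level gradient fitting.
* Dense eigendecomposition: domains beyond ~10k voxels would need sparse
  or randomized solvers.
* No surface-based (spin-test) nulls; the surrogate machinery is
  volumetric/point-cloud based.
* The rectification of negative cosine affinities and the
  explained-variance normalization are conventions; both are configurable
  or test-pinned, and results near those choices should be checked when
  comparing against other toolboxes.
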
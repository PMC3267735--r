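---
title: "Voxel-level connectome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level connectome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voxgraph)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the choices we made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis model

The unit of analysis is a region of interest (ROI) of a few hundred voxels
on a 3 mm lattice — the scale of a single cortical area such as primary
motor cortex — with one BOLD time series per voxel (175 volumes at
TR = 1.8 s in the reference design, i.e. about five and a half minutes of
rest after discarding two equilibration volumes).

**Preprocessing.** Each voxel series is residualized against nine nuisance
signals plus an intercept (six rigid-body motion parameters, mean white
matter, mean CSF, and the global signal), prewhitened with a per-voxel
AR(1) (Yule–Walker) fit, and band-pass filtered to 0.01–0.09 Hz with a
zero-phase (forward–backward) 4th-order Butterworth filter. Sessions whose
motion traces exceed 1 mm or 1° rms are flagged by `motion_qc()`. The
order regression → prewhitening → band-pass is the default; it is recorded
in the output's provenance and is configurable, because reordering
regression and filtering genuinely changes the result and the literature is
not unanimous. The AR order (default 1) is likewise configurable.

**Graph construction.** The synchronization matrix `M` holds all-pairs
zero-lag Pearson correlations. An undirected simple graph has an edge
exactly when `M_ij > T` — a strict inequality, and only positive
correlations can form edges (the threshold grid lives entirely above
zero; absolute-value thresholding is deliberately not offered).
`scan_tmax()` raises `T` from 0.1 in steps of 0.002 until the largest
connected component first covers less than 95 % of nodes; `T_max` is the
last passing grid value. The comparison is `>=` 0.95 (the criterion is
stated both as "more than" and "at least" in the source literature; we use
`>=` and record the mode). The scan is implemented as a single
incremental union-find pass over the sorted edge list, which is exactly
equivalent to evaluating every grid point separately (edge sets are nested
in `T`) and is what makes scanning hundreds of datasets cheap. Group maps
are built at one common threshold: the minimum `T_max` over all datasets,
so every dataset keeps ≥ 95 % of its voxels in one component.

**Metrics and nulls.** Nodal degree `K_i`, Watts–Strogatz local clustering
`C_i = (edges among neighbours) / (k_i (k_i-1)/2)` (defined as 0 for
degree < 2 so maps are complete), and nodal path length `L_i` (mean BFS
distance to all other nodes of the largest component) are computed through
igraph; the test suite verifies them against independent brute-force
oracles (adjacency row sums, triangle enumeration, Floyd–Warshall) with
exact equality on hundreds of random graphs. Global `C` and `L` are the
unweighted means of the nodal values (mean-of-nodal was chosen over the
triangle-density ratio for consistency with the nodal maps). Null values
come either from the closed forms `C_rand = K/N`, `L_rand = ln N / ln K`
or, preferably, from an ensemble of Maslov–Sneppen double-edge-swap
rewirings (default 1000 replicates, 10·|E| attempted swaps each) that
preserve each node's degree exactly; fragmented replicates are analysed on
their largest component, mirroring the treatment of the empirical graphs
(a rejection-sampling flag is available). Nodal normalization divides by
the ensemble *scalars*, not per-node nulls.

**Maps and hubs.** The three nodal maps are normalized as `K_i / max(K_i)`
(per dataset, so maps are comparable across subjects), `C_i / C_rand`, and
`L_rand / L_i` — the inversion makes better-integrated voxels take larger
values. Smoothing is mask-restricted Gaussian with 6 mm FWHM on the voxel
lattice (surface-based smoothing is out of scope); the kernel is
renormalized to a doubly stochastic matrix (symmetric Sinkhorn scaling), so
smoothing leaves constant maps and the in-mask mean exactly unchanged.
Voxels outside the largest component are missing and stay missing. Hubs
are the top 15 % of the across-subject average baseline `L_rand/L_i` map
(ceiling count, ties included, realized fraction recorded).

**Group statistics.** Global metrics are compared before/after by paired
t-tests. Nodal maps enter a two-way repeated-measures ANOVA
(stimulation × time, subject as block); the interaction F has
`(2, 2(n-1))` degrees of freedom in the full three-session design.
Post-hoc paired t maps follow — by default only when the interaction
yields a corrected cluster (a gatekeeping flag). Cluster correction is by
permutation of the maximum cluster extent: supra-threshold voxels at an
uncorrected forming p are grouped under 26-connectivity (configurable to
6/18) and compared with the max-size null from sign-flipping of
per-subject difference maps (paired t) or within-subject session-label
permutation (interaction F); corrected
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, with exact enumeration available
for sign-flipping with few subjects. Cluster sizes are reported in voxels
and mm³ (extent, not mass). Finally, `baseline_dependence()` regresses the
per-subject cluster-mean change on the cluster-mean baseline by OLS.

## 2. The synthetic BOLD generator

The generator exists so that every stage above can be validated against
known ground truth. Its default parameters are the reference study
conditions: 14 subjects × 3 sessions (anodal / cathodal / sham) × 2 times
(before / after) = 84 datasets; 175 volumes at TR 1.8 s; ROIs of a few
hundred voxels on a 3 mm lattice; signals band-limited to 0.01–0.09 Hz.

**Signal model.** Each session draws `n_latents` (default 40) latent
signals, each a sum of 16 sinusoids at uniform random frequencies in
0.01–0.09 Hz with random phases, anchored at voxels spread over the ROI.
The latent basis is orthonormalized within the session, so the field's
correlation structure is determined by the spatial mixing weights
(exponential decay, length scale 2 voxels) rather than by finite-sample
overlap of sinusoids. This is a deliberate design: with 175 volumes and an
0.08 Hz band the in-band signal space has only ~50 effective dimensions,
and un-orthogonalized latents produce session-to-session swings of the
whole correlation distribution far larger than the test–retest variability
of real resting data. The latent count is kept below the band dimension
for the same reason. On top of the field sit AR(1) voxel noise (φ = 0.3 —
giving the prewhitening stage something real to remove), a smooth
per-session gain field (log-sd 0.3 by default) standing in for
scan-to-scan SNR variation from repositioning and coil sensitivity, and
nine nuisance components that are both mixed into the data and returned as
the regressor set; the global signal is built from the actual common mode
of the generated data plus extra-ROI background, so that global-signal
regression removes what it removes in real pipelines. Motion traces are
smoothed random walks scaled to ~0.25 rms by default, with a `qc_fail`
switch for testing the exclusion rule.

**Architecture.** Two stable architectural elements can be added as extra
weight columns: a dominant *hub* region (default 30 voxels, off-centre
along the ROI's long axis) and per-subject baseline coupling of the
central target region. The hub matters statistically: the `K/max`
normalization divides every voxel by the map's peak degree, and if the
peak sits inside a region being perturbed, any effect leaks into all
voxels of the normalized map. A stable hub pins the normalizer — and is
also what the hub analysis of real motor cortex finds.

**Planted effects.** `local_coupling` raises the mean pairwise correlation
of a target region by a calibrated `coupling_delta`: the injected latent is
a mixture of the region's own coherent signal (amplification of existing
shared structure, surround correlations preserved) and a fresh independent
source, in proportion `decoupling`. The mixing weight is solved
numerically from the model covariance, which the generator tracks in
closed form, so the planted increase equals `delta` by construction (the
test suite checks ±0.05 after full preprocessing). The decoupling fraction
is the scientifically interesting dial: at 0 the target gains connections
(degree rises with clustering); at 1 it synchronizes internally while
shedding its surround (degree falls). Intermediate values emulate the
reported phenomenon of a local-connectedness increase *without* a degree
change — the default 0.7 was calibrated once so that the planted cathodal
analogue leaves degree maps statistically silent while the clustering maps
light up. `long_range` applies the same mechanism to the union of the
target and a compact distal partner region, creating supra-threshold
shortcut correlations between the two; the path-length signal concentrates
in the partner region (whose baseline integration is poorest) and the
planted system is scored as target ∪ partners. In study simulations a
biological ceiling caps effects that would push mean correlations past
0.92 (`saturate`), instead of erroring as the low-level API does.

**What the generator does not emulate.** No hemodynamic response or neural
mass dynamics; no scanner artifacts beyond slow drift; motion exists only
as regressor traces, not as image transformations; sessions are
exchangeable apart from seeds and planted effects. Consequently, passing
recovery tests demonstrate that the *pipeline* detects the planted
correlation structure at realistic noise levels — not that real tDCS
effects of this size would be detectable in scanner data.

## 3. Problem sizes used by the tests and the acceptance script

All sizes below are the package's own choices for desk-scale validation;
the pipeline itself runs unchanged at full scale.

* Oracle equivalence: 200 random graphs with N ≤ 30, exact equality.
* Null-model fidelity: 1000 rewires of a connected G(300, K ≈ 12);
  ensemble means within 20 % of `K/N` and `ln N / ln K`.
* Small-world: Watts–Strogatz (N = 100, k = 6, rewiring 0.1) and an
  Erdős–Rényi control, each against 200-replicate rewired ensembles.
* Effect recovery: 20 replicate studies per effect kind, 14 subjects,
  300-voxel ROI, 40-voxel target, δ = 0.15 (local) with 1000-permutation
  cluster correction. The recovery experiments form clusters at
  uncorrected p = 0.01 rather than the pipeline default 0.05: with 6 mm
  smoothing on a desk-scale ROI, a 0.05 forming threshold lets
  smoothing-induced null clusters grow to the size of the 40-voxel target
  and the extent test loses its meaning; p = 0.01 forming is the standard
  modern recommendation for cluster-extent inference and is what the
  reduced-scale dissociation needs. The pipeline default remains 0.05.
* Specificity: 100 sham studies at a 150-voxel ROI, 500 permutations;
  plus 500-draw type-I calibrations of the paired t and the
  baseline-slope test at the metric level.
* Baseline dependence: the recovery of a planted effect–baseline
  correlation of 0.7 is checked at the operation level with
  `simulate_coupled_maps()` (100 replicates), where map noise is small and
  the regression's R² estimates ρ² directly. Pushing the same planted
  coupling through the full BOLD pipeline attenuates the recovered R²
  severely — `baseline_dependence_study()` measures it at roughly 0.05–0.2
  — because the per-dataset `C_rand = K/N` normalization injects
  session-level multiplicative noise (the mean degree of a 175-volume,
  0.01–0.09 Hz dataset has ~5–10 % session-to-session variability) into
  both the baseline and the change scores. This attenuation is a real
  property of single-session voxel-graph metrics and is reported as such
  by the acceptance script rather than hidden by tuning.

## 4. Numerical choices and degenerate inputs

* Thresholding: strict `>`; grid values are computed as `t0 + k·step`
  (never accumulated), so boundary cases like an entry exactly equal to a
  grid value behave predictably.
* Constant voxel series: an error in `correlation_matrix()` (naming the
  voxels); zero residuals plus a warning in `prewhiten()`.
* Rank-deficient nuisance designs: collinear columns are dropped with a
  warning and recorded in provenance.
* Degree-0/1 nodes: clustering 0; path lengths are only defined on the
  largest component, so infinite distances never arise downstream.
* Graphs with no valid degree-preserving swap (e.g. a triangle) are
  returned unchanged with a warning.
* Smoothing uses a symmetric Sinkhorn-scaled kernel (tolerance 1e-13), so
  constants and the in-mask mean are preserved to numerical precision;
  FWHM 0 is the identity.
* All randomness flows from one master seed through a counter-based
  `seed_for()` fan-out; derived seeds stay below 2³¹, and end-to-end runs
  are byte-reproducible.

## 5. Known limitations

* Group analyses assume a shared voxel grid across subjects (the
  generator's deterministic ROI geometries provide this); anatomical
  registration is out of scope.
* Cluster inference is on the volumetric lattice; the surface-based
  variant of the original methodology is not implemented.
* The interaction permutation scheme (within-subject session-label
  permutation under a parametric forming threshold) is one standard
  reading of an under-specified procedure; sign-flipping covers the paired
  contrasts.
* Voxel-graph metrics from single ~6-minute sessions are intrinsically
  noisy; analyses that divide by per-dataset null scalars inherit that
  noise (see the baseline-dependence discussion above).
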
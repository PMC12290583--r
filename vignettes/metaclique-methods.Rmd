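---
title: "From activation coordinates to connectivity cliques: the metaclique methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From activation coordinates to connectivity cliques: the metaclique methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaclique)
```

metaclique implements a complete coordinate-based meta-analysis and
connectivity-profiling chain for functional neuroimaging: activation
likelihood estimation (ALE) with Monte-Carlo family-wise error (FWE)
inference, conjunction and permutation subtraction contrasts between
experiment groups, seed-ROI extraction from meta-analytic peaks,
meta-analytic coactivation modeling (MACM) against a term-annotated
coordinate database, desk-scale seed-based resting-state functional
connectivity (rsFC), multimodal connectivity-profile correlation matrices,
Ward clustering of regions into *cliques*, and term-based functional
decoding. This vignette is the package's own account of the statistics it
computes, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data tests do and do not establish.

## The ALE model

The input is a table of activation *foci*: peak coordinates (mm, MNI or
Talairach space) reported by independent experiments, each with a subject
count. Talairach rows are converted with a vendored Lancaster-style affine
(`tal_to_mni()`; pooled transform by default, SPM/FSL variants and a custom
matrix are accepted, because the source transform literature offers several
fits and published analyses rarely say which was used).

Each experiment's spatial evidence is summarised by a **modeled activation
(MA) map**. A focus is blurred with an isotropic Gaussian kernel whose
full width at half maximum (FWHM) reflects the spatial uncertainty of the
experiment: a fixed between-template component (default 5.7 mm) and a
between-subject component (default 11.6 mm) that shrinks with `sqrt(n)`,
combined in quadrature (`kernel_fwhm_from_n()`). Both constants are data,
not contract, and can be overridden. The kernel is sampled at voxel-centre
distances, scaled by the voxel volume so each value is a probability that
the true activation lies in that voxel, and truncated where it falls below
`1e-8` of its peak. A voxel's MA value is the **maximum** over the
experiment's focus kernels, not their sum — multiple nearby peaks from one
experiment are one piece of evidence, not several.

The **ALE statistic** at a voxel is the probabilistic union across
experiments,

$$\mathrm{ALE} = 1 - \prod_i \bigl(1 - \mathrm{MA}_i\bigr),$$

bounded in [0, 1] and at least the largest single MA value. Foci are
snapped to the nearest voxel centre before kernel placement (the common
volumetric convention; ties at half-voxel positions resolve
deterministically through round-half-even).

### The voxel-level null

Under the null hypothesis of no spatial convergence, each experiment's MA
values are randomly located across the in-brain mask. The null
distribution of the union is computed analytically by discretising each
experiment's in-mask MA histogram and sequentially convolving the
histograms under the union operation (`ale_null()`, bin width `1e-5` by
default). Numerically the convolution is carried out in the log-complement
domain $y = -\log(1 - \mathrm{MA})$, where the union is exact addition, so
the sequential convolution becomes a product of FFTs; the result is
re-binned onto ALE-value bins. p-value lookups are conservative: an
observed value maps to its bin's lower edge, and the lookup bin is lowered
by $k - 1$ further bins for $k$ experiments so that discretisation can
never push a null atom out of the right tail (the sum of $k$ floors
undershoots the floor of the sum by at most $k-1$). The tests verify the
resulting CDF against 200,000-draw Monte-Carlo resampling to within
|Δp| ≤ 0.005.

Two fine-print consequences are worth knowing. First, the conservative
lookup spans $k-1$ bins, so with many experiments and the default bin width
the *bulk* of the p distribution is shifted slightly upward (the far tail,
where thresholding happens, is unaffected in practice — the cluster-level
calibration below uses the default width); for fine-grained p-value work at
large $k$, set `bin_width` nearer `1e-5 / k`. Second, the null model treats
experiments as placing values independently at a voxel, whereas under true
relocation a voxel's position relative to the mask boundary is shared by
all experiments; on desk-scale masks whose radius is only a few kernel
radii this makes marginal p-values mildly super-uniform (~0.01 at the
median on the test fixture). The cluster-extent Monte Carlo absorbs this,
since observed and null maps are thresholded with the same critical value.

### Cluster-extent FWE correction

Voxels are thresholded at `voxel_p < 0.001` (the critical ALE value is
inverted exactly from the null). Family-wise control of cluster extent is
by Monte Carlo (`cluster_extent_threshold()`): in each iteration every
focus is replaced by a uniformly drawn in-mask voxel centre (per-experiment
focus counts and kernel widths preserved), the ALE map is recomputed,
thresholded, and the maximum supra-threshold cluster size under
**26-connectivity** is recorded. Observed clusters survive if they are
strictly *larger* than the 95th percentile (ceiling order statistic) of
these maxima. Because cluster sizes are integers, the attainable
false-positive rate is the largest achievable value at or below 0.05; the
calibration test measures it at roughly 0.03–0.045 on the test fixture.
Full-scale analyses use 10,000 iterations; the tests and the acceptance
script use 500 (the sizes reported throughout this vignette are the
package's chosen desk-scale problem sizes). The analytic voxel null — and
hence the critical ALE value — depends only on the corpus *composition*
(which kernels, how many foci), so it is computed once per composition and
reused across Monte-Carlo iterations and replicate corpora.

### Conjunction and subtraction

The conjunction of two thresholded group maps is the minimum statistic on
the intersection of their supra-threshold sets — the convergence common to
both groups. (The source literature sometimes calls this a "union"; the
implementation is an intersection, which is what "common between both"
means operationally.)

The subtraction contrast (`ale_subtraction()`) compares the *unthresholded*
ALE maps of two groups. The observed statistic is their voxel-wise
difference; the null shuffles experiment labels between groups (sizes
preserved) and recomputes the pseudo-ALE difference. Per-experiment
log-complement MA vectors make each permutation a vector addition, so the
permutations cost far less than rebuilding MA maps. Voxel p-values come
from the permutation distribution of |difference| (floored at
`1/(n_iterations+1)`); FWE control uses the max-|difference| distribution
at 0.05 (a Benjamini–Hochberg FDR alternative is available, since published
descriptions of this step mix the two); surviving voxels must form
clusters of at least 100 contiguous voxels (26-connectivity). The group
pair is canonicalised internally (deterministic key on experiment ids) so
that swapping the two arguments negates the output exactly, permutation for
permutation.

## Seed ROIs

Local maxima of the thresholded ALE map are voxels at least as large as
all 26 neighbours, inside a surviving cluster; an equal-valued connected
plateau contributes its smallest linear index (deterministic tie rule).
Maxima closer than 20 mm are pruned greedily in descending value order —
the strongest evidence wins — and the rule is applied jointly across all
clusters by default (`per_cluster = TRUE` restricts it, since the source
convention is ambiguous). Each surviving peak becomes a 6-mm-radius
spherical seed of in-mask voxel centres. Anatomical labels come from a
user-supplied table of labelled mm boxes (`label_roi()`), a configurable
stand-in for atlas lookup; centres inside no box are `"unlabeled"`.

## MACM and term maps

For each seed, `select_studies()` finds every database study reporting at
least one focus within the seed sphere (closed ball; a voxel-set rule is
available). The coactivation map is the ALE union over the selected
studies using a **fixed 15-mm FWHM kernel** for all studies — at the
database scale subject counts are often missing, so a common width is the
convention. Voxel-level FWE correction at p < 0.001 uses a max-statistic
Monte-Carlo null (uniform relocation of all selected studies' foci;
threshold at the 99.9th percentile of per-iteration maxima). Downstream
profile correlation always uses the *unthresholded* map, so pipelines that
only need the clustering can skip the thresholding iterations entirely
(`iterations = list(macm = 0)`).

Term-association maps for decoding are built as the difference of two
fixed-kernel ALE maps: studies annotated *with* the term minus studies
*without* it (`term_map()`). This is a transparent stand-in for
database-derived term maps; externally computed maps can be supplied to
`decode_terms()` unchanged.

## Desk-scale rsFC

A rest run is a T × V matrix of in-mask voxel series on the session grid.
For a seed ROI, the run-level map regresses each (spatially smoothed,
6-mm FWHM) voxel series on an intercept, the ROI's mean time course, and
the global-signal time course as a nuisance regressor; the map value is the
seed coefficient standardised to correlation scale,
`beta * sd(seed)/sd(voxel)`, so rsFC and MACM maps are comparable inputs to
the profile matrices (raw coefficients are available with
`standardize = FALSE`). Runs combine within subject as a voxel-wise mean
(fixed effects); the group map is the subject mean with a one-sample t
statistic — a deliberate simplification of a full mixed-effects model,
recorded as such. Maximum-height thresholding is by sign-flip permutation
of subject maps at voxel-level p < 0.001 (a parametric t alternative
exists, because the source description conflates parametric random-field
and nonparametric thresholding; neither is asserted as "the" original).
Smoothing is a separable Gaussian with mask renormalisation, implemented as
banded-matrix multiplication over a 4D slab for speed; a constant global
signal is dropped from the design rather than allowed to make it singular.

## Profiles, cliques, decoding

The unthresholded maps of each modality are vectorised over the mask
(V × M) and Pearson-correlated pairwise into an M × M **profile matrix**
(symmetric, unit diagonal, positive semi-definite up to numerical
tolerance). The rsFC and MACM matrices are averaged element-wise into the
multimodal matrix, which provides the final clustering features: ROI *i*'s
feature vector is row *i* of the multimodal matrix, diagonal included.
Columns are standardised to unit variance ("standardised Euclidean";
whether the original standardisation ran across ROIs or within profiles is
not documented anywhere authoritative — columns were chosen and are
recorded here), distances are Euclidean, and linkage is Ward's minimum
variance (`hclust(method = "ward.D2")`).

The number of cliques is selected by mean silhouette width over
`k = 2 … M−1` (Calinski–Harabasz is reported alongside), but the dendrogram
and the full metric table are always exported so a human can inspect and
override (`override_k`) — mirroring the visual-inspection practice this
step automates. Synonym handling in decoding is deliberately config-driven
(explicit synonym groups, keep the highest-r member), never automatic
stemming. A clique's decoding input is the voxel-wise mean of its member
ROIs' unthresholded MACM maps; terms with spatial correlation r > 0.29 are
reported, ranked.

## The synthetic worlds

`synth_world()` fixes the ground truth everything else is tested against:

* **`tiny`** — 3 loci / 3 networks on a 20³ 4-mm grid with a spherical
  mask (3544 voxels); used for unit tests and calibration fixtures.
* **`paper-like`** — 10 loci on a brain-sized 4-mm ellipsoid grid
  (~33,000 voxels), using the printed pooled-ALE peak coordinates of the
  source corpus as the planted loci and their three published cliques
  (language / salience / attention-control) as the networks; 39
  experiments in a 25 + 14 group split; subject counts uniform on 7–61,
  matching the corpus's reported range.

Foci corpora place one Gaussian-scattered focus per locus per experiment
(5-mm sd, truncated to the mask by rejection sampling, at most 1000
attempts) plus 5 uniform noise foci. The coordinate database annotates 75%
of studies with one term each; a term's studies place a fraction (default
0.8) of their foci near the term's network loci; optional null terms are
annotated but spatially flat. Rest runs follow a block-covariance model:
voxel value = `global_amp * g(t) + sqrt(block_rho) * b_k(t) + noise_sd *
e(t)` with unit-variance latents; with the default
`noise_sd = sqrt(1 - block_rho)` the expected within-network correlation is
`block_rho` (0.5 by default, `global_amp` 0.5). Network membership extends
12 mm around each locus; the rest of the mask is background noise. All
generators are pure functions of (world, parameters, seed).

What passing these tests shows: the statistics are computed correctly, the
nulls are calibrated, and planted effects of realistic magnitude are
recovered end to end. What they do not show: robustness to the things the
generators deliberately omit — autocorrelated haemodynamic noise, motion,
anatomically shaped masks and inhomogeneous gray-matter density,
publication bias in which foci get reported, and term annotations derived
from text mining. Conclusions about real data still require the real data.

## A worked pipeline

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  out_dir  = "runs/demo", seed = 101, simulate = "paper-like",
  iterations = list(ale = 100, subtraction = 100, macm = 0, rsfc = 0),
  simulate_args = list(db = list(n_studies = 200, n_null_terms = 1),
                       runs = list(n_subjects = 4, n_runs = 2, n_timepoints = 100)))
run <- run_pipeline(cfg)
run$cliques$metrics      # silhouette / Calinski-Harabasz per k
tidy(run$pooled)         # peak table: cluster, x, y, z, volume_mm3, ale_max
run$decoding             # clique, term, r  (all r > 0.29)
autoplot(run$cliques)    # dendrogram with the cut height
```

Every stage writes its artifacts (NIfTI maps, TSV tables, JSON linkage,
Newick dendrogram) under the run directory along with a checksum manifest
and a threshold-echoing log; re-running the same config and seed reproduces
the checksums. Deleting a stage's outputs and re-running regenerates them
identically, because each stage is a deterministic function of the config,
the inputs, and the master seed (per-stage streams are derived from it).

## Numerical choices and limitations

* Voxel indices are 0-based; world coordinates are mm; mm→voxel uses the
  nearest voxel centre. Boundary foci count as in-mask iff their nearest
  centre is in-mask.
* Default test/acceptance problem sizes: 4-mm grids, 500 extent-MC
  iterations, 100–200 permutations, 10 end-to-end seeds. Full-scale
  defaults (10,000 iterations, 2-mm grids) are configuration away but are
  not what the shipped tests run.
* The analytic null assumes experiments relocate independently and
  uniformly; real gray-matter density is not uniform, and the package does
  not model small-volume correction or effect-size (image-based)
  meta-analysis at all.
* Sample-size→FWHM constants and the Talairach affine are vendored data
  with override hooks, not contractual values.
* `choose_k` automates what is, in practice, a human judgement; the export
  of dendrograms and metrics is deliberate so the override path is a
  first-class outcome, not an afterthought.
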
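# metaclique

Coordinate-based meta-analysis of brain activation and connectivity-profile
clustering, in R.

Functional neuroimaging experiments report their results as peak activation
coordinates ("foci"). metaclique is for researchers who want to ask, across
a corpus of such experiments: *where do studies converge*, *how do the
convergent regions hang together as networks*, and *what mental operations
are those networks associated with* — without leaving R, and with every
stage testable on synthetic data with planted ground truth.

The chain it implements:

1. **ALE meta-analysis.** Each experiment's foci are blurred with a
   Gaussian kernel whose width shrinks with the sample size
   (spatial-uncertainty model); a voxel's modeled activation (MA) is the
   maximum over the experiment's kernels, and the ALE statistic is the
   probabilistic union across experiments,
   `ALE = 1 − Π(1 − MAᵢ)`. Voxel p-values come from an analytic
   histogram-convolution null; cluster-extent family-wise error (FWE)
   correction uses a Monte-Carlo null of randomly relocated foci
   (voxel p < 0.001, cluster FWE 0.05).
2. **Contrasts.** Minimum-statistic conjunction of two thresholded group
   maps; permutation subtraction of unthresholded maps with max-statistic
   FWE and a 100-voxel extent filter.
3. **Seed ROIs.** Local maxima of surviving clusters, pruned to ≥ 20 mm
   separation, become 6-mm spherical seeds.
4. **Connectivity profiles.** Per seed: a meta-analytic coactivation map
   (MACM; fixed 15-mm kernel ALE over all database studies reporting a
   focus in the seed) and a seed-based resting-state connectivity map
   (global-signal regression, 6-mm smoothing, fixed-effects runs,
   group-level t with sign-flip max-height thresholding).
5. **Cliques.** ROI × ROI Pearson matrices of the unthresholded maps per
   modality, averaged into a multimodal matrix; standardised-Euclidean /
   Ward clustering; cluster count by silhouette with dendrogram export and
   a human override.
6. **Decoding.** Each clique's mean coactivation map is correlated with
   term-association maps; terms with spatial r > 0.29 are reported, with
   config-driven synonym de-duplication.

A synthetic-data module (`synth_world()`, `gen_foci_corpus()`,
`gen_coordinate_db()`, `gen_rest_runs()`) generates all inputs with planted
loci, networks, and term signals, so the whole pipeline runs end to end on
a laptop with no downloads.

## A worked example

Simulate a brain-sized world with 10 planted loci in 3 networks (the
coordinates follow a published pooled-ALE peak table), 39 experiments in a
25 + 14 group split, a 200-study annotated coordinate database, and 4
subjects × 2 rest runs — then run the full chain:

```r
library(metaclique)

cfg <- pipeline_config(
  out_dir = "runs/demo", seed = 101, simulate = "paper-like",
  iterations = list(ale = 100, subtraction = 100, macm = 0, rsfc = 0),
  simulate_args = list(db   = list(n_studies = 200, n_null_terms = 1),
                       runs = list(n_subjects = 4, n_runs = 2, n_timepoints = 100)))
run <- run_pipeline(cfg)
run
#> <pipeline_run> runs/demo
#>   39 experiments -> 4 pooled clusters -> 8 ROIs -> k = 3 cliques

run$cliques$metrics
#> # A tibble: 6 × 3
#>       k silhouette calinski_harabasz
#>   <int>      <dbl>             <dbl>
#> 1     2      0.653              10.0
#> 2     3      0.970            2582.
#> 3     4      0.695            2931.
#> 4     5      0.612            2681.
#> ...

run$decoding
#> # A tibble: 3 × 3
#>   clique term          r
#>    <int> <chr>     <dbl>
#> 1      1 term_net2 0.470
#> 2      2 term_net3 0.520
#> 3      3 term_net1 0.483
```

Reading this: the pooled ALE found 4 FWE-surviving clusters whose local
maxima yield 8 seed ROIs (two of the 10 planted loci sit closer than the
20-mm separation rule and merge into their neighbours). The silhouette
profile peaks decisively at k = 3, recovering the three planted networks
(adjusted Rand index 1.0 against ground truth for this seed), and decoding
ranks each network's generating term first for its clique, all above the
r > 0.29 reporting threshold — while the planted null term never passes it.
`tidy(run$pooled)` gives the peak table (`cluster`, `x`, `y`, `z`,
`volume_mm3`, `ale_max`), `autoplot(run$cliques)` the dendrogram, and the
run directory holds every intermediate artifact (NIfTI maps, TSV tables,
Newick dendrogram, checksum manifest, threshold log).

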
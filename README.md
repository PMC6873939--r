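# scDiversity

Diversity profiles and composition comparison for single-cell cluster
occupancy.

## What this is for

When the cells of a sample are assigned to the clusters of a joint
single-cell RNA-seq clustering, the fraction of cells per cluster is a
discrete distribution that captures the sample's internal heterogeneity —
intratumor (or intraleukemic) heterogeneity, when the sample is a tumor.
`scDiversity` scores that distribution with the **Hill number of order q**,
the effective number of clusters

$$
{}^qD = \Big(\sum_{i:\,p_i>0} p_i^{\,q}\Big)^{1/(1-q)},
$$

evaluated across a whole spectrum of orders rather than at a single index.
The familiar indices are special cases: richness at `q = 0`, the
exponential Shannon index as `q → 1`, inverse Simpson at `q = 2`, and
Berger–Parker dominance (`1/max p`) as `q → ∞`. Low orders expose rare
subclones; high orders count dominant ones. The package is for anyone
comparing cluster compositions across samples or conditions: tumor vs
healthy cohorts, sorted vs polyclonal populations, pre- vs post-treatment
timepoints.

Around the profile it provides the companion procedures such an analysis
needs:

* **Composition comparison** — the Kolmogorov–Smirnov distance between
  discrete occupancy distributions over a shared, canonically ordered
  cluster space, pairwise across samples or pooled conditions.
* **Cluster expression network** — per-cluster geometric-mean UMI
  profiles (pseudocount-stabilized), pairwise Euclidean distances, and a
  condition-annotated cluster graph as plain node/edge tables.
* **Downsampling robustness** — repeatedly drop half the cells, recompute
  the profile at the anchor orders `{0.01, 0.1, 1, 2, 10, 100}`, and
  summarize absolute and mean-normalized relative changes.
* **I/O and plumbing** — 10x-style MTX directory reader/writer,
  Loupe-dialect cluster CSV + samples-sheet ingestion keyed on barcode
  aggregation suffixes, a minimal PCA + k-means++ stand-in clusterer, and
  a negative-binomial synthetic cohort generator with analytic ground
  truth.

## Worked example

Simulate a two-condition cohort (two "healthy-like" and two "AML-like"
samples over a shared 16-cluster space), score each condition's profile,
compare compositions, and check stability:

```r
library(scDiversity)

cohort <- combineScenarios(presetScenarios()[["healthy-like"]],
                           presetScenarios()[["aml-like"]],
                           name = "aml-vs-healthy")
sim <- simulateCohort(cohort, seed = 1)
ann <- sim$annotation
ann
#> CellAnnotation: 6000 cells, 4 samples, 2 conditions, 14 clusters

for (cond in conditionLabels(ann)) {
  occ <- occupancy(ann, cond, "condition")
  print(round(dValues(diversitySpectrum(occ, anchorQValues())), 2))
}
#> 0.01  0.1    1    2   10  100
#> 7.93 7.38 4.38 3.37 2.39 2.21
#>  0.01   0.1     1     2    10   100
#> 13.96 13.59 10.76  9.00  6.28  5.46
```

The healthy-like condition occupies 8 clusters with an effective number
falling from ~7.9 (richness-weighted) to ~2.2 (dominance-weighted); the
AML-like condition is more diverse at **every** order — the profile-level
ordering a single index can miss. Their compositions are far apart, while
the two samples within a condition are nearly identical:

```r
round(pairwiseKS(ann, "condition"), 3)
#>              healthy-like aml-like
#> healthy-like        0.000    0.367
#> aml-like            0.367    0.000
```

Removing half the cells 1,000 times barely moves the score — here by at
most ~0.6 effective-cluster units at any anchor order, and least of all at
low orders:

```r
ds <- downsampleSpectrum(ann, label = "aml-like", by = "condition",
                         nReplicates = 1000, seed = 2)
relativeChange(ds)$summary
#>      label     q baseline_d mean_d    sd_d max_abs_change
#> 1 aml-like 1e-02      13.96  13.96 0.00235        0.00852
#> 2 aml-like 1e-01      13.59  13.59 0.02224        0.08027
#> 3 aml-like 1e+00      10.76  10.74 0.13001        0.46850
#> 4 aml-like 2e+00       9.00   8.98 0.16209        0.57725
#> 5 aml-like 1e+01       6.28   6.27 0.19394        0.58647
#> 6 aml-like 1e+02       5.46   5.48 0.20527        0.59494
```

Real data enter through the readers instead of the simulator:
`read10xMtx("filtered_feature_bc_matrix/")` for counts and
`readAnnotations("clusters.csv", "samples.csv")` for Loupe-style cluster
exports plus a `suffix,sample_id,condition` samples sheet.

## Command line

The same pipeline is scriptable via the thin wrapper in
`inst/scripts/scdiversity` (subcommands `simulate`, `diversity`,
`compare`, `network`, `downsample`; all outputs are plain CSV):

```sh
scdiversity simulate --scenario aml-vs-healthy --seed 17 -o cohort/
scdiversity diversity --clusters cohort/clusters.csv \
    --samples cohort/samples.csv --by condition -o spectrum.csv
scdiversity compare --clusters cohort/clusters.csv \
    --samples cohort/samples.csv --by sample -o ks.csv
```

## Further reading

The methods vignette (`vignettes/diversity-profiles.Rmd`) documents the
model and its assumptions, the numerical choices (log-space evaluation,
the `q = 1` branch, large-`q` asymptotics), the KS ordering convention,
what the synthetic generator does and does not emulate, and known
limitations.
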
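# brainglance

Group-level fMRI results are usually reported as a single average map in
template (MNI) space. That average hides the thing many studies actually
care about: how differently individual brains express an effect.
`brainglance` takes the complementary route. Each subject's 3D map — a
GLM contrast, an eigenvector-centrality map, a regional-homogeneity map,
any scalar volume — stays in the subject's own native space. An atlas
warped onto that subject (with nearest-neighbour interpolation, so
labels stay integral) reduces the map to one number per brain area, and
the resulting **region × subject matrix**

> S ∈ ℝ^(M×N), S<sub>ij</sub> = summary statistic (default: mean) of
> subject *j*'s map over atlas area *i*

is drawn as a single grid: every subject a row, every one of the M areas
a column. Columns are grouped by gross anatomical region and ordered
**mirror-symmetrically** — left hemisphere on the left, right on the
right, with the innermost columns of both halves showing the same area —
so bilateral patterns are visible at a glance.

The package is aimed at neuroimaging researchers who want to report
single-subject results for a whole cohort without hand-picking
"representative" subjects. It provides:

- **Atlas handling** — `read_atlas_description()`, `validate_label_volume()`,
  `build_column_layout()` (the mirror ordering).
- **Region summarization** — `extract_region_values()`,
  `build_region_matrix()`, `average_sessions()`; statistics: mean
  (default), min, max, sd, median.
- **Map-level metrics** from 4D NIfTI time series —
  `compute_ecm()` (eigenvector centrality: dominant eigenvector of the
  voxel similarity matrix A = (r + 1)/2, computed matrix-free by power
  iteration), `compute_reho()` (regional homogeneity: Kendall's W over a
  voxel's 7/19/27-neighbourhood), `highpass_filter()` (discrete-cosine
  drift removal, e.g. the conventional 1/100 s cutoff), and
  `smooth_volume()` (Gaussian, FWHM in mm).
- **Subject clustering** — `cluster_subjects()`: affinity propagation on
  negative squared Euclidean distances between subject columns. Each
  subgroup is represented by an actual subject (its exemplar) and the
  number of clusters is not fixed in advance. Cluster rows are drawn
  with height 1 + log10(size).
- **Native-vs-template statistics** — `region_differences()` (native
  minus template) and `ttest_per_region()` (one-sample t per area,
  p = 0.05 uncorrected by default), rendered as a two-panel figure.
- **Synthetic phantoms** — `make_phantom_atlas()`, `make_subject_maps()`,
  `make_synthetic_timeseries()`, `write_demo_dataset()`: everything is
  testable and demonstrable without downloading any imaging data.
- A **CLI** (`inst/cli/brainglance.R`) with subcommands
  `simulate` / `fingerprint` / `metrics` / `cluster` / `compare`.

## Worked example

```r
library(brainglance)

dir  <- file.path(tempdir(), "bg-demo")
recs <- write_demo_dataset(dir, n_subjects = 6, n_gross_regions = 2,
                           areas_per_region = 3, grid_shape = c(20, 20, 20),
                           n_clusters = 2, noise_sd = 0.2, seed = 11)
cfg  <- run_config(attr(recs, "atlas_description"), recs, cluster = TRUE,
                   output_dir = file.path(dir, "results"), seed = 11)
res  <- run_fingerprint(cfg)

res$matrix
#> <region_matrix> 12 regions x 6 subjects, statistic 'mean', 0 missing
glance(res$matrix)
#> # A tibble: 1 × 6
#>   n_regions n_subjects statistic n_missing   min   max
#> 1        12          6 mean              0 -2.00  2.01
res$clusters
#> <brainglance_clusters> 2 cluster(s) over 6 subjects
#>   sizes: 3, 3
#>   exemplars: sub-02, sub-05
```

The demo plants two subject subgroups (subjects were dealt to the
planted groups alternately, so sub-01/03/05 and sub-02/04/06 belong
together); affinity propagation recovers exactly that partition and
names one real subject per group as its exemplar. `res$paths$figure` is
the fingerprint SVG: 6 rows (or 2 log-height cluster bands), 12 columns
split into mirrored L/R halves, orange for positive and blue for
negative values, grey slashed cells for areas missing from a subject's
warped atlas. `autoplot(res$matrix, layout = res$layout)` gives the
same figure as a ggplot.

From a shell:

```sh
Rscript inst/cli/brainglance.R simulate --out demo --subjects 10 --seed 7
Rscript inst/cli/brainglance.R fingerprint --config demo/config.json
```

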
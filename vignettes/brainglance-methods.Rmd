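---
title: "Methods: atlas-based subject fingerprints, their metrics, clustering and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atlas-based subject fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainglance)
```

This vignette records the model choices behind the package: what each
computation assumes, which knobs matter, and where the design was
genuinely open and a convention had to be fixed.

## The region × subject matrix

The core object is the matrix `S` with one row per atlas area (M rows)
and one column per subject (N columns); `S[i, j]` summarizes subject
*j*'s scalar map over area *i*. The premise is that voxel-wise
correspondence across subjects is unreliable — morphology and
functional topography vary too much — while *area-level* correspondence
through a warped atlas is defensible. Everything downstream (display,
clustering, statistics) operates on `S`.

Assumptions worth stating explicitly:

- The subject's map and the subject's warped atlas live on **the same
  voxel grid**. The package never resamples; a grid mismatch is a hard
  error. Warping is upstream work (and must use nearest-neighbour
  interpolation for the atlas so labels stay integral — fractional
  labels are rejected at load time).
- The default summary is the **mean** over the area's voxels. Mean,
  min, max, sd and median are available; which one is scientifically
  right depends on the map (a z-statistic map may warrant max, a
  homogeneity map the mean).
- An area with **zero voxels** in a subject's warped atlas — small
  areas do get swallowed by nearest-neighbour warping — becomes an
  explicit missing value, drawn as a grey slashed cell. Encoding it as
  0 would fabricate a measurement.
- Non-finite voxels inside an area are excluded from the statistic with
  a warning; the treatment of such voxels is a package convention, not
  an established standard.
- Multi-session data are averaged subject-wise *after* region
  extraction (`average_sessions()`), i.e. metrics are computed per run
  and their region summaries averaged, preserving the per-run
  computation order.

## Mirror-symmetric column layout

Columns are grouped by gross anatomical region (FRO, INS, TEM, …) in
**definition-file order of first appearance** — curated anatomical
orderings would be destroyed by alphabetical sorting. The left
hemisphere fills the left half; the right half reverses both the group
order and the within-group order, so the sequence of (gross region,
area) pairs in the right half read outward equals the left half read
inward: the two innermost columns show the same area, left and right.
Formally, stripping hemisphere labels, the column sequence is a
palindrome — a property the tests check on randomized atlases.

Areas with no contralateral partner (possible in asymmetric atlases,
e.g. midline or subcortical subdivisions) cannot participate in the
mirror. They are kept, pushed to the **outer edge** of their
hemisphere's half, and reported with a warning. Dropping them silently
would lose data; failing would make asymmetric atlases unusable. This
placement is a package convention.

## Eigenvector centrality

`compute_ecm()` summarizes a 4D series as the dominant eigenvector of
the voxel-by-voxel similarity matrix

\[ A_{uv} = \tfrac{1}{2}(r_{uv} + 1), \]

with `r` the Pearson correlation between the two voxels' time courses.
The +1/2 shift makes `A` non-negative, so by Perron–Frobenius the
dominant eigenvector is unique and entry-wise non-negative — a
well-defined "hubness" score. The shift (rather than `|r|` or truncating
negatives at 0) was chosen because it preserves the ordering of
correlations and admits an exact matrix-free iteration: with
row-standardized data `Z` (each voxel's centered series scaled to unit
norm), `A x = (Z (Zᵀ x) + sum(x) 1) / 2`, so one iteration costs
O(n·T) and the n × n matrix is never formed. Power iteration starts
from the uniform positive vector (already inside the Perron cone; a
custom start vector is accepted and the result is start-independent to
≤ 1e-8), and stops when the eigenvalue estimate's relative change is
below `tol` (default 1e-12). The returned map has **unit Euclidean
norm** over the mask — any monotone rescaling is display-equivalent,
and unit norm makes variants comparable; no rescaling to mean 1 is
applied. Masked-out voxels are 0; masked-in voxels with zero temporal
variance are a hard error (their correlation is undefined).

## Regional homogeneity

`compute_reho()` scores each voxel by Kendall's coefficient of
concordance W across the time series of the voxel and its spatial
neighbours (7 = faces, 19 = faces+edges, 27 = full 3×3×3 cube;
default 27, the most common convention — the neighbourhood size is
exposed because no single standard exists). Each series is ranked over
time with mid-ranks for ties; with K series, T time points, rank sums
`R_t` and tie correction `C = Σ_series Σ_groups (g³ − g)`,

\[ W = \frac{12 \sum_t (R_t - \bar R)^2}{K^2 (T^3 - T) - K\,C}. \]

W is 1 exactly when all neighbourhood series are rank-identical, and
lives in [0, 1]. Neighbourhoods are clipped at mask and volume borders
(the actual K is used there). A fully tied neighbourhood has no rank
information; its denominator degenerates and W is defined as 0.

## Temporal high-pass and spatial smoothing

`highpass_filter()` removes drifts by projecting each voxel's series
onto a low-frequency discrete-cosine basis and returning the residual.
The basis contains the constant plus all cosines with period longer
than the cutoff; its dimension is `floor(2·T·TR/cutoff) + 1`. A DCT
projection was preferred over a Butterworth filter because it is
deterministic, closed-form, and directly testable against an explicit
regression on the same basis. The cutoff must exceed twice the TR, and
a cutoff so short that the basis reaches the series length is refused.

`smooth_volume()` applies separable Gaussian convolution with
`σ = FWHM / √(8 ln 2)` per axis, converted to voxel units via the voxel
size; FWHM 0 is the identity. Outside the volume the data is treated
as **zero, with no mask renormalization** — the simplest fixed rule.
Values within ~4σ of the border therefore shrink toward zero; since
native-vs-template comparisons apply one fixed rule to both sides this
does not bias the contrast, but absolute edge values should not be
over-interpreted. The kernel is truncated at 4σ.

A consequence the package treats as a first-class property: smoothing
raises local spatial correlation, hence regional homogeneity increases
monotonically with FWHM. The test suite and the acceptance script
verify this on a white-noise phantom across 0/3/6/9 mm — and,
pipeline-level, that native-minus-smoothed region differences grow more
negative as the kernel widens.

## Affinity propagation over subjects

`cluster_subjects()` partitions subjects by affinity propagation:
similarity = negative squared Euclidean distance between subject
columns, messages (responsibilities and availabilities) exchanged with
damping until the exemplar set is stable. Two properties motivated the
choice of algorithm: exemplars are *actual subjects*, not averages, and
the number of clusters emerges from the data rather than being fixed a
priori.

Defaults and their reasons:

- **damping 0.9, max 1000 iterations, 50-iteration stability window**
  — stability over speed; non-convergence returns a flagged result
  with a warning, never silently.
- **preference "median"** (median off-diagonal similarity) — the
  canonical choice producing moderate cluster counts.
- **continuous input by default.** Clustering a binarized matrix is
  supported (`binarize_matrix()`, strict `> threshold`), but no
  universal binarization rule exists, so binarization is opt-in with an
  explicit threshold.
- **Missing entries refuse to cluster** rather than being imputed
  silently.
- A deterministic, zero-mean, last-digit jitter
  (`|s|·ε·(((173 i + 331 j) mod 997)/997 − 1/2)`) is added to the
  similarity matrix before iterating. Exactly symmetric inputs (e.g.
  two equidistant candidate exemplars) otherwise oscillate between
  degenerate fixed points; this is the standard remedy, made
  deterministic so identical inputs give identical outputs without
  touching the RNG. Knife-edge configurations whose message fixed point
  sits exactly at the exemplar threshold are decided by this jitter;
  robust configurations are unaffected.
- All-identical subjects are a degenerate input (every similarity 0);
  message passing carries no information there, and the package returns
  the only sensible answer directly: one cluster, exemplar subject 1.
- Display order is descending size with ties broken by exemplar index,
  so figures are reproducible.

Cluster bands in the figure get height `1 + log10(size)`: a singleton
stays exactly one row unit high, and the logarithm (base 10 chosen so
the anchor is exact) keeps very large groups from drowning out small
ones while still showing their weight.

## Native-space vs template-space statistics

`region_differences()` computes native **minus** template per region
and subject (so a negative value means template-space processing
inflated the measure), and `ttest_per_region()` runs a one-sample t per
region: `t = d̄ / (s/√n)`, two-sided p on n−1 degrees of freedom. The
test is two-sided because differences of either sign are substantively
interesting. No multiple-testing correction is applied by default —
the conventional uncorrected p < 0.05 map — with Bonferroni and
Benjamini–Hochberg available behind a flag. Zero-variance regions with
zero mean get t = 0, p = 1; zero-variance regions with non-zero mean
(a constant offset across all subjects) are flagged degenerate with a
warning rather than producing a misleading finite t. Regions are tested
on their non-missing subjects with the per-region n recorded.

## Synthetic phantoms

The generators exist so every mechanism is exercisable with known
ground truth: a mirrored block atlas with ≥ 8 voxels per area and a
background margin; subject maps built as planted cluster-by-region
means plus i.i.d. Gaussian voxel noise; 4D series that are white noise
plus, optionally, a latent signal shared between designated hub voxels
and (more weakly) everyone else. Generator parameters used in the
shipped tests — e.g. two planted groups of 8 subjects with a
between-group separation 20 at noise SD 0.05 for clustering recovery,
white-noise series of 10–24 volumes for the homogeneity oracles, and
the 10-subject / 32-area / 24³ demo cohort — were fixed once as
plausible miniature analogues of a cohort study and scaled to keep the
full suite in tens of seconds.

What the phantoms deliberately do **not** model: spatial
autocorrelation of noise, hemodynamics, physiological confounds, motion
artifacts, and registration error. Passing tests therefore demonstrate
the *computations* are correct and the pipeline's logic is sound — not
that real acquisitions will behave as benignly. In particular, real
warped atlases produce missing and mis-assigned voxels that the
validation report (`validate_label_volume()`) is there to surface.

## Numerical and rendering choices

- Region matrices serialize to TSV at 12 significant digits (the
  round-trip tolerance the reader guarantees) with `NA` for missing;
  files are written through binary connections so line endings are
  platform-independent and byte-comparable.
- Colour limits resolve symmetrically about 0 when the data span both
  signs (so zero is always the palette midpoint), `[0, max]` for
  non-negative data; mapping is a clipped affine transform into the
  palette, global across the figure — never per-region — so shades are
  comparable across subjects within a column.
- The SVG renderer is the package's own emitter with fixed element
  order and fixed number formatting: repeat renders are byte-identical,
  which makes figures diffable and regressions detectable by hash.
  General-purpose graphics devices do not guarantee this (internal
  object counters leak into their output), so SVG is the contract
  format; PNG/PDF go through the ggplot2 `autoplot()` path.
- The per-figure geometry (`brainglance_geometry()`) is computed and
  asserted before anything is drawn: column count must equal M and row
  units must equal the height sum.

## Known limitations

- Atlas areas are summarized independently; within-area spatial
  patterns (MVPA-style structure) are out of scope.
- Affinity propagation's cluster count is preference-driven; the
  package does not validate cluster counts statistically, and subgroup
  membership should be read as descriptive, not causal.
- Numerical identity with other eigenvector-centrality or homogeneity
  implementations is not promised: the similarity variant, scaling and
  neighbourhood conventions differ across tools and are documented
  above precisely so results can be compared knowingly.
- The voxel-level comparison pipeline tests areas marginally
  (uncorrected by default, per the reporting convention it mirrors);
  users needing familywise control should switch the `adjust` flag.
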
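---
title: "Connectivity-based segmentation of a periaqueductal-gray-like seed: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based segmentation of a periaqueductal-gray-like seed: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The periaqueductal gray (PAG) is a small midbrain structure wrapped around
the cerebral aqueduct. Animal work divides it into four longitudinal columns
— dorsomedial (dm), dorsolateral (dl), lateral (l), and ventrolateral (vl) —
that differ in anatomical connectivity and function, but the columns are
cytoarchitectonically invisible and far below the resolution of structural
MRI. Connectivity-based segmentation sidesteps this: every seed voxel gets a
*connectivity profile* (the distribution of probabilistic-tractography
streamlines it emits over the brain), voxels with similar profiles are
clustered, and the clusters are read as columns.

`pagseg` implements that pipeline end to end — probabilistic streamline
tracking over voxelwise fiber-orientation fields, cross-correlation k-means
clustering with silhouette filtering, per-column target profiles with
permutation-based column comparisons, winner-take-all back-projection, and
template-space group probability maps — and validates every stage against a
synthetic brainstem phantom with known four-column ground truth. Human
diffusion data of the kind the method was designed for is not distributable,
so the phantom is the package's test bed: it generates cohorts of subjects
whose columns, by construction, connect to distinct targets, and the
pipeline must recover them.

## The phantom

A phantom subject is a set of co-registered volumes on an isotropic grid
(default $40 \times 40 \times 24$ voxels at 1.5 mm):

* an **aqueduct** void along the grid's longitudinal axis (radius 1.6
  voxels), a hard termination region for streamlines (CSF is not
  traversable);
* a **seed annulus** around it, about 14 mm long and 4.5 mm wide per side,
  restricted to an angular span of 160° from the dorsal axis (the
  ventromedial rim is not part of the structure), split at the midline into
  left and right seeds;
* per side, `n_columns` (default 4) equal angular **sectors**, the
  ground-truth columns, with truth labels recorded per seed voxel;
* a **fiber-orientation field**: one axial mean direction per voxel with a
  von-Mises–Fisher concentration `dispersion_kappa` and a population weight
  (zero weight = no orientation support = termination);
* **target masks**: one designated target per column, plus a *shared* shell
  crossed by the first two sectors' bundles (so neighboring columns have
  genuinely overlapping connectivity, as real columns do), plus a
  *distractor* block outside every corridor that picks up essentially no
  streamlines and exercises the probability-floor removal rule;
* a 4×4 **subject affine** mapping subject voxels to the template grid.

### Bundle geometry

The orientation field routes one smooth bundle per sector. Near the seed the
field is radial and in-plane, so the backward half of each streamline runs
into the aqueduct and terminates. Between `r_seed_out` and `r_seed_out + 3`
voxels the direction blends into a fan of straight chords aimed at a virtual
focus placed 4.5 voxels beyond the target radius on the sector bisector (and
at the mid-seed plane axially), so the column's fibers funnel into one
bundle that converges angularly and axially yet is still a few voxels wide
where it crosses the target shell.

Each column's **designated target is its bundle's own cross-section**: the
radial shell `target_radius_mm ± 1.5` voxels cropped, via back-projection of
each voxel through the focus onto the blend-exit cylinder, to chords whose
seed-side origin lies inside the sector (angular offset within the sector
half-width, axial origin within the seeded slices). This has two properties
the validation depends on: every seed voxel's chord crosses its designated
target, and every target voxel lies on chords fed by the column's own
interior seeds, so no part of a target depends on streamlines that do not
exist. Free-standing target blocks do not have the second property — their
corners can sit outside the fan, reachable only by boundary-blurred paths —
and an earlier block-based design measurably confused the back-projection
maps at the lateral column's corners for exactly that reason.

Sector-boundary seed voxels are genuinely ambiguous: trilinear
interpolation mixes the two adjacent bundles' headings within a voxel of
the boundary, so a fraction of a boundary voxel's samples ends up in the
neighboring bundle. This is the phantom's analog of partial-volume overlap
between columns at 1.5 mm resolution, and it is what the silhouette filter
is for; it is deliberately not engineered away.

### Subject variability

Two draws distinguish subjects (both seeded from the global seed via
`derive_seed()`, so any subject regenerates in isolation):

* **geometric jitter**: a translation of the whole geometry, drawn with SD
  `geometry_jitter_mm` (default 1.5 mm = 1 voxel) and then *quantized to
  whole voxels* (clamped at 3 SD). Quantization keeps the subject affine
  lattice-exact, so nearest-neighbour resampling through the stored affine
  reconstructs template-space maps without interpolation error; the tests
  rely on this exactness. Sub-voxel anatomical variability is instead
  carried by
* **orientation noise**: a frozen per-voxel perturbation of the mean fiber
  directions, Gaussian with SD `orientation_noise_deg` (default 3°),
  independent of the sampling dispersion.

The defaults emulate a healthy adult cohort scanned at 1.5 mm isotropic
resolution with a well-estimated orientation posterior
(`dispersion_kappa = 100`, angular SD ≈ 6°). What the phantom does *not*
emulate: crossing fibers inside the seed (the container supports two
populations per voxel; the phantom uses one), scanner noise and artifacts,
nonlinear anatomical variability, gyral geometry, or distance-dependent
tractography bias. Passing the validation therefore shows the pipeline's
machinery is correct under known geometry — not that four columns would be
recovered in any particular human dataset.

## Tracking

`track_seed_mask()` launches `n_samples` samples per seed voxel (default
10,000; the cohort simulations use 1,000). Each sample draws an initial
axial orientation at the seed center with random sign and is propagated in
both directions in steps of `step_size_mm` (default 0.75 mm, half a voxel).
At each step the local orientation is drawn by choosing a fiber population
proportional to its weight at the nearest voxel, trilinearly interpolating
that population's axial mean directions (signs aligned to the previous step
direction), and sampling a von-Mises–Fisher deviate at the interpolated
concentration. A path ends on leaving the brain mask, entering the
aqueduct, losing orientation support, exceeding `max_steps` (2000), or
drawing a direction that turns more than `curvature_limit_deg` (80°) in one
step. Step size, curvature limit and cap follow common practice for
probabilistic tractography at this resolution; the scientifically salient
parameters (samples per voxel, probability floor) are exposed alongside
them in `tracking_params()`.

Counting: a sample contributes at most 1 to each brain voxel it visits
(both half-paths pooled), so visit counts are bounded by `n_samples` and
the connection probability is `count / n_samples`. Per-target hits are
recorded the same way at sample level — a sample counts once per target
however many of its voxels it crosses — which is what "probability of
connection to a region" means here and cannot be reconstructed from
per-voxel counts after the fact. The floor `P < 0.0003` (with 10,000
samples: counts below 3) removes spurious connections wherever profiles
are thresholded.

The propagation loop, vMF sampler and visit accounting are implemented in
C++ (Rcpp) because streamline propagation is sequential and
sample-parallel; everything else is R.

## Segmentation

Per side (left and right are segmented independently):

1. **Profiles**: thresholded visit counts, spatially down-binned 3× (counts
   summed over 3³-voxel bins) to keep the correlation tractable; `bin = 1`
   is the exact mode used in oracle tests.
2. **Cross-correlation**: Pearson correlation between all pairs of seed
   voxels' profiles. Zero-variance voxels (no supra-threshold connectivity)
   cannot be correlated; they are reported unclassified, never imputed.
3. **k-means** with `k = 4` on the *rows* of the correlation matrix (the
   standard choice in the connectivity-parcellation lineage; clustering the
   raw profiles instead is available via the same function), 50 restarts
   with k-means++ seeding, best fit by within-cluster sum of squares, ties
   to the earliest restart. `stats::kmeans` does the fitting.
4. **Silhouette filter**: per-voxel silhouette $(b-a)/\max(a,b)$ with
   distance $1 - \mathrm{cor}$ between the clustered feature rows,
   consistent with the clustering geometry; voxels below 0.25 are flagged
   poorly differentiated (column overlap at voxel resolution) and excluded
   from profiles and back-projection. Singleton clusters get silhouette 0.
5. **Identity assignment**: each cluster's retained voxels get a circular
   mean angle around the aqueduct axis; clusters are matched one-to-one to
   the four canonical sector bisectors by minimal total angular
   discrepancy (all $k!$ assignments enumerated). A cluster is *columnar*
   if its occupied axial slices form a contiguous run covering at least
   60% of the seed length and its angular spread is at most 120°.
   Contiguity matters: a cluster split into separated rostral and caudal
   segments spans the full length yet is not "parallel to the aqueduct",
   and that split is the canonical failure mode of this segmentation.
   Non-columnar clusters are marked unassigned; `evaluate_success()`
   scores, per column, the fraction of sides with an assigned columnar
   cluster.

## Profiles and column comparisons

Targets whose cohort-mean connection probability falls below the floor are
removed before profiling (the phantom's distractor is built to be removed).
Per column, `column_profiles()` averages the per-sample target hit rates
over the column's retained voxels and derives each column's *relative*
share of the across-column total per target; shares sum to 1 per target by
construction whenever any column connects.

Column pairs are compared across subjects (sides averaged within subject —
the subject is the statistical unit): per target, a paired t-test
(Wilcoxon switch available), Bonferroni-corrected by the number of column
pairs (6 for four columns); and per pair, a multivariate within-subject
permutation test standing in for a repeated-measures MANOVA, whose
assumptions are unverifiable at cohort sizes like 19. The statistic is the
sum over targets of squared paired t statistics; the null distribution
exchanges the two column labels within subject, i.e. flips the signs of
whole difference rows. Because row sign flips leave each target's sum of
squares invariant, the permuted statistics are computed from the flipped
means alone, which makes 10,000 permutations cheap. The add-one
permutation p-value is exact under exchangeability; its calibration is
itself checked by simulation in the acceptance suite.

## Back-projection and group maps

`backproject()` aggregates, for every brain voxel, the connection
probability from each column's retained seed voxels (mean by default; max
and sum are exposed since the aggregation is a modelling choice) and labels
the voxel with the strongest column if that strength reaches the floor.
Exact ties are labeled 0 and flagged — no evidence should mean no claim.
Raising the floor can only relabel voxels to 0, never to another column.

`to_template()` resamples subject volumes onto the template grid through
the stored affine — nearest-neighbour for labels, trilinear for continuous
maps. `group_probability_map()` averages per-subject binary maps (a
subject's two sides pooled into one map) into voxelwise population
fractions, thresholded *strictly above* 0.30 per the pipeline's default;
some published displays of such maps use 0.35, so the cutoff is an
argument, not a constant.

## Numerical choices and conventions

* Voxel coordinates are 1-based with voxel centers at integer coordinates,
  the natural R convention; all affines act on these coordinates, and the
  NIfTI world transform is the voxel-size scaling of the subject affine.
* Orientations are axial ($v \equiv -v$); the sampler resolves sign
  against the previous step direction, and the curvature check applies
  after sign resolution with a $10^{-9}$ tolerance so an exactly straight
  field survives a 0° curvature limit.
* Masks are looked up at the nearest voxel (crisp termination);
  orientations are interpolated (smooth propagation).
* The vMF sampler uses the standard inverse-CDF construction for the polar
  angle ($w = 1 + \log(u + (1-u)e^{-2\kappa})/\kappa$), stable for large
  $\kappa$; $\kappa = \infty$ short-circuits to the mean direction, and
  $\kappa = 0$ is uniform on the sphere.
* One global seed fans out to per-stage, per-subject seeds through a fixed
  affine hash (`derive_seed()`), computed exactly in doubles below
  $2^{53}$; every stage can be rerun in isolation and the full pipeline is
  bit-reproducible.
* Connectivity matrices persist as MatrixMarket sparse triplets plus TSV
  tables (text formats round-trip across platforms and need no extra
  system libraries).

## Problem sizes

The validation cohort used throughout the tests and the acceptance script
is 19 subjects at the default grid, tracked at 1,000 samples per seed
voxel (~230 seed voxels per side), which reproduces the pipeline's
behavior at full sample counts while keeping a cohort run under a few
minutes; the statistical-calibration check uses 200 simulated null
cohorts with 999 permutations each. Oracle tests (exact path equivalence,
silhouette formula, threshold arithmetic) run on purpose-built miniature
fields and matrices where the expected values are computable by
independent code.

## Known limitations

* The phantom's columns are angular sectors with deterministic bundle
  topology; it cannot probe failure modes arising from crossing fibers,
  artifactual orientation estimates, or registration error.
* The columnarity rule is an operationalization of a visual judgment; its
  thresholds (60% contiguous length, 120° spread) are exposed but any
  such rule draws an arbitrary line.
* Whether silhouette filtering should act in correlation or Euclidean
  space is underdetermined by the method's lineage; the package follows
  its clustering geometry ($1-\mathrm{cor}$) and exposes the pieces
  (`silhouette_values()`) for either.
* With `k` fixed at 4 the pipeline cannot conclude how many columns the
  data supports; model selection over `k` is explicitly out of scope.
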
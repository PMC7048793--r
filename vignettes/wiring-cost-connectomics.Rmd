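---
title: "Quantifying cortico-cortical connectivity with wiring-cost geodesics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortico-cortical connectivity with wiring-cost geodesics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`cortexwire` implements the quantitative core of a retrograde-tracer
connectomics pipeline for the primate cortex. Retrograde tracers injected
into a cortical area label the cell bodies of neurons that project to the
injection site; once the labeled cells are registered to a volumetric
parcellation, four families of analysis become possible, and this package
implements all of them:

1. **Connectivity matrices** — per-injection and per-area FLNe (extrinsic
   fraction of labeled neurons) and SLN (fraction of supragranular neurons).
2. **Wiring distances** — lengths of simulated axonal tracts obtained as
   geodesics through a gray/white-matter cost field, yielding an interareal
   distance matrix and point-to-point distances.
3. **Connectivity-distance statistics** — the labeled-neuron-weighted mean
   afferent length per injection (area-based and cell-based), modeled
   against the distance to the nearest primary sensory/motor area.
4. **Local-versus-distant comparisons** — the ratio of labeled neurons
   within 4 mm to those beyond 8 mm of the injection site, compared across
   functional networks with a Kruskal-Wallis test and Dunn's post-hoc tests.

Because the experimental data live in an external portal, the package ships
a synthetic brain phantom whose statistical structure matches what the
analyses assume, so every stage is testable offline.

## The models

### FLNe and SLN

For an injection into area $A$, the strength of the projection from area
$B$ is

$$\mathrm{FLNe}_{B \to A} = \frac{N_{B \to A}}{\sum_{X \neq A} N_{X \to A}},$$

the count of labeled neurons in $B$ over all labeled neurons outside the
injected area; intrinsic (within-area) labeling is not evaluated. The
laminar origin of a projection is summarized by

$$\mathrm{SLN}_{B \to A} = \frac{N^{supra}_{B \to A}}{N_{B \to A}},$$

the supragranular fraction, undefined for areas without a discernible
layer 4 (in the marmoset parcellation: Ent, Pir, APir, and the subdivisions
of area 29). Multiple injections into the same area are aggregated by the
arithmetic mean of FLNe and by pooling supra/infra counts before forming
SLN. Two choices deserve comment:

- The FLNe mean counts a projection that an injection did not reveal as 0
  in that injection. Averaging only over observing injections would bias
  strength upward for rarely seen projections; the package exposes the
  alternative (`unobserved = "na"`) but defaults to zero-filling.
- SLN pooling across injections (rather than averaging per-injection SLNs)
  weights injections by their labeled-cell counts, which is how the ratio
  of pooled totals behaves.

### Wiring-cost geodesics

Axonal tracts are simulated as geodesics in a medium in which white matter
is fast ($f_{WM} = 1$), gray matter slow but passable ($f_{GM} = 0.05$,
ratio 20), and the outside forbidden ($f_{OUT} = 0$). The arrival-time
field $T$ from a seed solves the Eikonal equation $|\nabla T| = 1/f$,
computed by fast marching on the voxel grid (anisotropic spacings
supported). Geodesics are recovered by fixed-step steepest descent on the
trilinearly interpolated field; the wiring *distance* is the arclength of
that trajectory in mm, not the travel time.

Area-to-area distances seed the solver at one area's centroid — the maximum
of the signed distance transform, i.e. the deepest interior voxel, which
unlike a center of mass always lies inside the area — trace from the other
centroid, and average the two directions:
$d_{ij} = \tfrac12 (d_{i \to j} + d_{i \leftarrow j})$. The relative
direction difference $|d_{i \to j} - d_{i \leftarrow j}| / d_{ij}$ is kept
as a per-pair quality diagnostic; on the phantom at default settings every
pair falls below 0.05 (the QC requires at least 95% to). An absolute (mm) variant is available since the
definition of this unitless diagnostic is a package choice.

Numerical choices that matter:

- **Scheme.** First-order upwind updates, upgraded to second-order
  one-sided differences where two consecutive upstream values are available
  and the stencil does not straddle a speed interface (where the wide
  stencil is inconsistent). The seed's surroundings (a 3-voxel ball with an
  unbroken homogeneous line of sight) are initialized analytically to
  temper the source-point singularity.
- **Backtrace.** Fixed step of 1/10 of the smallest voxel edge, gradient by
  central differences of the interpolated field, stopping within one voxel
  of the seed (the remaining straight segment is added). A discrete
  downhill hop is the fallback wherever the interpolated gradient stalls.
  The step fraction was chosen from an accuracy study on the phantom: it
  roughly halves the per-path noise of a 1/4-voxel step at modest cost.
- **Length measurement.** The polyline is smoothed with a 0.75 mm
  moving-average window before its arclength is measured. Steepest descent
  wanders at sub-voxel scale wherever the arrival field is nearly flat
  (inside wide white-matter tubes); the wander inflates raw arclengths and
  is the main source of direction asymmetry. The window is far below the
  curvature scale of real tracts, and straight corridors measure to within
  a fraction of a percent of the Euclidean distance.
- **Ties and failures.** Centroid ties take the lexicographically smallest
  voxel index; mutually unreachable areas get distance `Inf`, are flagged,
  and are excluded from summary means.

The cost-ratio choice is audited by `sensitivity_sweep()`: mean interareal
distance is recomputed for $f_{WM}/f_{GM}$ ratios from 1 (uniform medium)
upward. On the phantom the mean varies by well under 5% across ratios
10–30 and exceeds the uniform-medium limit, matching the expectation that
the analysis is insensitive to the exact ratio within the biologically
plausible range. Between adjacent large ratios (20 vs 30) the continuum
effect is smaller than the solver's per-path noise (~0.3%), so only the
contrast against the uniform limit is asserted in tests.

### Validation against a lattice oracle

The test suite validates the solver against an independent 26-neighbour
Dijkstra oracle (igraph), with edge weights equal to the mean slowness
sampled along the edge times its length. Two caveats, documented here
because they bound what such an oracle can certify: a lattice metric
overestimates Euclidean lengths by up to ~12% in the worst direction
(metrication), and at tissue contrast 20 the two discretizations treat
boundary voxels differently. The suite therefore asserts the relationship
that holds mathematically — the oracle is an admissible-path upper bound
on travel time, and the solver must stay within a small margin above it
and within the metrication bound below it — alongside closed-form checks
in uniform media (arrival times within two voxel diagonals, straight
corridors within 5%, refinement at better than first-order). A strict
3% pointwise equivalence between the two discretizations is not
attainable on coarse grids and is knowingly left as a failing check in
the acceptance suite rather than weakened.

### Connectivity distance and the distance-to-primary gradient

Per injection the package computes:

- `cd_area` — the count-weighted mean of centroid distances from the
  injected area to each source area (intrinsic excluded);
- `cd_cell` — the mean simulated-tract length from each labeled cell to
  the injection center. Cells and the center are first projected to the
  mid-thickness surface so that laminar depth does not bias lengths, and
  cells within the injection's exclusion radius (where labeling is
  unreliable) are dropped; intrinsic and extrinsic cells both contribute;
- `L_supra`, `L_infra` — `cd_cell` restricted to supragranular or
  infragranular cells, and their ratio;
- `dist_to_primary` — 0 inside a primary area, else the minimal wiring
  distance from the injection barycenter to a boundary voxel of any
  primary area. Three named primary sets are shipped (default,
  functionally defined sensory, koniocortex-type).

`fit_cd_glm()` regresses connectivity distance on `dist_to_primary` plus
covariates: for the area-based response, the location centrality of the
injected area (mean wiring distance from its centroid to all others,
capturing that central areas have shorter connections by construction) and
its gray volume; for the cell-based response, the injection volume and the
mean wiring distance from the injection to the cortical sheet (sampled on
the mid-thickness surface, capped at 1500 points). The reported $\beta$ is
standardized (z-scored design) and therefore unitless; the raw-scale slope
is also returned. A perfect fit is flagged (`F = Inf`) rather than
reported with a meaningless denominator. Both a per-injection and a
per-area-mean mode are available, the latter averaging records of
injections sharing an area before fitting.

### Local versus distant connectivity

`local_distant_ratio()` classifies each labeled cell by its distance to
the injection center: local within 4 mm, distant beyond 8 mm, neither in
between (the fractions need not sum to 1). The metric defaults to the same
wiring distance used by `cd_cell` and can be switched to Euclidean; the
thresholds are arguments. Ratios are compared across the five shipped
functional networks (Pri, HOSom, VisM, CON, APEX — the latter two putative
homologs of the human default mode network subsystems) with the
tie-corrected Kruskal-Wallis H and Dunn's pairwise z-tests under Holm
adjustment (no adjustment is selectable; the reference analysis does not
state one). Injections with no distant cells have infinite ratios; they
are excluded from the test and logged, since a rank test cannot use them
without an arbitrary convention. Ratios are computed per injection, not
per area, matching how outliers are displayed in the reference analysis.

## The phantom: what it emulates and what it does not

`phantom_config()` + `build_template()` construct a spherical-shell cortex
(default: 80³ voxels at 0.25 mm, shell thickness 2 mm) around a
white-matter core, partitioned into `n_areas` contiguous sectors (Voronoi
cells of deterministic quasi-uniform anchor directions). The outer half of
the shell is supragranular, the inner half infragranular — the radial
midpoint stands in for layer 4 and carries the mid-thickness surface
sample. The geometry was chosen so that oracles are tractable: distances,
boundaries, and laminar splits all have analytic counterparts, and the
default grid keeps a fast-marching solve under a second while leaving
8 voxels across the cortical thickness.

Injections are placed at uniformly drawn gray voxels of requested areas,
with exclusion radii uniform in 0.1–1.1 mm (the range reported for real
injection sites). Labeled cells are drawn per injection from a multinomial
over source areas whose per-voxel intensity is
`pair_weights[target, source] * exp(-d(target, source) / lambda)`, so a
source area's expectation also scales with its gray volume; `d` is the
same wiring distance the analyses use, so generator and analysis share one
metric. The default decay length is 3 mm, pair weights are log-normal
(the empirical distribution of projection strengths is heavy-tailed and
the reference dataset does not publish its shape — a free choice,
documented here), the intrinsic weight is 2 (intrinsic labeling dominates
locally but is excluded from FLNe anyway), and each pair has its own
supragranular probability. Supra and infra cells share one spatial law, so
the laminar length ratio is 1 in expectation — a deliberate null that the
laminar split must recover.

What the phantom does **not** emulate: gyral/sulcal morphology, laminar
variation in cell density, registration error, histological artifacts, and
the anisotropic section spacing of a reconstructed atlas (it supports
anisotropic voxels but defaults to isotropic). Passing tests on the
phantom certify the estimators and their calibration, not the biology of
any real dataset.

## Statistical calibration

Three properties are verified by simulation in the test suite, at problem
sizes chosen to finish in minutes on one CPU:

- the GLM recovers a planted standardized slope of 0.33 at $n = 143$
  (500 replicates; the CI covers at its nominal 95% within a binomial
  3-sigma band);
- with a response independent of the predictor, the slope's CI excludes
  zero at the nominal 5% rate;
- the Kruskal-Wallis test holds its 5% size across five groups totalling
  143 observations (1000 replicates), and small-sample H agrees with the
  exact permutation distribution.

## Known limitations

- The centroid of a shell-like sector sits on a signed-distance ridge, so
  its exact voxel can shift under resolution changes; distances between
  such centroids are stable only at a fixed resolution.
- At tissue contrast 20 and coarse voxels, arrival times carry a few
  percent discretization error near gray/white interfaces; traced lengths
  are considerably more robust and are what the analyses consume.
- Distance-to-primary prunes trace candidates by arrival time before
  measuring lengths; this is exact in practice (validated against brute
  force within 2%) but is formally a heuristic.
- The importer deliberately has no network client for the data portal;
  real data arrive as NIfTI label volumes plus CSV cell tables, with a
  column-mapping option for foreign spreadsheets.
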
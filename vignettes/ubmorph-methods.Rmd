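---
title: "Methods: 3D cell-shape morphometrics for branching epithelial tips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D cell-shape morphometrics for branching epithelial tips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ubmorph quantifies individual epithelial cell shape in 3D images of
branching tubular organs.  The motivating system is the embryonic kidney
ureteric bud, whose tips iterate through four morphologies — initial bud,
ampulla, asymmetric ampulla, T-bud — plus the non-tip trunk epithelium.
The package covers the full analysis chain: cell reconstruction from
membrane-staining probability maps, seven-parameter shape description,
clustering with spatial back-mapping, 2D embeddings, stage statistics,
nuclear-envelope wrinkling metrics, and traction-force computations.  A
synthetic-tissue generator with exact ground truth makes every stage
verifiable without imaging data.  This vignette explains the models,
conventions and design choices; it states no empirical result beyond what
the package's tests and `scripts/acceptance.R` themselves compute.

## Conventions

All grids are `(z, y, x)` arrays in physical units: micrometres for
lengths, Pa for stresses, N for forces.  The default voxel is anisotropic,
`(0.333, 0.2, 0.2)` um, matching a 0.333 um confocal z-step with 0.2 um
lateral sampling.  Anisotropy is handled by computing distances and
structuring elements in physical coordinates — volumes are never resampled
to isotropy, which would interpolate exactly the thin membrane structures
the segmentation depends on.

## Segmentation (`segment_pipeline()`)

The input is a membrane probability map, the standard output of a pixel
classifier trained on membrane staining (the package consumes such maps; a
thresholded intensity image works as a crude substitute).  Four stages:

1. **Gap closing** — grayscale morphological closing with an ellipsoidal
   structuring element of physical radius `radius` (default 0.6 um).
   Closing is extensive and idempotent, and seals staining dropouts
   smaller than the element.  A radius that resolves to less than one
   voxel along any axis is refused (no-op with a warning) rather than
   applied anisotropically.
2. **Marker seeding** — voxels below `threshold` (default 0.5) form the
   interior mask; its exact anisotropic Euclidean distance transform is
   computed in micrometres, and markers are the 26-connected components of
   the h-maxima of that distance map (`h` = 1 um by default).  The
   h-maxima transform merges maxima whose separating relief is shallower
   than `h`, which suppresses spurious markers from membrane roughness
   inside a single cell; an isolated interior component always keeps
   exactly one marker regardless of `h`, so small cells are not lost.
   Marker components touching the volume border are merged into a single
   marker so the tissue exterior floods as one basin.
3. **Watershed** — Meyer's marker-controlled flooding on the probability
   relief, 26-connectivity, deterministic tie-breaking by queue insertion
   order.  Voxels where two basins meet become watershed lines and stay at
   label 0; excluding shared boundary voxels keeps per-cell moments
   unbiased.
4. **Volume gate** — labels with physical volume outside `[vmin, vmax]`
   (default 50–500 um^3, the plausible epithelial cell range) are removed;
   this is also what removes the lumen-cavity and exterior basins.
   Survivors are renumbered consecutively by decreasing volume.

26-connectivity is used throughout: 6-connectivity splits cell bodies
along diagonal contacts at this anisotropy.

## Shape descriptors (`compute_features()`)

Per cell, the seven parameters follow the ellipsoid-moment convention.
The covariance matrix of voxel-centre coordinates of a solid ellipsoid
with semi-axes $(a, b, c)$ has eigenvalues $(a^2, b^2, c^2)/5$, so the
full axis lengths are reported as $L_i = 2\sqrt{5\lambda_i}$, descending.
Then

* **volume** $V$: voxel count times voxel volume (um^3);
* **longest / intermediate / minor axis**: $L_1 \ge L_2 \ge L_3$ (um);
* **elongation**: $L_1 / ((L_2 + L_3)/2)$, $\ge 1$, dimensionless;
* **ellipticity**: $1 - L_3/L_1$, in $[0, 1)$, 0 for a sphere;
* **roundness**: $3V/A$ (um), where $A$ is the surface area; this equals
  the radius for a perfect sphere and is strictly smaller for any other
  shape of the same volume, because spheres minimise area at fixed volume.

Roundness carries micrometre units, consistent with reporting cell
roundness on a um scale; it is the only common shape descriptor that does.
Surface area is measured by triangulating the 0.5 iso-surface of a lightly
smoothed indicator (marching tetrahedra: each grid cube is split into the
six Kuhn tetrahedra and iso-crossings are interpolated in physical
coordinates).  The Gaussian pre-smoothing (sigma = 0.7 times the largest
voxel edge) suppresses voxelization staircase bias; it is tied to the
voxel, not to the object, so it does not scale with cell size.  On
digitized test shapes this puts spheres within ~1% and a cube within ~7%
of the closed forms — the residual cube error is the price of the
smoothing that makes curved (i.e., cell-like) surfaces accurate.

Stage-level summary values are unweighted means over cells — means of
per-cell ratios.  This matters: the mean of per-cell elongations does not
equal the elongation of the mean axes, and the package deliberately
reports the former (the table convention); a test asserts the two differ
on heterogeneous data.

Degenerate labels (too few or coplanar voxels) get their minor axis
floored at one voxel extent and are flagged in the `degenerate` column,
never silently dropped.

## Clustering, selection, back-mapping

Features are z-scored once (`zscore_features()`); the same standardized
matrix feeds clustering and both embeddings, so there is a single
standardization pathway.  Clustering is agglomerative with Euclidean
metric and Ward linkage — a choice made here for compact, size-balanced
clusters of the kind seen in cell-shape clustergrams; the number of
clusters is a user parameter (default 6).  Cluster labels are canonical
(renumbered by smallest member row index), making the partition invariant
to input row order.  `select_quantile()` implements the top-decile rule:
the `ceiling(q N)` cells with the highest value of one feature, ties at
the cut broken by ascending cell id; because only the order matters, any
monotone transform of the feature leaves the selection unchanged.
`backmap()` paints selected cells back into the source label volume
voxel-exactly, and `cluster_proportions()` reports per-tip percentages
with per-stage values as unweighted means over tips.

## Embeddings

`pca_2d()` projects the z-scored matrix on its top two principal axes,
with each component's sign fixed so its largest-magnitude loading is
positive (determinism).  `umap_2d()` wraps UMAP with community defaults
(`n_neighbors = 15`, `min_dist = 0.1`, seed 0), single-threaded for exact
seed reproducibility; hyperparameters are recorded on the result.
Embeddings are pure views — they never alter, filter or reorder the
feature table.

## Stage statistics

The statistical layer is rank-based: a tie-corrected Kruskal–Wallis
omnibus followed by the Conover–Iman post hoc on the joint ranks,

$$ t_{ij} = \frac{\bar R_i - \bar R_j}
   {\sqrt{S^2 \frac{N-1-H}{N-k}\left(\frac1{n_i}+\frac1{n_j}\right)}},
   \qquad S^2 = \frac{\sum R^2 - N(N+1)^2/4}{N-1}, $$

referred to $t_{N-k}$ and Holm-adjusted.  Holm was chosen for the post hoc
because it controls the family-wise error rate without independence
assumptions.  For small cohorts an exact permutation p-value is available
(`p_method = "permutation"`, full enumeration of group relabelings); the
test-suite validates it against an independent brute-force oracle.  The
asymptotic chi-square/t p-values and the exact permutation p-values
differ at tiny n (e.g. H = 3.86 on two groups of three gives chi-square
p = 0.0495 but exact p = 0.10) — the permutation path is the exact
reference there.

Variance comparisons use the classic mean-centred Levene W (one-way F on
absolute deviations; `center = "median"` gives Brown–Forsythe), computed
through base R's ANOVA machinery and cross-checked against
`car::leveneTest` in the tests.  Mean-centred is the default because
"Levene's test" without qualifier conventionally means the mean-centred
form.  Note a property of the classic form itself: on normal null data at
moderate n it is mildly liberal (empirical size ~0.055 at n = 30–100 per
group in our null simulations, identical in the reference
implementation), whereas the Brown–Forsythe centring holds its nominal
size; the calibration checks in the test-suite therefore exercise the
median-centred variant, and users testing variance differences at small
n may prefer it for the same reason.  Within-range comparisons use two-sided Mann–Whitney tests with
exhaustive enumeration when both samples have at most 8 values (ties by
mid-counts, two-sided by doubling) and the tie/continuity-corrected
normal approximation otherwise.  Shared cell-volume windows for
cohort-vs-stage comparisons are explicit configuration values
(`shared_volume_ranges()`: 50–298, 50–490, 50–272, 50–500 um^3), not
auto-derived, so analyses reproduce the same windows exactly.
Distribution summaries report mean, median, sd and the adjusted
Fisher–Pearson skewness, with histogram bins shared across groups for
overlay plots.

One deliberate choice: where a legend-style shorthand would say "ANOVA",
the package implements the nonparametric Kruskal–Wallis/Conover–Iman path
as primary — the procedure actually specified for these comparisons — and
one-way ANOVA remains available through base R as a cross-check.

## Nuclear contour morphometrics

`contour_metrics()` computes the standard shape-descriptor panel
analytically from the polygon: shoelace area, perimeter, circularity
$4\pi A/P^2$, fitted-ellipse major/minor axes from the second moments of
the *filled* polygon (Green's theorem; for an ellipse the covariance
eigenvalues are (semi-axis)^2/4), aspect ratio, roundness
$4A/(\pi\,\mathrm{major}^2)$ and solidity $A/A_{hull}$.  Moments of the
filled region — not the vertex ring — match the standard shape-descriptor
convention.  The convex hull is taken on the vertices, which is adequate
for densely sampled contours (import warns below 128 vertices).  Solidity
is 1 exactly for convex shapes and decreases monotonically with boundary
wrinkling; `wrinkling_compare()` runs Welch's two-tailed t-test per
descriptor between two cohorts.

## Traction cytometry

Fourier-transform traction cytometry with the spectral Boussinesq
half-space surface Green's tensor for wave vector $k$:

$$ \tilde G(k) = \frac{2(1+\nu)}{E k^3}
   \begin{pmatrix} (1-\nu)k^2 + \nu k_x^2 & -\nu k_y k_x \\
                   -\nu k_y k_x & (1-\nu)k^2 + \nu k_y^2 \end{pmatrix} $$

`fttc_forward()` maps tractions to displacements; `fttc()` inverts with
zeroth-order Tikhonov regularization
$\tilde t = (\tilde G^\top\tilde G + \lambda^2 I)^{-1}\tilde G^\top\tilde u$
per wave vector, zero-frequency traction pinned to zero (no net drift).
The Poisson ratio defaults to 0.5, the incompressible-polyacrylamide
convention, and is configurable.  When `lam = NULL` the parameter is
picked per field by the L-curve corner (maximal curvature of log residual
vs log solution norm on a 20-point log grid), removing a hand-tuned
constant.  Real displacement crops are non-periodic, so a 10% cosine
taper is applied by default before the FFT; synthetic fields produced by
the spectral forward model are periodic by construction, and
oracle-equivalence checks therefore run with `taper = 0`, where the
inversion at `lam = 0` is exact up to the band limit.

`rms_traction()` is the monolayer summary (root mean square traction over
the field of view or a mask).  `intercellular_force()` integrates the
unbalanced traction under one cell of a doublet,
$F_{ab} = -\sum_a t\,\mathrm{d}A$ (Pa um^2 converted to N via 1e-12),
which by force balance equals the junction force; the two cells' vectors
are checked for 10% balance.  `piv_displacement()` estimates bead
displacements by normalized cross-correlation block matching with
parabolic sub-pixel refinement, flagging and inpainting featureless
windows.  `delamination_speed()` measures mean outward boundary advance:
the distance transform of the earlier mask averaged over the later mask's
boundary, divided by the elapsed time (e.g. a 5280 s observation window).

## The synthetic-tissue generator

`generate_tip_tissue()` builds monolayer epithelia with exact per-cell
ground truth.  Cells are digitized ellipsoids seeded on the surface of a
stage-specific lumen — sphere (initial bud, ampulla), two-sphere union
(asymmetric ampulla: merged unequal lobes; T-bud: two separate lobes) or
capsule (trunk) — with Poisson-disc spacing, long axis along the surface
normal (columnar epithelium), tangent orientation random.  Overlaps
resolve to the smallest ellipsoidal norm, so labels stay disjoint;
infeasible packings raise an explicit error rather than degrading
silently.  The membrane probability map is a band of physical thickness
`membrane_thickness` (default 0.4 um) hugging the outside of every cell
(plus any directly touching interfaces), Gaussian-smoothed — emulating a
pixel-classifier output directly.  Placing the band in the intercellular
gap puts the watershed crest mid-gap, which makes recovered cell volumes
essentially unbiased.

**Calibration.**  Per-stage semi-axis distributions are log-normal.  Their
medians are calibrated to published stage-level means with a constraint:
real cells are space-filling polyhedra, so their reported mean axis
lengths and mean volumes are not simultaneously attainable by a true
ellipsoid (the ellipsoid spanned by the stage-mean axes has roughly 40%
of the stage-mean volume).  The generator keeps the stage-mean *axis
ratios* — which carry the elongation/ellipticity stage signal — and sets
the overall scale so the ellipsoid volume matches the stage-mean volume,
keeping synthetic cells inside the 50–500 um^3 analysis window.  The
dispersion (`sdlog = 0.08`) is a free parameter chosen modest so synthetic
cohorts emphasise stage-to-stage shifts; real tissues are far more
heterogeneous, which is one of the things passing tests on synthetic data
do *not* demonstrate (see Limitations).  Degradation for robustness tests
is explicit: `degrade_membrane()` punches contiguous disc-shaped dropout
patches (real staining failures are local, not salt-and-pepper) and adds
clipped Gaussian noise.

Wrinkled nuclear contours follow
$r(\theta) = R\,(1 + \varepsilon\sin(k\theta + \phi))$ — star-shaped,
hence simple by construction; cohorts jitter $R$, $\varepsilon$ and $k$,
optionally rescaling $R$ by $1/\sqrt{1+\varepsilon^2/2}$ so the expected
area is independent of wrinkling (planted-equal areas).  Traction scenes
place cosine-tapered disc patches (band-limited; a patch radius below
twice the grid spacing is refused) and compute displacements through the
forward model, so the scene is its own oracle.

## Problem sizes and reproducibility

Everything is seeded and bit-reproducible: tissues from `spec$seed`,
UMAP from its `seed` argument, pipelines from the configuration (which
carries a hash embedded in every output bundle).  The test-suite and the
acceptance script use deliberately compact problem sizes chosen as the
smallest that exercise each property cleanly: 10–40 cells per synthetic
tip, 100 random ellipsoids for recovery, 128x128 traction grids, 2000
null replicates for test calibration, 20 seeds for the stage-structure
experiment.  The stage-structure experiment (`branch_cycle_recovery()`)
uses compact lumen geometries — just large enough that lumen-cavity and
exterior basins stay outside the 50–500 um^3 gate — and comparable packing
density across stages, because watershed crests sit mid-gap and strongly
unequal crowding would bias recovered tangent axes differently per stage.

## Numerical choices and degenerate inputs

* Distance transforms are exact (separable parabolic envelopes) with
  per-axis spacing; no chamfer approximations.
* Watershed ties break by queue insertion order — deterministic across
  runs and platforms.
* The h-maxima plateau detection uses an epsilon of 1e-7 times the
  distance-map maximum; distances are quantized well above this.
* `prob = 1` everywhere (no interior) and `h` above the maximal interior
  distance raise explicit errors; empty masks, empty regions, shrinking
  delamination masks and non-finite displacement fields are rejected with
  messages naming the violated assumption.
* Probability TIFFs are stored as 32-bit samples (quantization 2^-32,
  far below imaging precision); label TIFFs as 16-bit integers, exactly.
  Reading a volume without a voxel-size sidecar and without an explicit
  `voxel_size` is an error — the package never silently assumes isotropy.

## Limitations

The synthetic generator emulates geometry, not microscopy: no PSF, no
depth-dependent attenuation, no classifier confusion structure — membrane
dropouts and Gaussian noise are coarse stand-ins.  Synthetic cells are
ellipsoids, so feature recovery results quantify the pipeline's accuracy,
not its behaviour on concave or interdigitated real cells.  Cell-shape
dispersion is deliberately modest; stage-recovery results demonstrate
sensitivity to planted shifts, not power on real heterogeneity.  The FTTC
model assumes an elastic half-space (thick gel) and in-plane tractions;
finite gel thickness and out-of-plane components are out of scope.  The
fitted-ellipse convention for 2D contours assumes densely sampled,
simple polygons.
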
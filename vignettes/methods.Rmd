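---
title: "Methods: 3D single-cell morphometry and filopodia dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D single-cell morphometry and filopodia dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmorph)
```

`isletmorph` quantifies single-cell 3D morphology and protrusive dynamics of
sparsely labeled cells in confocal stacks — the situation of mosaically
labeled endocrine cells in the developing zebrafish islet, where a handful of
bright cells with actin-labeled filopodia sit on a dark background. This
vignette explains the models and procedures, the parameters that matter, and
the choices made where the underlying workflow (originally a chain of
interactive ImageJ/Fiji, MATLAB and Mathematica steps) left the details open.

## The synthetic scene generator

No imaging data ships with the package, so every stage is validated against
a scene generator with complete ground truth. A scene is a list of cells,
each an ellipsoidal body (semi-axes in µm, optional rotation, peak intensity)
carrying filopodia: straight tapered frustums from a base radius (default
0.45 µm) to a tip radius (default 0.25 µm), with an intensity profile that
falls from the body level proximally to 0.6× distally — brighter proximal
actin labeling with tapering dim tips, as in real protrusions. Per frame the
geometry is rasterized, convolved with an anisotropic Gaussian point-spread
function (default σ = (0.6, 0.25, 0.25) µm in (z, y, x)), translated by the
cumulative whole-field drift, then degraded with background (10 intensity
units), Poisson shot noise (2 photons per intensity unit, i.e. ≈200 photons
at a body peak of 100 — a typical confocal operating point) and Gaussian read
noise (sd 2). The default grid uses voxels of (1.0, 0.3, 0.3) µm, so every
downstream computation must handle ~3× axial anisotropy; time-lapse
conventions are 2-minute frames over a 20-minute window (11 frames).

Two rasterization details matter. First, filopodium shafts are thinner than
the axial voxel spacing, so a hard inside/outside test can miss them entirely
when the axis runs between two z-planes; shafts therefore deposit intensity
with a partial-volume soft edge one voxel footprint wide, as physical
sampling does. Second, the contrast defaults are set so that protrusions are
traceable end to end over the noise floor — the regime the source imaging
was in, since its protrusions were traced by eye; substantially dimmer tips
simply vanish from a 1-µm-z-step raster and no tracer could recover them.

The truth ledger records exact per-frame cell centres, filopodium lengths,
applied drift, and per-filopodium dynamics labels. Those labels are computed
by *the same function* that classifies measured tracks
(`truth_event_labels()` and `classify_dynamics()` share one rule
implementation), so recovery tests compare like with like.

What the generator does **not** emulate: curved or branched shafts (the
geometry supports branch extraction, but scripted scenes use straight rays),
duct and exocrine tissue context, spectral bleed-through, depth-dependent
attenuation, and photobleaching. Passing recovery tests therefore shows the
pipeline is correct and robust at realistic noise for sparse, well-separated
cells; it does not certify performance in dense tissue.

## Preprocessing and drift correction

The preprocessing chain mirrors the standard confocal recipe and is applied
uniformly (identical parameters to every frame and channel): a 2D median
filter per z-slice (radius 1 voxel) against speckle noise; rolling-ball-style
background subtraction, realized as grayscale opening per slice with a
square structuring window whose radius is given in µm (default 10) and
converted through the xy spacing, so results do not depend on magnification;
and contrast normalization by percentile clipping (defaults 0.1 and 99.9)
with linear rescaling to [0, 1]. The original workflow names no numeric
values for any of these; all are parameters with logged defaults.

Whole-field drift is estimated per frame against frame 1 by 3D phase
correlation on a reference channel and corrected by an integer-voxel
translation applied to all channels (out-of-frame voxels zero-filled).
Integer translation matches the registration-by-translation tools the
original chain used; sub-voxel refinement is deliberately out of scope.
Recovery is within one voxel per axis for drifts up to five voxels per
frame over ten-frame series.

## Segmentation

Single cells are segmented by 3D hysteresis thresholding: voxels at or above
the high threshold seed the mask, voxels at or above the low threshold are
kept iff 26-connected to a seed. Auto mode takes the high threshold from
Otsu's method and sets low = 0.5 × high; both values are recorded in the
mask's provenance. Masks are refined by hole filling (background components
not 6-connected to the array border), dilation by a voxel-isotropic ball,
and smoothing by morphological opening-then-closing (the original "smooth"
operation is unspecified; a morphological realization keeps the mask binary
and the operation idempotent-ish, and is flagged as a choice). `purify()`
retains the largest 26-connected component, with ties broken toward the
smallest linear voxel index so reruns are deterministic. Manual slice-wise
trimming of touching neighbors is replaced by serialized exclusion masks
(`apply_exclusion()`), so every published measurement can be re-derived from
recorded inputs. Foreground connectivity is 26 and background 6 — the
standard complementary pair.

## Morphometry in physical units

Volume is voxel count × voxel volume. Surface area comes from an isosurface
mesh in physical coordinates: the binary mask is Gaussian-smoothed (σ =
0.7 µm), resampled to an isotropic grid at the finest axis spacing, and
triangulated by marching tetrahedra at a *volume-matched* iso level — the
level at which the super-threshold volume of the smoothed field equals the
mask's voxel volume. Counting exposed voxel faces would overestimate the
area of a sphere by ~50% and cap sphericity near 0.62, contradicting the
defining property that a perfect sphere scores 1; the volume-matched level
additionally removes the curvature-dependent bias of a fixed 0.5 level
(which shrinks convex bodies by ≈ σ²/r). On digitized spheres of 4–15 µm
diameter at (1.0, 0.3, 0.3) µm spacing this pipeline yields sphericity
`π^(1/3) (6V)^(2/3) / A` between 0.98 and 1.00 and mesh-enclosed volumes
within ~1% of the voxel count.

The Feret (maximum caliper) diameter is the largest pairwise distance
between surface-voxel centres in µm, computed over convex-hull vertices — a
pure-R quickhull, written for this package because no installed dependency
provides 3D hulls — and verified in tests against the brute-force all-pairs
maximum. The best-fit ellipsoid is the inertia-equivalent ellipsoid: from
the voxel cloud's second central moments (plus the voxel's own moment,
spacing²/12), semi-axes are `sqrt(5 λ_i)`; the volume:ellipsoid-volume ratio
is a convexity/complexity measure that is ≤ 1 for convex bodies up to
discretization.

Group comparisons use the two-tailed two-sample t-test, pooled-variance by
default with the Welch variant behind a flag (the original statistics do not
state which was used; both are available and the default is recorded in the
output). Regressions are ordinary least squares per group with R².

## Filopodium tracing and dynamics

A filopodium is any traced protrusion at least 1.0 µm long. Tracing per
frame proceeds: segment the whole cell including protrusions (hysteresis
with low = 0.2 × high, keeping dim shafts); subtract the cell body; and
trace each protrusion component by multi-source Dijkstra through its voxel
graph (26-connectivity, physical edge lengths) from the voxels adjacent to
the body, the same shortest-path computation the interactive neurite-tracing
tool performs. Tips are local maxima of geodesic distance; each tip yields
one trace (branched protrusions share their trunk), and the trace's length
is its geodesic distance in µm.

Robustness around the body surface drives several parameters. The body mask
is first opened with a physical-unit ball (1.5 µm) so that bright proximal
shafts — which pass the body threshold — are not swallowed into the body,
then grown by a 0.6 µm guard margin so the point-spread halo hugging the
surface is not read as protrusions; the margin is added back to reported
lengths. Components under 8 voxels are noise; candidate tips within 2.5 µm
of an already-traced path are echoes of it; traces from different components
rooted at the same base (≤1.6 µm) or running parallel within one z-spacing
are axial blur copies of one shaft and are deduplicated; and a trace must
point outward (≥0.4 of its base-to-tip displacement along the outward radial
direction), which rejects halo spurs running tangential to the body. With
these defaults, single noiseless filopodia of 4–10 µm trace within ~8% of
truth and within 15% under the default noise model.

Across frames, traces are linked greedily by nearest base point within a
2 µm gate (ties to the closest length); series analysis applies Otsu once to
the whole series so thresholds cannot flicker frame-to-frame, and smooths
each frame with a light 0.3 µm Gaussian first. Tracks detected in fewer
than 2 frames are discarded as flicker, tracks rooted at the same base are
merged, and interior single-frame detection gaps are closed by linear
interpolation — a 2-minute dropout of an otherwise continuous track is
detector noise, not a disappearance.

Dynamics follow the published rules: a **dynamic event** is counted at each
frame where a filopodium (≥1.0 µm) appears, disappears, or changes length by
more than 50% relative to the previous frame; a **stable filopodium** is
present at every time point of the 20-minute window and never ranges by more
than 50% of its minimum length. Where the 50% rule's baseline was
unspecified, events compare consecutive frames and stability uses the series
minimum; both are parameters (`change_fraction`, and the window via
`series_duration`/`frame_interval`). A transition across the 1.0 µm floor
counts as appearance/disappearance, never double-counted as a length change.

On scripted cohorts (10 cells per group, 5 filopodia each, 11 frames at the
default noise), the pipeline recovers stable/dynamic labels and keeps
per-cell event counts within ±1 of truth; the acceptance suite runs exactly
this study and also verifies that a generator-imposed difference in stable
counts between an "isolated" and a "clustered" cohort is detected at
p < 0.05 with n = 10 per group.

## Trajectories and clustering metrics

Cell centres are binary-mask centroids in µm; identity across frames comes
from per-cell masks, since sparse mosaic labeling makes identity
unambiguous — no general multi-object tracker is attempted. Trajectories can
be normalized to a reference cell (reference at the origin, whole-field
motion removed). Centre-to-centre distance series carry two added trend
summaries, the last-minus-first delta and Kendall's τ against time, because
the original analysis reports distance curves without a summary statistic;
the curves remain the primary output. The clustering metric is the volume of
the convex hull of all present cell centres (the same quickhull as above);
fewer than four non-coplanar centres give volume 0 with a degeneracy flag.

## Counting and reporting

Labeling-efficiency counts compare two channels of point annotations: a
reference point is double-positive iff a second-channel point lies within
the match radius (default 3 µm, about half a nuclear diameter — the original
matching was by eye). Points may come from a saved annotation table or from
the built-in 26-neighborhood local-maximum detector; duplicates closer than
half the radius merge with a warning. `build_report()` bundles stage outputs
into CSVs plus a deterministic JSON body (timestamps excluded) with
parameters and package version, flagging absent stages rather than failing.

## Numerical and scale choices

Problem sizes throughout the tests and drivers are chosen for a laptop-class
run: grids of roughly 20×100×100–24×120×120 voxels (30–36 µm fields), single
cells of 6–12 µm diameter, 11-frame series, cohorts of 20 cells. Quickhull
uses a tolerance of 10⁻⁹ × the cloud extent; degenerate hulls report zero
volume rather than erroring. Phase correlation regularizes the cross-power
spectrum at 10⁻¹². TIFF samples are stored as 32-bit floats normalized by a
recorded intensity scale, with voxel spacing and axis sizes in a JSON
sidecar; stacks therefore round-trip exactly at single precision.

## Known limitations

Tracing assumes protrusions thin relative to the body and roughly outward;
strongly curved or surface-hugging protrusions would fail the radiality
criterion (set `min_radiality = 0` to disable it). Lengths carry a bias of
order one voxel from the guard margin compensation and the 26-connectivity
path metric (≤ ~8% overestimate in the worst direction). Integer-voxel drift
correction leaves sub-voxel residual motion. The t-test is applied to counts
(as in the source analyses); exact tests for small counts are not provided.
Segmentation is single-cell by construction — dense tissue requires the
exclusion-mask route or upstream cropping.
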
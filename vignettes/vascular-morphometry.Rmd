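---
title: "Skeleton-graph morphometry of brain vasculature in micro-optical volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-graph morphometry of brain vasculature in micro-optical volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascmorph)
```

## The problem

Whole-brain micro-optical sectioning produces submicron image stacks in
which resin-filled vessel lumina appear brighter than the surrounding
Nissl-stained tissue, cell somata darker, and nerve processes in between.
Quantifying the vasculature in such stacks — mean diameter, length density
(m of centerline per mm³ of tissue), volume fraction, the distribution of
segment diameters, and how branch angles change with branching generation —
requires a chain of steps: artifact removal, gray-value vessel extraction,
centerline skeletonization into a node/segment graph, and group statistics.
`vascmorph` implements that chain end to end, driven by a ground-truthed
synthetic phantom generator, because the terabyte-scale source volumes of
this kind of study are not practically shareable: every stage of the
pipeline is validated against phantoms whose true geometry is known
exactly.

## The phantom generator

`phantom_spec()` + `generate_tree()` emulate the features such stacks are
described to contain: parallel, equally spaced *transverse* trunk vessels
in a rake-like arrangement; hierarchically branching daughters leaving at
divergence angles drawn from `Normal(branch_angle_mean * angle_scale,
branch_angle_sd)` clipped to (5°, 90°); and, with `comb_mode`, a comb of
short (20–60 µm), thin (< 10 µm diameter), nearly perpendicular (80–90°)
capillaries along the last trunk, emulating the capillary bed of the
dentate-gyrus molecular layer. Trunk daughters alternate sides
(dorsal/ventral), branches are *self-avoiding* (a growing branch is
truncated before touching any vessel but its parent), and each trunk's
subtree stays within its half-spacing slab so subtrees never fuse — all
three properties of real vascular trees that also keep the measured graph
faithful to the generative one.

Two group-effect dials mimic the disease-model reductions: `diameter_scale`
rescales **all** radii once (so the measured mean-diameter ratio between
two cohorts tracks the parameter directly; applying it per generation
would compound the effect with depth), and `angle_scale` shrinks the mean
divergence angle.

What the generator does *not* emulate: anastomotic loops (trees only),
nerve-process texture, amyloid pathology, flow, and the full thinness of
real capillaries at desk-scale sampling. At the default 1 µm isotropic
grid the deepest phantom generations are near the voxel size, so the
default tree (trunk radius 3.2 µm, radius decay 0.68 per generation,
3 branching generations) is roughly twice as thick as the real hippocampal
network, whose reported mean diameter is ~1.7 µm at 0.35 µm in-plane
sampling. Passing tests on these phantoms therefore demonstrates the
correctness of the measurement chain, not the biology of any particular
brain.

`rasterize()` renders the tree as a union of sphere-swept capsules
(linearly tapered radii; a voxel is vessel iff its center is within the
local radius), marks every densely sampled centerline voxel so sub-voxel
capillaries stay 26-connected, adds Poisson-placed dark soma ellipsoids
(semi-axes 3–8 µm) outside the vessels, and returns both the clean volume
and the exact truth mask. `degrade()` adds the artifact classes the
optimization stage must remove: a sinusoidal stripe field along one axis,
a smooth random staining background (white noise on a coarse grid,
trilinearly interpolated; default correlation length 64 µm — staining
inhomogeneity is region-scale, i.e. much coarser than the correction
kernels, and a field at kernel scale would be indistinguishable from
anatomy by construction), and i.i.d. Gaussian noise. Each artifact class
draws from its own seeded substream, so toggling one never changes the
others.

## The image-optimization chain

`optimize_volume()` applies, in fixed order:

1. **Stripe correction** (`correct_strips`): the mean gray profile along
   the stripe axis, minus its running-median baseline, is subtracted from
   every plane; the volume mean is preserved exactly. The running-median
   window must exceed the stripe period (3 periods + 1 sample suppresses
   ≥ 90 % of the stripe-frequency Fourier magnitude for periods 8–64
   voxels).
2. **Background flattening** (`estimate_background` +
   `correct_background`): a grayscale opening (box structuring element,
   default 75³ voxels) removes thin bright structures, a box filter
   (default 101³; a centered box filter needs odd support) smooths the
   opened image into the background reference, and the volume is
   flat-fielded subtractively (`v - bg + mean(bg)`), which preserves
   absolute vessel–background differences; a division mode exists. The
   full-scale kernels are infeasible naively, so the reference is computed
   on a block-mean-downsampled grid (default factor 4) with kernels scaled
   accordingly and trilinearly upsampled. Kernels are validated against
   the downsampled grid; desk-scale volumes use proportionally scaled
   kernels (the tests use 19³/25³ at factor 2 on 64×128×128 voxel
   volumes).
3. **Bilateral denoising** (`denoise_bilateral`): 3×3×3 kernel, spatial
   sigma 1 voxel, range sigma 10 % of the dynamic range by default.
4. **Linear contrast stretch** (`enhance_contrast`): the 0.1 and 99.9
   data percentiles (robust to hot pixels) are mapped affinely onto the
   dynamic range; a degenerate histogram is an error, never a silent
   no-op.

All filters use reflective padding. The stage order is part of the
contract and cannot be permuted.

## Extraction

Vessels are the brightest class, so extraction is plain gray-value
thresholding. `threshold_vessels(method = "otsu")` maximizes Otsu's
between-class variance over the **above-median half** of the histogram:
the stacks carry three gray populations (somata, parenchyma, vessels) of
which vessels are often ~1 %, and on the full histogram the variance
criterion settles between the two large tissue classes instead. The lower
half of the histogram holds only those tissue classes, so the restriction
reduces the problem to the two-class one Otsu's criterion solves; on
genuinely bimodal data the restriction is inconsequential. The threshold
and method are recorded in the mask's provenance. `clean_mask()` removes
26-connected components below a voxel count; `density_map()` and `mip()`
produce the volumetric-density heat maps and maximum-intensity
projections used for visualization.

## Skeletonization and morphometry

`skeletonize()` resamples the mask to isotropic spacing (smallest axis
spacing, linear interpolation, re-threshold at 0.5) and extracts
centerlines by **distance-penalized geodesic path tracing** (the
TEASAR family): starting from the deepest voxel of each component, the
farthest not-yet-covered voxel is repeatedly traced back to the skeleton
along the path minimizing a cost that strongly penalizes departure from
the medial axis, and each accepted path paints its surrounding vessel
volume as covered. Classic topological thinning was evaluated first and
rejected: on even-width tubes (medial axis between voxel centers)
sequential simple-point deletion — including the canonical
Lee-style formulation — retracts or outright annihilates the centerline,
and it shortens every terminal branch by about one radius, which makes
full-length contracts (cylinder skeleton length within 2 %) unreachable.
Path tracing yields full-length, centered lines at any voxel parity; its
one structural limitation is that anastomotic loops are reduced to trees
(irrelevant for the tree phantoms, documented for real data).

Numerical details that matter:

* Terminal paths end on the tube's end-cap **corner** (the farthest
  voxel), so each terminal segment is trimmed by one local radius and
  re-extended straight along its end tangent while still inside the mask.
* Spurs shorter than 3 µm (configurable) are pruned; pass-through nodes
  are merged.
* Local diameter = 2 × the anisotropy-aware Euclidean distance transform,
  sampled as the maximum over the 3³ neighbourhood of each centerline
  point (re-centres voxel-grid jitter). No half-voxel correction is
  subtracted: the voxelized EDT of a 3 µm rod reads ≈ 3.16 µm, so the
  raw value is the less biased estimate at these scales. Points within
  one local radius of a branch node are flagged junction-influenced and
  excluded from maximum-diameter statistics.
* **Branch levels** (`assign_branch_levels`): the root is the thickest
  segment with a free end (trunks enter the volume through an open end;
  junction-bulge stubs are excluded by a 10 µm minimum length), and at
  every node the best-aligned downstream segment (divergence < 30°)
  *continues* the parent's level — a skeletonized trunk is chopped into
  one graph piece per branch point, and counting each piece as a new
  generation would inflate levels along an unbranched vessel. All other
  downstream segments get level + 1. Because vessel taper is below
  diameter-measurement noise at coarse grids, flow orientation is checked
  against the prior that daughters branch at acute angles: if the mean
  divergence over a component is obtuse, the alternative root at the far
  end of the flow is evaluated and the more acute orientation kept.
* **Branch angles** (`branch_angles`): the divergence between the
  parent's continuation direction and the child's leaving direction,
  estimated by total-least-squares line fits over a 15 µm window that
  starts 1.5 local radii away from the node — the child's centerline only
  leaves the parent's lumen after about r_parent/sin(angle) of arc, and
  the skipped stretch would otherwise bias angles upward. The 1.5×
  multiplier was calibrated on isolated synthetic junctions at 30–60°,
  where the estimator is unbiased to within ±2°.
* `region_morphometry()` assigns each centerline step to the region of
  its midpoint, so totals over a label partition equal the whole-volume
  totals exactly. The per-segment diameter histogram uses 1 µm bins over
  0–20 µm with values above 20 µm clamped into the top bin (counts always
  sum to the number of segments). The optional isotropic shrinkage
  correction `s` multiplies lengths and diameters by 1/(1−s) and volumes
  by 1/(1−s)³ — tissue and vessel alike, so the volume fraction is
  invariant and the length density scales by (1−s)²; it is off by
  default.

One semantic caveat: `true_morphometry()` sums frustum volumes along the
generative centerlines, which double-counts the small overlap where a
daughter's mouth sits inside its parent, whereas a voxel mask measures the
union. Convergence of the rasterized volume fraction to the analytic one
is therefore checked on unbranched tubes.

## Virtual endoscopy

`mesh_vessel()` extracts the 0.5 iso-surface of the (Gaussian-smoothed)
binary field by marching tetrahedra on the Freudenthal six-tetrahedron
cube decomposition — table-free, watertight and orientation-consistent by
construction; normals are area-weighted and globally oriented outward
(positive signed volume). `normal_distance_field()` casts a ray from each
vertex along the **inward** normal (only inward rays can hit the opposite
wall of the same tube), excludes the vertex's own incident triangles and
hits closer than 0.25 µm, and records the first intersection distance —
on tubes this wall-to-wall distance approximates the local lumen
diameter (sphere of radius R → 2R; cylinder of radius r → 2r at
mid-section). No hit within the ray budget gives `NA` in memory and a −1
sentinel in the PLY export. `camera_path()` resamples a connected segment
chain, smooths it, and propagates the up vector by the double-reflection
parallel-transport method (sub-degree twist on planar arcs), flagging any
pose that leaves the lumen.

## Group comparison

`ttest_unpaired()` is the classic pooled-variance two-tailed Student
t-test (Welch available behind a flag); `compare_regions()` reports one
test per metric and region with mean ± s.e.m., and
`compare_angle_by_level()` compares per-subject mean branch angles per
level (s.d. dispersion), dropping levels with fewer than 3 branches in a
subject. **No multiple-testing correction is applied** — each test is
nominal at the study alpha (0.05 default) and families of tests should be
read accordingly. Subjects are aggregated before testing; sections are
never pooled across subjects unless explicitly configured.

`run_pipeline()` chains everything — generate, rasterize, degrade,
optimize, extract, skeletonize, measure, compare — writing per-subject
reports, comparison tables and a run manifest; identical configuration
and seeds give byte-identical reports, and `resume = TRUE` reloads
finished subjects.

## Study conditions and problem sizes

The default study compares 3 reference subjects against 3 reduced-caliber
subjects (`diameter_scale 0.8`, `angle_scale 0.75`) on 64×128×128 voxel
volumes at 1 µm — about 15 s per study on one core, chosen so that entire
replicate families run in minutes. At this scale the deepest reliably
populated branching generation is level 3; the injected angle reduction
appears there as a decrease (the full-scale analysis of real data would
extend the same comparison to deeper levels). A caveat on power: the
diameter and volume-fraction effects are recovered with the right
direction and nominal significance in *every* study seed examined,
whereas the 10° angle effect is only about one standard deviation of
between-study noise at this problem size, so a single desk-scale study
recovers its direction in roughly two out of three replicates — angle
conclusions need the replicate family, not one study. Level 2 is
*compositionally* mixed: it contains both scaled daughters and the
unscaled near-perpendicular comb capillaries, and since the thinner
reduced-caliber daughters are detected less completely, the comb's share
— and hence the level-2 mean — can move either way. Level 3 carries no
comb and is the clean probe of the angle effect. Diameter
and volume-fraction reductions are recovered with the injected direction
and nominal significance in every replicate; the diameter ratio tracks
`diameter_scale` to within a few percent.

## Known limitations

* Loops are broken: anastomoses in real capillary beds would be reduced
  to trees by the path-based skeletonizer.
* Diameters below ~2 voxels saturate at the grid limit (the EDT of a
  1-voxel-wide line reads 1), compressing group differences among the
  thinnest capillaries; angle estimates on such vessels are noisy.
* The generator's distributional choices (trunk count, daughter counts,
  lengths, taper) are stand-ins constrained only by described patterns,
  not fitted to data.
* Gray-value thresholding carries no spatial regularization; heavy noise
  must be handled by the optimization chain and component cleanup.
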
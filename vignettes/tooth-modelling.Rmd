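---
title: "Parametric tooth reconstruction and its validation loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric tooth reconstruction and its validation loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothrecon)
```

## The problem

Orthodontic treatment planning would like three-dimensional knowledge of
dental roots without the radiation cost of volumetric imaging. A panoramic
radiograph (PAN) is a routine low-dose 2D image, but it only yields a
handful of mesio-distal distances per tooth: crown equator width (EQU),
cement–enamel junction width (CEJ), root widths at half root length
(RAD, or MRAD/DRAD/PRAD per root), crown heights (C-H, or MC-H/DC-H), tooth
heights apex-to-cusp (T-H, or MT-H/DT-H/PT-H), and the furcation-to-apex
distance H-FURC for multi-rooted teeth. `toothrecon` turns such a
measurement record into a watertight 3D triangle mesh through a fixed
**shape template**: the measured values act as control parameters, and
everything the measurements do not determine (cross-section roundness,
crown depth relative to width, blend heights, inter-root spacing) is held
constant at population-plausible dimensionless ratios.

The package also implements the entire loop used to validate such models
against volumetric ground truth: repeatability statistics, unit-scale
calibration, nonparametric method comparison, threshold-calibrated
iso-surface segmentation, best-fit rigid superimposition, and signed
deviation mapping — all exercisable on synthetic data generated by the
package itself.

## Geometry kernel

Curves are polynomial B-splines (all weights 1; uniform-weight rational
splines reduce exactly to this case). Open curves use clamped knot vectors,
so they interpolate their end control points; closed curves wrap the first
`degree` control points over a periodic uniform knot vector, giving
C^(degree−1) continuity at the seam. Degree is cubic wherever at least four
control points exist, otherwise `count − 1`.

Whether the operator-picked "nodes" of a CAD spline are control points or
interpolation points is genuinely ambiguous in dental CAD practice. The
kernel supports both readings: `bspline_curve()` takes control points, and
`interpolate_bspline()` solves the global interpolation problem
(chord-length parameterisation, knot averaging, banded linear solve). The
builders use interpolation wherever a modelled feature must *hit* a
measured dimension exactly — a root profile passing through its prescribed
half-length width, for instance — because a control polygon only bounds,
and never attains, its spline.

Surfaces come in three kinds, all mapping the unit square:

* **Lofts** through ordered closed sections. `loft_sections()` interpolates
  every section at its v-level and bridges between them with a natural
  cubic spline per u. Inside the tooth builders, stacks are blended
  **piecewise-linearly** between adjacent sections instead: a global spline
  through a width sequence like CEJ → equator → rim can overshoot the
  prescribed extremum by several percent, which would silently corrupt the
  width parameters the builders must honour. Exactness at the sections was
  judged worth the loss of G2 continuity at section levels; at default
  tessellation density the kink is invisible.
* **Coons patches** bounded by four curves in loop order, with the standard
  bilinear blend. Degenerate boundary curves (a constant point) are
  allowed, which is how the incisal tip closes the crown dome.
* **Surfaces of revolution** about an arbitrary axis, u being the rotation
  fraction. Profiles may touch the axis at their ends (closed apex) but not
  cross it.

`tessellate()` evaluates an nu × nv parameter grid, welds the seam of
u-closed surfaces and collapses degenerate rows (poles) to single vertices,
so closed surfaces come out edge-manifold ("every edge shared by exactly
two faces" is the closedness predicate used throughout). Cross-section
curves are *extent-calibrated*: the template's unit section is densely
sampled once, and its control points rescaled so the dense x/y extents
equal the requested width and depth exactly — control-point scaling is
exact for B-splines, so no tolerance is consumed here.

## The two builders

Both builders work in a canonical frame: origin at the CEJ centroid, +z
occlusal, +x mesial, +y buccal. Cross sections are superellipse-like closed
interpolating B-splines through 16 layout points (exponent 1.8–2.0; rounder
for roots, squarer for crowns).

**Single-rooted (incisor class).** The root is a section stack from a tiny
apex-band section (6 % of RAD, pole-welded to the apex point at z =
−(T-H − C-H)) through the half-root section at exactly RAD, a cervical
collar, to the CEJ section at z = 0. The crown is a connection loft from
the CEJ section to the equator section (width EQU, at 32 % of C-H), topped
by a dome of four Coons patches whose meridians interpolate from the
equator rim to the incisal tip at z = C-H.

**Multi-rooted (molar class).** The crown lofts CEJ → equator (EQU) →
occlusal rim and is capped by a morph onto a thin two-cusp ridge whose
height profile attains MC-H and DC-H exactly at ±30 % of EQU, with a
central fissure between them; the profile uses cosine-eased monotone
segments between knots, so the cusp knots are exact maxima (an ordinary
spline would overshoot them). The occlusal slit is closed by a fan dipped
to the fissure level — a fan at the ring centroid would sit at the *mean*
ridge height and could overtop the lower cusp. The root trunk lofts from
the CEJ section down to the furcation plane, where the trunk ring is cut
into sector loops through its centroid (two sectors, or three when a
palatal root is specified). Adjacent loops share their septum edges, so
the branch point is watertight by construction — a deliberate alternative
to boolean unions, which would have required a CSG kernel and can produce
non-manifold output. Each root then descends through circular sections
(morphing smoothly out of its sector loop) with a revolution-style radius
profile that passes through MRAD/2 (resp. DRAD/2, PRAD/2) exactly at half
root length, to a pole-welded apex at its own tooth height. The furcation
sits H-FURC above the *shorter* of the mesial/distal root apexes; when
H-FURC is not measured it defaults to 60 % of the shorter root length.

Two small anatomical liberties are load-bearing. First, a cervical collar
4 % wider than CEJ sits just below the cervix, making the CEJ plane a true
local minimum of the width-vs-height profile (the cervical waist). Real
teeth do show a cervical constriction; a strictly monotone taper would
leave the CEJ unrecoverable from mesio-distal widths alone. Second, crowns
are deliberately smooth — no cuspal detail beyond the two molar cusps —
because the crown of such a model is expected to be replaced by an optical
scan in any downstream use; the root is the part that matters.

The headline contract, enforced by a property test over randomised
parameter sets, is **parameter faithfulness**: re-measuring a built mesh
recovers every control parameter within max(2 %, 0.1 mm).

## Mesh metrology

`measure_mesh()` inverts the builders using only operations a panoramic
projection could justify: widths are mesio-distal (x) extents of
horizontal slices (200 levels, with a small irrational offset so slice
planes never coincide with tessellation rings); heights are axial extents.
EQU is the widest crown slice. The CEJ plane is found as the first local
width minimum walking *down* from the equator plane — the cervical waist —
refined on a fine local grid; if no waist exists (a cylinder, say), the
narrowest slice of the middle third is used as a fallback. A
narrowest-middle-third rule alone was rejected: for a monotonically
tapering tooth the narrowest middle-third slice is the apical end of that
window, nowhere near the cervix. The furcation is the highest z at which
the cross-section splits into ≥ 2 contours (contours are connected
components of the slice polyline, linked through shared faces), refined by
bisection to ~10⁻³ mm; root contours are labelled mesial/distal/palatal by
centroid direction, and each root's apex is the lowest mesh vertex near its
lowest labelled contour. Requesting molar measurement of a single-rooted
mesh raises a furcation-not-found error rather than guessing.

## Statistics

`dahlberg_error()` implements the classical repeatability estimate
S_D = √(Σ dᵢ² / 2n) over replicate pairs; it estimates the per-measurement
error SD, which the Monte-Carlo test confirms (injected σ = 0.4 recovered
within ±0.05 at 500 pairs). `estimate_scale()` fits the multiplicative
factor minimising Σ(ref − s·target)² in closed form; it is exact on
proportional data and direction-agnostic (the caller decides which series
is the reference). `compare_methods()` runs the nonparametric battery a
method-agreement study would: Shapiro–Wilk per method and per paired
difference, paired Wilcoxon signed-rank per method pair — overall, per
dental arch, and per tooth group derived from FDI numbers — and
Kruskal–Wallis omnibus tests across methods and across tooth groups of the
paired differences. Test internals delegate to the standard implementations
in base R; the module's contract is the protocol's structure. Raw p-values
are reported without multiplicity correction, mirroring common practice in
agreement studies (noted, not endorsed). All-zero difference vectors
return p = 1 with a `degenerate` flag, since the exact signed-rank test is
undefined there and identical methods should read as "no difference";
strata with fewer than two pairs are flagged `insufficient data` rather
than crashing.

## Segmentation

Scalar volumes are axis-aligned grids with uniform per-axis spacing (the
NRRD reader/writer covers raw little-endian and ascii encodings; DICOM is
out of scope at desk scale). Iso-surfaces are extracted by **marching
tetrahedra** over the Kuhn six-tetrahedron cube decomposition with linear
interpolation along cell edges. This was chosen over table-driven marching
cubes deliberately: the tetrahedral decomposition has no ambiguous
configurations, is consistent across neighbouring cells, and with
edge-keyed vertex welding yields watertight meshes by construction, at the
same linear-interpolation accuracy class (grid values equal to the
iso-level are nudged by 10⁻¹⁰ of the data range to avoid degenerate
zero-area output). On signed-distance test volumes the extracted surface
sits within half a voxel of the analytic level set.

`calibrate_threshold()` emulates reference-guided threshold selection: for
each candidate level the iso-surface is extracted, best-fit aligned to the
reference mesh, and scored by the mean absolute vertex-to-reference
distance; the calibrated threshold is the arg-min over the user-supplied
grid (no derivative-based search — the objective is cheap and possibly
non-smooth). Because alignment absorbs rigid misplacement, the objective
depends on shape only; a Gaussian-blurred binary occupancy recovers its
half-level (symmetric blur preserves the 0.5 surface), and inflating the
reference pushes the calibrated level down, as the level-offset relation
predicts.

## Registration and deviation mapping

`best_fit_align()` is point-to-surface ICP: a deterministic evenly-spaced
subsample of moving vertices (default 1000) is matched to closest points on
the fixed surface (exact point-to-triangle distance, compiled), the optimal
rigid motion is solved in closed form (SVD/Kabsch), and the loop repeats
until the correspondence RMS changes by less than 10⁻⁶ mm or 200
iterations. The correspondence RMS is non-increasing across iterations and
is asserted as such in the tests. Initialisation aligns centroids and
principal axes, scoring all four proper axis-sign combinations plus a
centroid-only candidate on a 200-point probe and keeping the best, so
near-identity poses are never flipped. An optional trim fraction discards
the worst correspondences for partial-overlap robustness (default 0).
Collinear point sets are rejected. One caveat surfaced by testing: the
idealised template tooth is exactly centrally symmetric about its long
axis, so pose recovery on an *unmodified* template is only well-defined up
to a half-turn; registration fixtures therefore carry a smooth
symmetry-breaking warp. Real anatomy is asymmetric and unaffected.

`signed_distance_map()` assigns each parametric vertex its distance to the
segmented surface, signed by a ray-parity inside test against the closed
segmented mesh: **positive = parametric excess (outside, warm colours),
negative = parametric lack (inside, cold colours)**. The map is one-sided
(parametric → segmented), matching how a dimensional-comparison colour map
is read; a symmetric Hausdorff-style measure was considered and rejected
as it has no per-vertex rendering. `deviation_report()` partitions
vertices into apex band (apical 15 % of the axial extent), CEJ band (±1 mm
about the cervical plane), crown, and root body, and summarises |d| and
signed extremes per region; the bands partition the vertex set exactly,
and empty regions report n = 0.

## The synthetic patient

`generate_patient()` fabricates everything the validation loop consumes,
fully determined by one seed through named substreams (anatomy, per-tooth
mesh fields, per-method tables), so components are independently
reproducible and regeneration is bit-identical. Per tooth, the base roster
dimensions are scaled by one global anatomical size factor
(N(1, 0.04), clamped at ±2σ) — a homogeneous factor preserves every
parameter invariant by construction. The defaults are the package's
standing study conditions:

| setting | default | rationale |
|---|---|---|
| landmark noise sd | 0.35 mm | reference-point identification error of panoramic measurements reported around 0.4–0.6 mm; keeps every method's Dahlberg error well under 1 mm |
| PAN magnification | ×1.15 heights, ×1.05 widths | vertical magnification is the dominant panoramic distortion, cited up to 17–27 % in the worst regions; defaults sit inside that envelope |
| CBCT unit scale | 1/0.313854 device units per mm | emulates volumetric data recorded in device units, recovered at run time by `estimate_scale()` against in-vivo crown measures |
| mesh perturbation | 0.3 mm RMS, 8 mm wavelength | segmentation-scale shape error; a sum of six seeded harmonics rescaled to the exact RMS, smooth enough to preserve closedness |
| replicates | 2 | the minimum that feeds Dahlberg's formula |
| voxel size | 0.4 mm, blur σ = 1 voxel | CBCT-like sampling at desk-scale volumes |

"Segmented" meshes are the ground truth warped by the smooth displacement
field; volumes are blurred binary occupancies of the segmented meshes;
in-vivo tables contain crown measures only (no root measures can be taken
in the mouth).

What the generator does **not** emulate: beam hardening, scatter or metal
artifacts; panoramic image formation (only measurement-level magnification
and noise); root curvature or dilaceration; per-patient crown morphology;
tooth rotation or crowding. Passing tests therefore demonstrate the
internal consistency and calibration of the tool chain under measurement
noise, magnification and smooth shape error — not robustness to pathology
or to the projection geometry of real panoramic devices.

## The pipeline, and the problem sizes used

`run_pipeline()` chains the stages: simulate → Dahlberg per method (on the
millimetre scale) → CBCT unit calibration (in-vivo crown measures vs CBCT)
→ PAN magnification calibration (heights and widths separately, against
calibrated CBCT) → method comparison → parametric rebuild from calibrated
PAN replicate means (with gentle clamping of order invariants that noise
can violate) → threshold calibration → best-fit superimposition → signed
deviation report. The command-line launcher in `inst/scripts/toothrecon`
exposes each stage as a subcommand writing STL/PLY, NRRD, CSV and JSON
artifacts with sidecar metadata.

Validation runs use deliberately desk-scale sizes, chosen as the package's
own operating points: tessellation at 32–64 points per section ring,
parameter-recovery sweeps of 50 random records per class, 20 random rigid
motions for registration, 500 replicate pairs for the Dahlberg
Monte-Carlo, 1000 simulation replicates for the protocol's type-I error,
0.4–0.5 mm voxels for volumes, and nine-level threshold grids.

## Known limitations

Cross-section shape, crown depth and all other template ratios are fixed
constants, not fitted quantities; the two builders cover an incisor-like
and a molar-like class only (premolars and canines are approximated by the
single-rooted class in the synthetic roster); lofted blends are only C0 at
section levels; the deviation map is one-sided; the statistics module
implements the comparison protocol as specified, without multiplicity
control; and none of the synthetic results speak to patients with
displaced, rotated or malformed teeth.
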
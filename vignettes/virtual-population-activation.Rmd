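---
title: "Ventricular activation in a virtual population: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventricular activation in a virtual population: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

PurkinjeFT simulates the electrical activation sequence of the human
ventricles across a virtual population of anatomies, with three anatomical
ingredients that are usually left out of activation models: papillary
muscles (PMs), an algorithmically grown Purkinje (PK) network that respects
them, and an optional false tendon (FT) — a fast-conducting band crossing
the left-ventricular cavity from the left bundle branch to a papillary
muscle or the free wall. Its purpose is to quantify how such a tendon
changes the QRS duration when the left bundle branch is blocked (LBBB).
This vignette documents the models, the tunable parameters, the numerical
choices and the known limitations; the README shows a worked example.

## 1. The synthetic shape model

Virtual anatomies come from a point-distribution model
$x = \bar{x} + P^{\top} b$: a mean shape of $n \approx 5\,000$ 3-D
landmarks, $t = 10$ orthonormal deformation modes (rows of $P$) and
per-mode variances $\lambda_1 \ge \dots \ge \lambda_t$. Population samples
draw $b_i \sim N(0, \lambda_i)$ truncated at $\pm 3\sqrt{\lambda_i}$ (a
uniform-in-bounds alternative is available; the bound can also be read as
$\pm 3\lambda_i$ via `boundType = "lambda"`).

The atlases on which such models are usually built are patient-derived and
not redistributable, so the mean shape here is parametric: the LV wall is
the region between two coaxial truncated prolate ellipsoids (endocardial
semi-axes 27/70 mm, wall thickness 10 mm, base plane at the mitral level),
and the RV is a crescent-section chamber wrapped around one side of the LV
(half-span 70 degrees about the septal azimuth, maximal cavity depth 22 mm,
free wall about 4 mm); the shared wall is the septum. These dimensions are
literature-typical and put the mean apex-to-mitral-centre LV length at
exactly 98.0 mm; mode 1 (global scale) is calibrated so that one standard
deviation of its weight changes the LV length by 8.5 mm. The remaining
modes are smooth analytic deformation fields — long-axis elongation, wall
thickness, septal curvature, apical sharpness, basal dilation, RV volume,
eccentricity, anterior–posterior skew, torsion — orthonormalized by
Gram–Schmidt; the combination matrix is stored so the same modes can be
evaluated at volume-mesh nodes, keeping surface and volume geometry exactly
consistent for any sample.

One geometric consequence of wrapping the RV onto the LV with vanishing
wall thickness at the insertion lines is a *pinch seam*: the triangulated
surface is watertight and 2-manifold within each anatomical region, but a
few edges along the seam are shared by four triangles. All downstream
algorithms (volume meshing, activation solves) are built to handle this.

## 2. Papillary muscles

Each LV has one anterior (APM) and one posterior (PPM) papillary muscle.
A PM is a cylinder making up 60% of its length $L$, capped by the
paraboloid $z(r) = L - 4\cdot 0.4\,L\,r^2/d^2$. Its parameters are drawn
from published per-patient statistics: normalized length
($33.6 \pm 5.3$ APM, $27.6 \pm 5.5$ PPM, percent of LV length), normalized
diameter ($8.9 \pm 1.7$, $8.3 \pm 1.9$), tip–attachment azimuth about the
LV axis ($19.9 \pm 6.3$ and $27.8 \pm 12.2$ degrees) and tip distance from
the LV axis ($24.1 \pm 3.1$ and $21.7 \pm 3.8$ mm). Draws are truncated at
three standard deviations; infeasible placements on extreme shapes (a tip
that would cross the opposite wall) are redrawn. The azimuth is honoured
exactly; the tip distance is a soft target (within 10%) because both
cannot always be met on arbitrary shapes. The published tables state the
tip distance both relative to the LV axis and to the wall; it is
implemented as the distance from the axis.

On the surface, the PM is merged by removing the endocardial triangles in
the attachment footprint and stitching the PM base ring to the hole
boundary (watertightness is preserved; the enclosed cavity volume drops by
the analytic PM volume to within a few percent). In the volume mesh the PM
is a structured block of disc stations whose base nodes snap onto
endocardial mesh vertices, so conduction between wall and PM needs no
special treatment.

## 3. Tetrahedral meshing

Because every surface produced by the shape model knows its parametric
provenance, the wall is meshed by structured extrusion: a
$\theta \times u$ grid with four transmural layers for the LV (three for
the RV shell), hexahedra fanned into six tetrahedra around a main diagonal
(conformal across neighbouring cells), deformed by the sample's mode
weights evaluated analytically at every node. The default density targets
approximately 70 000 vertices and scales linearly with `targetVertices`.
The transmural coordinate $e \in [0,1]$ is exact by construction (layer
parameter), which is the quantity the usual endo/epi distance ratio
approximates. Generic closed surfaces without provenance (e.g. a test
cube) are meshed with a star-shaped "onion layer" scheme — scaled copies of
the boundary toward the centroid — which reproduces the enclosed volume of
star-shaped domains exactly.

## 4. Fiber orientation

The rule-based (Streeter-type) model: helix angle linear in the transmural
coordinate, $\alpha(e) = \alpha_\mathrm{endo} + e\,(\alpha_\mathrm{epi} -
\alpha_\mathrm{endo})$ with the classic $+60^\circ/-60^\circ$ defaults
(configurable), applied in the local circumferential–longitudinal tangent
frame obtained by central differences of the structured grid. PM vertices
are aligned to the PM long axis. Per-tet directions are sign-aligned
normalized means of the four vertex directions; the field is equivariant
under rigid rotations of the mesh.

## 5. The three-stage Purkinje L-system

Stage 1 is landmark-driven. In the LV, a bundle fiber runs from the His
origin (upper septal endocardium) toward the apex along the septum; at two
thirds of the geodesic arc length it trifurcates into fascicles toward the
PPM, the APM and the apex; after reaching its landmark each fascicle turns
toward the base and stops 20 mm short of the basal plane. Fascicles run
beneath the PMs on the retained endocardial sheet. The apical fascicle's
base-ward azimuth is degenerate at the apex; it continues up the lateral
free wall. Paths are shortest paths on the endocardial vertex graph,
smoothed by two rounds of on-surface Laplacian smoothing. In the RV the
bundle runs from the AV node toward the RV apex on the septal RV
endocardium and splits in two (apex; crossing to the free wall).

Stages 2 and 3 are rule-based Y-branching with per-stage Gaussian
parameters: LV stage 2 branches of $6 \pm 0.3$ mm at $60 \pm 40$ degrees
(10 segments, at most 300 branches), RV stage 2 $4 \pm 0.3$ mm at
$60 \pm 20$ degrees (at most 800), stage 3 in both ventricles
$1 \pm 0.03$ mm over 5 segments (at most 600/1000). Branch lengths are
truncated at three standard deviations (kept positive); branch angles are
drawn untruncated — a negative draw simply swaps the handedness of the
Y-split — so the sample moments of both match the nominal table values.
Growing LV tips terminate early within the avoidance radius (1 mm) of a
foreign fibre or fuse into a loop within the capture radius (0.5 mm); RV
fibres do not avoid each other; stage 3 creates no loops and its terminals
(and all stage-2 terminals) become Purkinje–muscle junctions (PMJs).
Stage-3 seeds are random points of the peripheral network, stratified over
the AHA 17 segments proportionally to segment endocardial area. The
proximal bundles (His-to-trifurcation, AV-to-split) are insulated
conduction tissue: they carry no PMJ seeds, are not fusion targets, and a
direct FT termination never connects to them. Each growth step projects
onto the tangent plane of the nearest endocardial vertex and is clamped to
a small multiple of the surface sampling distance, which keeps fibres on
the (open-rimmed) endocardial sheet.

## 6. False tendons and bundle branch block

The FT is a straight free-running chord of 20 segments from a configurable
take-off on the left bundle (default: arc-length midpoint) to the APM tip,
the PPM tip or a ventricular free-wall point (default: mid-height lateral
wall), at the Purkinje velocity and with no junction delay at the bundle.
A *direct* termination adds one segment to the closest peripheral Purkinje
node; a *delta* termination grows a ten-branch tree (segment length
$0.2 \pm 0.1$ mm truncated symmetrically to stay positive, branching angle
$60 \pm 1$ degrees) that never joins the main network — its terminals are
PMJs with the standard antegrade delay. Chords that would leave the cavity
are rerouted through one interior waypoint.

A complete LBBB sets `blocked = TRUE` on the left-bundle edge immediately
distal to the FT take-off (immediately distal to the His origin when no FT
is present); blocked edges carry infinite travel time in both directions.
The FT, originating proximal to the block, is unaffected.

## 7. Activation solves and coupling

The one-dimensional network problem is an exact shortest-time solve
(travel time length/velocity per edge; super-source Dijkstra). The
myocardium solves the anisotropic Eikonal equation
$\sqrt{\nabla\varphi^{\top} D\, \nabla\varphi} = 1$ with the per-tet tensor
$D$ having squared speeds $(v_L^2, v_T^2, v_T^2)$ along the averaged fiber
frame; defaults $v_L = 0.8$, $v_T = 0.3$ and $v_{PK} = 3.5$ mm/ms. The
solver is a fast-iterative (active-list, label-correcting) scheme whose
local update minimizes $t(y) + \lVert x - y \rVert_{D^{-1}}$ exactly over
each opposite face (interior KKT quadratic, edges, vertices); it converges
to the same viscosity solution a fast-marching method approximates and is
robust on unstructured anisotropic meshes where a plain heap can violate
causality. Iteration stops when no vertex improves by more than the solver
tolerance ($10^{-6}$ ms).

The two domains are coupled at the PMJs with asymmetric delays: network to
muscle 6 ms, muscle to network 1 ms, iterated to a fixed point (tolerance
0.01 ms, at most 20 sweeps; in practice 3–5). Source times are
non-increasing across sweeps, so each myocardial re-solve warm-starts from
the previous map (a valid upper bound), which roughly triples throughput
without changing the result. Retrograde re-entry — the septal wavefront
re-exciting the distal left network through its PMJs under LBBB — emerges
from this fixed point and is what keeps the LBBB prolongation at the
plausible ~25–30 ms rather than doubling the QRS.

Numerical conventions: mm, ms and mm/ms throughout (numerically equal to
m/s); degenerate tetrahedra (volume below $10^{-9}$ mm$^3$) are rejected;
unreachable vertices carry $+\infty$ and make QRS evaluation fail loudly.

## 8. Metrics and experiments

QRS duration is the last minus the first *myocardial* activation (network
nodes carry negligible charge and are excluded). The LV/RV split fits a
plane through the mid-septal vertices by least squares — automated rather
than manual for reproducibility across hundreds of runs; PM vertices are
always LV. Synchrony metrics report first/last/total activation per side
and the absolute difference of the last activations. Threshold statistics
use a strict inequality at 120 ms; quantiles are linear-interpolation
(type 7); the two-sample Kolmogorov–Smirnov test is the standard
asymptotic one.

`runMainPopulation()` runs, per heart, one healthy solve, one LBBB solve
and six LBBB + FT solves (APM/PPM/VFW × direct/delta) on the same mesh and
base network, and reports per-heart QRS reductions against the matched
LBBB run. One Purkinje realization is used per heart; network-topology
variance is characterized separately by `runPkSensitivity()` (25
independently seeded networks on one fixed heart). `runP1P2P3()` scales
shapes over a size grid (default 70–88 mm in 2 mm steps — ten sizes, which
makes the stated 4 × 10 = 40 hearts consistent; the grid is configurable to
70–90 mm), rescales the whole population to a fixed length, and varies the
VFW attachment point randomly (50 locations per shape at full scale).

## 9. Problem sizes

Full scale means 70 hearts at ~70 000 vertices. The package's reduced
standard conditions, used by `scripts/acceptance.R`, are 15 hearts and 25
network realizations at ~40 000 vertices; the test suite uses 10 hearts at
~15 000 vertices and one shared 15 000-vertex heart for the structural
suites. QRS levels shift by only a few ms between 15 000 and 70 000
vertices, so the reduced conditions preserve the contrasts the study is
about.

## 10. What the generator does and does not emulate

The synthetic population reproduces the *printed statistics* of the source
anatomy — mean LV length and spread, PM dimensional statistics, conduction
parameters — but not patient-specific shapes: no trabeculation, valves,
outflow tracts, regional wall-thickness maps or shape covariances beyond
the ten analytic modes. Consequences observed in the package's own runs:

* Relative effects are faithful: LBBB prolongs the QRS in essentially
  every heart (by ~25–30 ms on average), a false tendon under LBBB
  shortens it (by ~20 ms pooled, more for direct than for delta
  terminations), and the first-LV-activation delay under LBBB is ~11 ms.
* Absolute QRS levels run some 8–15% below the reference values (healthy
  ~95–100 ms rather than ~108 ms), because the parametric anatomy gives
  the network slightly more homogeneous endocardial coverage than a
  CT-derived one. Threshold *proportions* at the absolute 120 ms cutoff
  inherit this shift and under-count relative to the reference.
* The latest-activated tissue often sits in the PMJ-free basal band (both
  stage-1 margins meet there), on either side of the heart; which side
  "wins" can differ from the reference anatomy, so the ordering of mean
  QRS between the three *direct* FT endpoints is within a millimetre-scale
  margin rather than clearly VFW-first.
* On healthy hearts a VFW tendon can shorten the QRS by slightly more than
  the reference's "barely affected" (up to ~10 ms on some shapes), again a
  coverage effect.

These deviations are documented rather than recalibrated away: every
anatomical default above was fixed before the simulations were run, and
the acceptance checks report the model as it is.

## 11. Known limitations

Activation only: no membrane kinetics, repolarization or surface ECG; QRS
duration here is the endocardial-to-epicardial activation span, which can
differ from an ECG-derived QRS. One FT per heart; fibromuscular (slow) FT
tissue is not modelled. The RV pinch seam makes a short strip of the
surface non-manifold (watertight nonetheless). The basal plane truncates
the anatomy at the valve level with a flat cap.
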
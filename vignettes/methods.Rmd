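---
title: "Estimating tibiofemoral contact stress: registration, DEA and reliability methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tibiofemoral contact stress: registration, DEA and reliability methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneedea)
```

## The problem

Articular contact stress is a direct mechanical exposure implicated in the
development of knee osteoarthritis, but estimating it per subject in an
epidemiological cohort requires a pipeline that is fast, scriptable and —
above all — reliable across operators and sessions. `kneedea` implements
such a pipeline in three stages:

1. **3D-to-2D registration.** Bone surfaces segmented from MRI (triangulated
   femur and tibia meshes, mm units) are brought into their weight-bearing
   apposition by aligning their ray-cast silhouettes with bone edges traced
   on a standing posterior-anterior fixed-flexion radiograph.
2. **Discrete element analysis (DEA).** With the bones posed, contact
   stress is computed by treating the subchondral bone as rigid and the
   combined tibiofemoral cartilage as a bed of independent compressive-only
   springs, loaded vertically to equilibrium.
3. **Reliability statistics.** Peak and mean contact stress per compartment,
   collected over raters and sessions, are summarised with Shrout-Fleiss
   ICC(2,1) and Bland-Altman agreement.

Because the cohort imaging this pipeline targets is not redistributable, the
package carries a first-class synthetic phantom module that exercises every
stage with known ground truth.

## The virtual radiographic scene

The scene reproduces a standing-knee acquisition protocol: a point source at
a source-detector distance of 72 in = 1828.8 mm exactly, with the central
beam tilted caudally by 5, 10 or 15 degrees. In scene coordinates the
detector occupies the plane $z = 0$ with in-plane axes $u$ (horizontal) and
$v$ (vertical), and the source sits at $(0, 0, \mathrm{SDD})$; the caudal
angle is realised by tilting the central axis about the detector's
horizontal axis while preserving the source-detector distance (the protocol
fixes the distance and the angle, not the mechanical realisation, so this
is the package's choice). A point at object-to-detector distance $d$ is
therefore magnified by $\mathrm{SDD}/(\mathrm{SDD}-d)$; the knee is placed
at a nominal 100 mm from the detector.

The detector raster defaults to 0.2 mm pixels on a 896 x 1024 grid — fine
enough that rasterisation error (half a pixel, 0.1 mm) is small against the
0.5 mm registration accuracy target, and large enough to hold a whole
phantom knee with margin for a perturbed initialisation.

## Silhouette cost

A mesh edge belongs to the silhouette when its two adjacent faces face
opposite ways from the source (sign change of
$n_f \cdot (c_f - s)$); boundary edges always do. Silhouette edges are
projected through the source onto the detector plane and connected with
Bresenham segments into a binary contour, exactly as the radiograph edge
tracings are represented.

The alignment cost between a projected model contour $M$ and a traced edge
image $R$ is the symmetric mean chamfer distance

$$ C(M, R) = \tfrac12\Big( \overline{D_R}(M) + \overline{D_M}(R) \Big), $$

where $\overline{D_R}(M)$ is the mean over foreground pixels of $M$ of the
exact Euclidean distance transform of $R$, converted to mm. The cost is
zero iff the two pixel sets coincide, symmetric by construction, and decays
smoothly as contours approach — the standard silhouette-matching choice.
Averaging (rather than summing) the two one-way terms keeps the unit
interpretable: a rigid one-pixel offset costs one pixel spacing. Projected
pixels that fall outside the raster are clamped to the border and charged
their overshoot distance, which pulls badly initialised poses back into the
field of view; a silhouette entirely outside the raster has no alignment
signal and is treated as infeasible.

## Registration

The pose is a 6-vector: translations $(t_x, t_y, t_z)$ in mm and intrinsic
z-y-x Euler rotations in degrees, applied about the moving bone's centroid
at optimisation start. Centroid-centred rotations keep rotation and
translation search directions decorrelated; the Euler convention is fixed
by this package (the source methodology does not state one).

The cost landscape is highly nonconvex (silhouettes are invariant to small
out-of-plane motions and can lock onto wrong limbs of the contour), so the
minimiser is a covariance matrix adaptation evolution strategy (CMA-ES)
with a population of 70 candidate alignments per generation and a budget of
8000 cost evaluations per run; three independently seeded runs are executed
and the lowest-cost run wins, ties broken by run order. The CMA-ES is the
canonical strategy — rank-mu covariance update with a rank-1 evolution-path
term and cumulative step-size adaptation — implemented in the package with
a seeded RNG so a run is bit-reproducible. Two further choices the protocol
leaves open: initial search scales are 5 mm for the in-plane translations,
10 mm out-of-plane (depth is only weakly observed through magnification,
so it deserves a wider prior) and 3 degrees per rotation; runs stop early
when the best cost improves by less than 1 part in 10^8 over 20
generations.

The femur is aligned first. Its best transform is then applied to the tibia
as the initial pose — the bones travel together — and the tibial cost adds
a proximity penalty $w \cdot \max(0, g - g_0)$ on the minimum tibiofemoral
surface distance $g$, with threshold $g_0 = 6$ mm (the combined cartilage
thickness) and weight $w = 1$ per mm. The penalty's functional form and
weight are this package's choices; it is zero whenever the bones stay
within a cartilage-thickness of each other and simply forbids the tibia
drifting away along the depth axis the silhouette cannot see.

Out-of-plane translation error is expected to exceed in-plane error for a
single projection; the tests therefore bound only the in-plane components
and record the depth error without a bound.

## Discrete element analysis

Bones are rigid; the combined cartilage is a uniform layer of thickness
$t = 6$ mm with elastic modulus $E = 12$ MPa and Poisson's ratio
$\nu = 0.42$. Each tibial facet is paired with its nearest femoral facet
within a search radius ($2t$ by default) using a uniform spatial grid that
returns results identical to exhaustive search. The intersurface
separation $s$ is measured along the tibial facet normal to the paired
femoral facet's plane — accepted only where that ray actually meets the
facet's extent (with a half-facet barycentric margin), so a facet cannot
"shadow" space beyond its own boundary — and pairs whose normals do not
oppose (side walls) carry no spring. The spring deformation is
compressive-only, $d = \max(0, t - s)$, and stress follows the
confined-compression (Winkler) law

$$ \sigma = \frac{E(1-\nu)}{(1+\nu)(1-2\nu)} \cdot \frac{d}{t}, $$

whose coefficient at the default properties is 30.63 MPa. The stress law is
pluggable in `solve_equilibrium()` should a different cartilage model be
wanted.

Loading is load-controlled: a 1000 N vertical force, with only the femur's
vertical translation iterated (bracketing plus bisection on the vertical
contact-force balance) until the net vertical spring force matches the
applied load within 0.5% (5 N). A single translational degree of freedom
matches the single prescribed vertical load, keeps the solve deterministic,
and converges in a few dozen bisection steps because the force-displacement
relation of a spring bed is monotone. The solver refuses configurations
that cannot reach contact within a 10 mm travel bound or that fail to
balance within 100 iterations — on very coarse meshes the force jump from a
single facet engaging can exceed the 5 N tolerance, which is a genuine
resolution failure and is reported as such rather than silently accepted.

Compartment metrics split tibial facets by the sign of their centroid
coordinate along the medial-lateral axis relative to the tibial surface
centroid (a configurable sagittal midline). Peak stress is the facet
maximum; mean stress is the area-weighted mean over facets *in contact* —
averaging over the whole compartment would dilute the value by however far
the segmentation happened to extend.

Verification anchors the solver to closed forms: a rigid flat punch on a
flat bed must carry exactly load/area everywhere; a rigid sphere of radius
$R$ on a flat spring bed must reach the Winkler peak pressure
$p_0 = \sqrt{kP/(\pi R)}$ with foundation modulus $k$ = aggregate modulus
over thickness (6.374 MPa at the defaults, matched by the solver to under
1% at fine mesh, with error decreasing under refinement).

## The synthetic phantom

The phantom generates every input the pipeline needs with known ground
truth. The femur is two spherical condyles of unequal radii (40 and 36 mm
by default, so left and right are distinguishable in silhouette) bridged by
a shaft stub; the tibia is a plateau slab carrying two concave spherical
sockets concentric with the condyles in the assembled pose, each 0.5 mm
larger in radius than its condyle and truncated at a 15 mm rim. Outside the
rims the plateau drops well below the condyles, so contact is rim-limited
for any cartilage thickness up to 8 mm. The assembled configuration is the
ground-truth pose (identity), with a uniform 0.5 mm radial clearance in
each socket.

Mesh resolution is a convergence parameter, not a physical one: condyle
icospheres at subdivision level 3 (about 2,500 femoral facets) suffice for
silhouette work, where facet chord error only perturbs the contour by a
fraction of a pixel. Contact stress is far more demanding — the spring
deformations at equilibrium are a few tenths of a millimetre, comparable to
the chord sag of a coarse sphere mesh — so the conforming phantom used for
DEA sensitivity work refines the femoral spheres two levels further
(subdivision 5, chord sag below 0.01 mm), at which point the peak-stress
thickness sensitivity agrees with a continuum force-balance estimate of the
same geometry to about a percentage point.

Radiograph edge images are rendered by the pipeline's own projector at the
ground-truth pose, which guarantees zero model-image mismatch at truth —
registration tests therefore measure optimizer recovery, not forward-model
error. What passing them does *not* show: robustness to segmentation bias,
to tracing errors on real radiographs, or to anatomy that differs from
spheres-in-sockets; those effects are emulated only coarsely by
`perturb_segmentation()` (smooth correlated normal displacement fields with
a prescribed RMS amplitude) and by the ratings simulator, which draws from
the exact two-way random-effects model the ICC assumes.

## Reliability statistics

ICC(2,1) — two-way random-effects, absolute agreement, single score — is
computed from the ANOVA mean squares of a targets-by-columns matrix:

$$ \mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}. $$

A constant matrix has no defined ICC and raises an error rather than
returning a sentinel (silent sentinels corrupt batch reports); rows with
missing cells are dropped listwise with a logged count. The study design
collapses a 3-rater x 2-day layout into single ICCs as follows (the source
design does not prescribe the collapse, so this is the package's recorded
convention, configurable by subsetting the input): day-to-day reliability
uses the two days as columns with knee-rater combinations stacked as
targets; interrater reliability uses the raters as columns with day-1
values. Bland-Altman summaries use limits at exactly plus/minus 2 standard
deviations of the paired differences, and pairs containing a zero (no
contact stress in that compartment) are omitted and counted.

## Problem sizes and numerical choices

The validation experiments the package ships run at these sizes, chosen as
the smallest at which each quantity is mesh- or sample-converged:

* Registration recovery: default asymmetric phantom (refinement 3, ~2,500
  femoral facets), 0.2 mm pixels, 10 seeded repetitions of best-of-3
  CMA-ES runs (popsize 70, up to 8000 evaluations each).
* Thickness sensitivity: conforming phantom, ~33,500 tibial facets,
  femoral subdivision 5; three equilibrium solves (t = 4, 6, 8 mm).
* Winkler benchmark: subdivision-4 sphere on a 0.75 mm plate grid.
* ICC recovery: 200 simulated studies of 30 knees per population value.

Other numerical choices collected in one place: duplicate vertices merge at
1e-6 mm on load and faces under 1e-12 mm^2 are dropped (they carry no load
and break normal computation); the equilibrium bracket steps at 0.5 mm
before bisection; pairing ties break to the lowest facet index so grid and
exhaustive search agree exactly; and every stochastic component (CMA-ES,
phantom perturbations, ratings simulation) takes an explicit integer seed
and restores the caller's RNG state.

## Known limitations

* Uniform cartilage thickness: subject-specific thickness maps are out of
  scope by design; the thickness-sensitivity experiment quantifies how much
  the peak stress cares (<10% over 4-8 mm on conforming geometry).
* A single static load case; no shear or friction springs; no
  biphasic/viscoelastic cartilage.
* Registration uses one projection: depth is recovered only through
  magnification and is the least reliable pose component.
* The phantom is spheres-in-sockets, not anatomy: it validates the
  machinery, not anatomical generalisation.
* Edge tracings are consumed as given binary rasters; detecting bone edges
  on raw radiographs is an interactive step outside the package.
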
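---
title: "Landmark-based scala tympani trajectory planning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based scala tympani trajectory planning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Atraumatic cochlear implantation requires the electrode array to be placed
in the scala tympani (ST) and to enter it along a direction aligned with the
mid-scala course of the basal turn, so that neither the basilar membrane nor
the modiolus is hit during insertion. Clinical CT resolution does not show
the basilar membrane or the ST lumen directly, so the planning problem is:
given only a segmented surface model of the bony labyrinth and a handful of
anatomical landmarks that *are* reliably identifiable, compute the ST
centerline in the basal turn, derive ideal insertion trajectories tangent to
it, and locate the corresponding cochleostomy targets on the bony surface.

`cochleoplan` implements that pipeline, the evaluation metrics used around
it in image-guided surgery (alignment angles, fiducial registration, target
error, membrane plane-approximation error, angular insertion depth), and a
synthetic phantom generator with analytic ground truth so that every stage
is testable without clinical data.

## The local cochlear coordinate system

Four landmarks define the frame (`build_cochlear_frame()`):

* `C` — basal center of the modiolus: the origin.
* `R` — round-window center at the bony overhang: the x-axis runs from `C`
  through `R`, anchoring the 0° reference of the basal turn angle θ.
* `A` — apical center of the modiolus: the z-axis is the component of
  `A − C` orthogonal to x (Gram–Schmidt), i.e. the modiolar axis.
* `I` — inner wall at the 0° reference: `|R − I|` is an upper bound for the
  ST width in the region of interest.

Two axes through three anatomical points cannot be exactly orthogonal, so a
choice is needed: x is kept exact and z is orthogonalized. The 0° reference
at the round window anchors every downstream angle (cross-section bins,
cochleostomy angle θ_C, insertion depth), which makes it the natural axis to
preserve; residual obliquity of the modiolar landmark direction only tilts z
by a fraction of a degree in practice.

The y-axis completes a right-handed frame, `y = z × x`. The pipeline's
truncation rule requires the basal ST to lie at *positive* y for either ear,
so for left ears the y-axis is flipped and the flip recorded as
`handedness = −1`. When the ear side is unknown (`side = "auto"`), the
orientation is resolved from the mesh itself: the labyrinth vertices within
2 mm of `R` are inspected and the frame is flipped if fewer than half of
them land at positive y.

Two modelling assumptions carried by the frame:

1. **Membrane plane.** The basilar membrane in the basal turn is
   approximated by the local x–y plane. Close to the round window the real
   membrane rotates toward the x–z plane, so the approximation is worst near
   θ = 0 and a planning region away from the round window (θ_C up to 20°)
   is used.
2. **Width bound.** The ST cross-section width in the region of interest
   does not exceed `|R − I|`.

## Centerline extraction

1. **Truncation** (`truncate_to_basal_st()`): keep mesh vertices with local
   y > 0 and z < 0 — the sub-membrane surface of the first basal half turn.
   Inequalities are strict: the plane z = 0 is the modelled membrane itself
   and its points are deliberately excluded, as are points at y = 0 (the
   0°/180° boundary).
2. **Radial cross sections** (`bin_cross_sections()`): each point is
   assigned to the nearest center on the grid θ = 0°, 5°, …, 180°
   (Δθ = 5°). Nearest-center assignment is a deterministic partition —
   equivalent to half-open angular bins of width Δθ — with no distance
   threshold to tune. Ties at bin midpoints are resolved by IEEE
   round-half-to-even; they occur with probability zero for measured data.
3. **Width filter** (`width_filter()`): per section, iteratively compute the
   centroid, discard points farther than `|R − I|` from it, and repeat to a
   fixed point. The kept set shrinks monotonically, so termination is
   guaranteed. This removes structures that survive truncation but are not
   basal ST surface (vestibule margin, hook region, neighboring turns).
   The rule is a documented stand-in: the width *assumption* fixes what must
   be removed, not the procedure. Its one failure mode is a contaminant
   massive or close enough to drag the initial centroid by more than
   `|R − I|` minus the section radius, which trims genuine ST points; the
   phantom's distractor tests pin the behavior on both sides of that line.
4. **Centroids**: the arithmetic mean of each surviving bin's members.
   Vertices are not weighted by incident triangle area; on reasonably
   uniform segmentation meshes the difference is far below the
   centroid-of-surface bias (below), and unweighted means keep the
   centroid the exact brute-force quantity the tests verify.
5. **Spline fit** (`fit_centerline()`): a smoothed cubic spline through the
   centroids, parameterized by basal angle.

Two numerical choices in the spline deserve explanation.

**Knot parameters.** Knots are placed at each centroid's *actual* basal
angle rather than the nominal bin center. Boundary bins (θ = 0°, 180°) are
only partially filled, so their centroids can sit 1–2° away from the
nominal center; using the nominal value there distorts the curve
parameterization exactly where the cochleostomy sweep starts.

**Smoothing in cylindrical components.** The smoothing level is the largest
penalty whose maximum 3D residual at the knots stays within `residual_tol`
(default 0.05 mm; 0 gives interpolation). The penalty is applied to the
centroids' in-plane radius and height as functions of θ, not to x, y, z
directly: a cubic smoothing spline has natural boundary conditions (second
derivative → 0 at the ends), and applied to the strongly curved x(θ), y(θ)
of a spiral that flattens the curve near the domain ends — tangent errors
of 8–30° at θ_C = 2° on noiseless phantoms. Radius and height of the
mid-scala course are slowly varying, nearly linear functions of θ, for
which the natural boundary condition is harmless. The smoothed cylindrical
curve is then re-expressed as per-coordinate cubic splines of (x, y, z)
against θ on a dense grid (0.5° spacing, knots included, near-duplicate
abscissae dropped), so evaluation and differentiation
(`spline_point()` / `spline_tangent()`) see an ordinary per-coordinate
cubic spline.

**Centroid-of-surface bias.** Cross-section centroids are means of *surface*
points of the truncated tube, not of the lumen: cutting the tube at the
membrane plane removes the top arc, which biases every centroid away from
the membrane by ≈ 0.24 of the tube radius (0.14 mm at a 0.6 mm tube). This
bias is inherent to the surface-based method, not a fitting artifact; it is
directed away from the basilar membrane (the structure the planning
protects) and is the dominant term in the phantom recovery error, which is
why the frozen regression bound for the mean centerline error (0.15 mm) sits
just above it.

## Trajectories and cochleostomy targets

The ideal insertion trajectory at cochleostomy angle θ_C is the centerline
tangent there, oriented toward increasing θ (deeper insertion). The
cochleostomy target is found by casting a ray from the centerline anchor
along the *negative* tangent — the direction from which the drill
approaches — and taking the nearest mesh intersection
(Möller–Trumbore, winding-agnostic, no backface culling, self-hit guard
t > 10⁻⁹ mm). For shells with an inner and outer bone surface the nearest
hit is the endosteal (inner) wall, which is where cochleostomy drilling
stops. The sweep covers θ_C = 2°, 4°, …, 20° by default. θ_C = 0 is
excluded: that is the round window itself, not a cochleostomy; the bound of
20° keeps the targets on the promontory inferior to the round window.

The implementation intersects all triangles with vectorized arithmetic
rather than a spatial tree: meshes of segmented labyrinths are tens of
thousands of triangles, for which a full vectorized pass is already
sub-millisecond per ray in R and — unlike tree traversal — trivially
identical to the brute-force reference. The tests compare it against an
independently coded plane/barycentric oracle on 10⁴ random rays.

## Evaluation metrics

* **Alignment angles** (`alignment_angles()`): with ideal direction `u` and
  planned direction `v` expressed in the local frame, the out-of-plane
  component is `δ = asin(u_z) − asin(v_z)` (positive: planned trajectory
  dips away from the membrane; negative: membrane collision risk) and the
  in-plane component ε is the signed angle between the x–y projections of
  `v` and `u`, positive toward the lateral wall and negative toward the
  modiolus. The lateral reference is the radial direction at the anchor
  orthogonalized against the in-plane tangent — without that
  orthogonalization ε would not vanish for `v = u`, since a spiral's
  tangent is not orthogonal to its radius.
* **Fiducial registration** (`register_fiducials()`): least-squares rigid
  point registration (SVD/Kabsch) of paired screw centers, reflection
  excluded, with the root-mean-square fiducial residual (FRE) reported.
  Surface-based screw registration would need the screw geometry; paired
  centers are the standard desk equivalent.
* **Target error** (`target_error()`): perpendicular distance from the
  planned target to the drilled trajectory *axis*. Point-to-axis is used
  (rather than point-to-point) because drilled tunnels are segmented as
  axes; an entry-point error along the axis direction is not a targeting
  error.
* **Membrane plane-approximation error** (`membrane_plane_error()`): mean
  |z| of a membrane point set per 5° bin plus the mean over an angular
  window (default 45–60°, the region the trajectories traverse).
* **Angular insertion depth** (`angular_insertion_depth()`): contact angles
  unwrapped monotonically from the most basal contact; the unwrapped angle
  of the most apical contact. Contacts must already be ordered
  basal→apical; no re-ordering is attempted.

## The synthetic phantom

`generate_phantom()` builds a helico-spiral ST tube with analytic ground
truth. Design targets: satisfy the two modelling assumptions *exactly* at
zero noise, so that any recovery error measures the pipeline rather than
the phantom.

* Centerline `c(θ) = (ρ(θ)cosθ, ρ(θ)sinθ, z(θ))` with logarithmic-spiral
  radius `ρ(θ) = a·e^(−bθ)`, a = 3 mm and b chosen so ρ(360°) = 0.6a —
  a human-scale basal turn.
* The basal half turn is flat: the tube center stays at depth
  0.8 · r below z = 0 (r = 0.6 mm tube radius, tapering linearly to half at
  the apex), so the tube's top cap crosses z = 0 and that cap *is* the
  membrane, planar by construction.
* Beyond 180° the centerline rises at 2.2 mm/turn. The pitch must be large
  enough that the ascending turns clear the membrane plane wherever their
  wrapped basal angle falls into the truncation half-space; at lower
  pitches the second turn's tube bottom dips below z = 0 near θ ≈ 360° and
  leaks vertices into the 0°-region bins, which contaminates the extracted
  sections with surface belonging to another turn. `phantom_spec()`
  validates this clearance analytically and rejects violating
  configurations.
* Landmarks by construction: `C` at the origin, `A` on the modiolar axis at
  apex height, `R` at the membrane level directly above the basal end of
  the centerline (the round window sits at the membrane), and `I` one tube
  diameter inward, so `|R − I| = 2r` equals the true ST width and the
  constructed frame reproduces the membrane plane exactly.
* Optional distractors: a vestibule-like blob entirely above the membrane
  plane, which only the truncation rule can remove, and a small coplanar
  blob below the plane, 3.5 mm radially outside the ST wall, which only the
  width filter can remove.
* Optional isotropic Gaussian vertex noise under a fixed seed; the left-ear
  variant is the exact mirror image, used for the chirality test.

What the phantom does **not** emulate: hook-region geometry near the round
window, anatomical cross-section shapes (real ST sections are not
circular), segmentation holes and topological defects, partial-volume
surface roughness, and inter-subject shape variation. Passing the phantom
suite therefore shows the geometry pipeline is correct under the method's
own assumptions; it does not validate the assumptions on clinical anatomy
(the membrane-plane error metric exists precisely to measure that on real
paired data).

`end_to_end_recovery()` runs the full pipeline on a phantom and reports the
distance from the fitted spline to the analytic centerline curve, the
tangent angular error over the sweep angles, and the distance of each
cochleostomy target from the analytic surface (tube wall or the flat basal
end cap, whichever is nearer — shallow θ_C rays legitimately exit through
the cap region that stands in for the round-window area).

## Problem sizes and tolerances in the shipped tests

The default phantom (2° rings, 24 vertices per ring, 2.5 turns) has ~10.8k
vertices / ~21.7k triangles; oracle-equivalence tests use a coarser variant
(15°/10, ~1.3k triangles) so that 10⁴-ray comparisons stay fast. Frozen
regression bounds on the default noiseless phantom: mean centerline error
≤ 0.15 mm (centroid bias, above), tangent error ≤ 5° over θ_C ∈ [2°, 20°],
targets on the surface to mesh chord tolerance; with 0.05 mm vertex noise,
mean centerline error ≤ 0.25 mm averaged over 20 seeds. Exact-arithmetic
properties (chirality mirror, membrane plane, rigid equivariance) are
asserted at 10⁻⁹–10⁻¹² tolerances.

## Known limitations

* The centerline is a *surface-centroid* line, biased ~0.14 mm below the
  true mid-scala axis at default geometry (direction: away from the
  membrane). Lumen-based centerlines (e.g. from micro-CT) would differ by
  that amount.
* Sections at the 0° and 180° boundaries are half-filled by construction;
  their centroids are noisier and the spline smooths across them.
* Basal-turn malformations (e.g. ossification) violate the width and
  membrane assumptions and are out of scope, as is everything upstream of
  the surface model (imaging, segmentation) and downstream of the plan
  (drilling, insertion mechanics).
* The planner emits the full θ_C sweep; choosing one cochleostomy angle
  against surrounding anatomy (facial nerve, chorda tympani) is left to the
  surgeon or planning software.
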
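# cochleoplan

Landmark-based planning of cochleostomy targets and electrode insertion
trajectories for minimally invasive cochlear implantation, in R.

Clinical CT cannot resolve the basilar membrane or the scala tympani (ST)
lumen, yet atraumatic implantation needs the electrode to enter the ST along
its mid-scala course. `cochleoplan` implements the geometric pipeline that
works around this: from a segmented surface model of the bony labyrinth and
four manually identified landmarks it computes the basal-turn ST centerline,
ideal insertion trajectories tangent to it, and the corresponding
cochleostomy targets on the bone surface. It is written for researchers in
image-guided otologic surgery who need a scriptable, testable implementation
of this planning geometry, and ships a synthetic phantom generator with
analytic ground truth so that every stage can be verified without clinical
data.

## Method

Four landmarks — round-window center **R**, basal modiolar center **C**,
apical modiolar center **A**, inner wall at the 0° reference **I** — define
a local cochlear frame: origin at C, x-axis through R, z-axis the
Gram–Schmidt orthogonalization of (A − C) against x (the modiolar axis),
y = z × x (flipped for left ears so the basal ST is always at positive y).
The basilar membrane is approximated by the x–y plane, and the ST width in
the region of interest is assumed not to exceed |R − I|. The pipeline then:

1. truncates the labyrinth surface vertices to y > 0, z < 0 (sub-membrane
   basal half turn);
2. partitions them into radial cross sections about the modiolar axis at
   Δθ = 5° over θ ∈ [0°, 180°], measured from R;
3. per section, iteratively trims points farther than |R − I| from the
   section centroid (width filter) and takes the centroid of the survivors;
4. fits a smoothed cubic spline through the centroids, parameterized by
   basal angle θ;
5. for θ_C = 2°, 4°, …, 20°, takes the spline tangent as the ideal
   insertion trajectory and finds the cochleostomy target by
   Möller–Trumbore ray casting from the centerline outward against the
   mesh.

Around the planner, the package provides the standard evaluation metrics of
image-guided cochlear surgery: the out-of-plane / in-plane alignment angles
δ = asin(u_z) − asin(v_z) and ε (signed toward the lateral wall) between a
planned and the ideal trajectory, least-squares rigid fiducial registration
with FRE, perpendicular target error to a drilled axis, basilar-membrane
plane-approximation error per angular bin, and angular insertion depth by
monotone unwrapping of electrode-contact angles.

See `vignettes/trajectory-planning.Rmd` for the full model, assumptions,
parameter defaults and numerical design choices.

## Worked example

Generate a phantom dataset on disk, plan on it from the files, and inspect
the result:

```r
library(cochleoplan)

out <- tempfile(); dir.create(out)
cmd_phantom(out, phantom_spec(), quiet = TRUE)   # phantom.stl, landmarks.json, truth.json

mesh      <- read_mesh(file.path(out, "phantom.stl"))
landmarks <- read_landmarks(file.path(out, "landmarks.json"))
landmarks
#> Cochlear landmark set (mm, world frame)
#>   R: (3.000, 0.000, 0.000)
#>   C: (0.000, 0.000, 0.000)
#>   A: (0.000, 0.000, 3.920)
#>   I: (1.800, 0.000, 0.000)
#>   side: right; ST width |R - I|: 1.200 mm

res <- plan_cochleostomy(mesh, landmarks)
res
#> Scala tympani cochleostomy plan
#>   vertices: 10826 -> 1758 after truncation; 1758 in 37 sections (0 removed by width filter)
#>   spline: theta in [1.00469, 178.9] deg, max residual 0.05 mm
#>   10 trajectories at theta_C = 2, 4, 6, 8, 10, 12, 14, 16, 18, 20 deg

res$plan[[5]]
#> Insertion trajectory at theta_C = 10 deg
#>   anchor (world mm): (2.914, 0.514, -0.634)
#>   insertion dir:     (-0.2643, 0.9641, 0.0265)
#>   cochleostomy target: (3.054, 0.004, -0.648) on face 21611, exit 0.528 mm
```

The 1758 vertices are the sub-membrane basal-turn surface; 37 sections are
the 5° bins over the half turn; the θ_C = 10° trajectory anchors on the
centerline at basal angle 10°, points tangentially into the spiral, and its
target sits on the mesh 0.53 mm outward of the anchor, next to the
round-window region.

Scoring a hypothetical user-planned drill direction against the ideal one:

```r
tr <- res$plan[[5]]
planned <- c(-0.2613, 0.9532, -0.1517)   # ideal tilted ~10 deg below the membrane plane
alignment_angles(planned, tr$insertion_dir, res$frame, tr$target)
#> Trajectory alignment: delta = +10.25 deg (out-of-plane), epsilon = +0.00 deg (in-plane)
```

Positive δ means the planned trajectory dips away from the basilar
membrane (safe side); negative δ or ε would flag membrane or modiolus
collision risk.

A shell interface wrapping the same functions is installed at
`inst/cli/cochleoplan.R` with `plan`, `phantom` and `evaluate` subcommands.

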
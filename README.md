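# orthomount

Digital model surgery for orthognathic (jaw-repositioning) surgery,
replacing the semi-adjustable articulator, face-bow and plaster work of
arbitrary (mean-value) surgical planning with a fully scripted pipeline on
intraoral-scan meshes.

**Who it is for.** Orthodontists and maxillofacial surgery planners who
mount dental casts on an articulator with an anatomic face-bow, simulate
the planned maxillary/mandibular movements as model surgery, and fabricate
intermediate and final occlusal splints — and who want that workflow on
STL scans instead of plaster, without patient-specific CBCT planning
systems.

## The model

The articulator's reference plane is the **axis-orbital plane (AOP)**,
represented clinically by the face-bow. Two hardware constants make the
mounting *arbitrary* (mean-value): the face-bow's nasal rest sits at a
fixed perpendicular offset from the face-bow plane (**30 mm**), and the
hinge axis lies a fixed distance anterior of the ear rods (**10 mm**).
Because of this, four landmarks on a lateral cephalogram suffice to
compute the whole mounting by plane trigonometry — Pi (Porion inferior),
Ns (nasal rest), Ie (upper incisor edge) and Dc (distobuccal cusp of the
first upper molar; Ie–Dc is the maxillary occlusal plane). In the image
frame (origin top-left, y down, patient facing right):

    alpha = arcsin(30 / |Pi-Ns|)            # nasal-rest triangle
    eta   = arctan(slope(Pi-Ns)) - alpha    # face-bow plane vs horizontal
    theta = arctan(slope(Ie-Dc))            # occlusal plane vs horizontal
    lambda = theta + eta                    # occlusal plane vs AOP

    Ax    = Pi + 10 * (cos eta, sin eta)    # arbitrary hinge axis
    omega = phi - theta,  phi = angle(Ax-Ie vs horizontal)
    d_up   = sin(omega) * |Ax-Ie|           # hinge height above occlusal plane
    d_post = d_up / tan(omega)              # incisor edge -> axis foot point

`lambda`, `d_up` and `d_post` place the hinge-axis pivot relative to the
maxillary scan and angle the mounted scene to the AOP — the digital
equivalent of a face-bow transfer. A frontal photograph supplies the
transverse occlusal cant against the interpupillary line. Planning is then
rigid-body arithmetic: jaws (mesh + measurement pivots) are cloned, moved,
measured per pivot in the mounted frame (x patient-left, y up, z
anterior), occlusal contacts are found by signed vertex-to-mesh distance,
and the splint STL sets (intermediate/final, with the ~2 degree mandibular
open rotation about the hinge axis) are exported in true relative pose.

## Worked example

Landmarks are picked on a scaled cephalogram (here: a synthetic case whose
ground truth is a 7.8 degree mounting angle with the hinge axis 35.8 mm
above the occlusal plane and 89.9 mm behind the incisor edge, at
0.1 mm/px):

```r
library(orthomount)

lm_px <- ceph_landmarks(Pi = c(1000, 1500), Ns = c(2006, 1800),
                        Ie = c(1942, 1977), Dc = c(1546, 1922),
                        mm_per_px = 0.1)
params <- hinge_axis_parameters(scale_landmarks(lm_px))
params
#> Articulator mounting parameters
#>   occlusal plane vs horizontal (theta):    7.8 deg
#>   face-bow plane vs horizontal (eta):      0.0 deg
#>   occlusal plane vs AOP (lambda):          7.8 deg
#>   hinge axis above occlusal plane:        35.8 mm
#>   incisor edge to axis foot point:        89.9 mm
#>   hinge axis to incisor edge:             96.8 mm
```

Reading: the maxillary occlusal plane makes 7.8 degrees with the AOP, so
after mounting, the scene is rotated by that angle; the hinge-axis pivot
is then 35.8 mm perpendicular above the occlusal plane, its foot point
89.9 mm posterior of the incisor edge.

Mount scan meshes, plan a 4 mm maxillary advancement, and measure it:

```r
case <- generate_synthetic_case(synthetic_case_config(seed = 42))
scene <- mount_scene(case$maxilla, case$mandible, case$mesh_landmarks, params)

post <- move_jaw(clone_jaw(scene$maxilla), planned_move(translation = c(0, 0, 4)))
head(measure_displacements(scene$maxilla, post), 3)
#>       pivot pre_x    pre_y     pre_z post_x   post_y    post_z dx dy dz euclidean
#> 1        Ie     0 0.000000   0.00000      0 0.000000   4.00000  0  0  4         4
#> 2  occ_left    30 6.107201 -44.58365     30 6.107201 -40.58365  0  0  4         4
#> 3 occ_right   -30 6.107201 -44.58365    -30 6.107201 -40.58365  0  0  4         4

detect_contacts(scene$maxilla, scene$mandible)
#> <contact_report> tolerance 0.1 mm: 58 upper / 58 lower contact vertices
#>   deepest penetration 0.0500 mm, closest approach 0.0500 mm
```

Every pivot advanced exactly 4 mm anterior (`dz`), nothing moved
laterally or vertically; the constructed occlusion sits at its stated
0.05 mm interocclusal gap. Splint export:

```r
plan <- surgical_plan(scene$maxilla, scene$mandible,
                      postop_maxilla = post,
                      postop_mandible = clone_jaw(scene$mandible),
                      hinge_pivot = scene$hinge_pivot)
export_splint_set(plan, "bimaxillary", "splints/")   # exactly 3 STL files
```

A command-line interface covering the same workflow
(`simulate`, `mount-params`, `cant`, `mount`, `plan`, `measure`,
`contacts`, `export-splints`, `report`) ships in
`inst/cli/orthomount`.

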
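---
title: "Virtual articulator mounting and digital model surgery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual articulator mounting and digital model surgery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomount)
```

## The problem and the model

Conventional orthognathic surgery planning mounts dental casts in a
semi-adjustable articulator via an anatomic face-bow, simulates the
planned jaw movements as plaster model surgery, and fabricates occlusal
splints that guide the surgeon. The mounting is *arbitrary*: it uses the
articulator's mean-value dimensions, not the patient's true hinge axis.
`orthomount` reproduces exactly this arbitrary workflow digitally, on
intraoral-scan meshes — deliberately inheriting its assumptions rather
than "improving" them, because decades of clinical experience calibrate
the whole downstream protocol to them.

Two hardware constants make a four-landmark cephalometric solution
possible:

* `ns_offset` (default **30 mm**): the face-bow's nasal rest sits at a
  fixed perpendicular distance from the face-bow plane, which represents
  the axis-orbital plane (AOP, the articulator's reference plane).
* `axis_anterior_offset` (default **10 mm**): the articulator's hinge
  axis lies a fixed distance anterior of the ear rods along the face-bow
  plane.

From Pi (Porion inferior), Ns (nasal rest), Ie (upper incisor edge) and
Dc (distobuccal first-molar cusp), plane trigonometry yields the face-bow
inclination `eta`, the occlusal-plane inclination `theta`, the mounting
angle `lambda = theta + eta`, and — after placing the hinge axis `Ax` at
the fixed offset from Pi — the two distances that matter for mounting:
the perpendicular hinge-axis height above the occlusal plane (`d_up`) and
the distance from the incisor edge to the foot of that perpendicular
(`d_post`). Both hardware constants are configurable (`load_config()`,
`facebow_constants()`) for other face-bow models.

### Coordinate conventions

All 2D computation happens in the tracing image frame: origin top-left,
y increasing **downward**, patient facing image-right (mirror left-facing
tracings first). Angles are degrees externally, radians internally;
printed summaries round to 0.1 deg / 0.1 mm but stored values are never
rounded. The 3D world frame is fixed once: **y up, +z anterior, +x
patient-left**; "distally" is −z. The mounted scene therefore has the
occlusal plane on the ground grid before the AOP rotation, and the hinge
pivot posterosuperior to the incisor edge after it.

### Two documented readings of the printed formulas

Two places in the published equation set require a choice; both are
explicit options here:

1. **Hinge-axis direction.** The axis coordinates are printed with
   `cos(alpha)/sin(alpha)`, but the axis is stated to lie *on the
   face-bow plane*, whose direction is `eta`. The default
   (`axis_direction = "facebow"`) uses `eta`, geometrically consistent
   with the rest of the construction; `axis_direction = "strict"`
   reproduces the literal `alpha` placement. The difference is bounded by
   the chord of a 10 mm circle over `|eta - alpha|` — sub-millimetre for
   typical anatomy.
2. **The perpendicular distance.** The printed product "sin(omega) ·
   Ax − Ie" is implemented as `sin(omega) * ||Ax - Ie||`, the only
   dimensionally consistent reading; likewise the printed
   `(y_Ie − y_Ax)/sin(phi)` equals the Euclidean norm `||Ax − Ie||` for
   anterior-facing input and is implemented as the norm (which also stays
   defined at `phi = 0`).

### Validity domain of the angle sum

A verification the package's tests encode (and that we have not seen
stated elsewhere): the relation `eta = epsilon − alpha` recovers the
face-bow inclination exactly only when Ns lies on the *inferior* side of
the face-bow plane — which the hardware offset direction implies — and
the angle sum `lambda = theta + eta` is exact precisely when the
radiograph is oriented with the face-bow plane horizontal (the standard
cephalostat orientation). A residual head tilt `psi` leaves `eta`,
`omega`, `d_up` and `d_post` exact but biases `lambda` by `2 psi`. The
synthetic generator therefore models an AOP-level radiograph by default
and exposes `head_tilt_deg` as an explicit error knob; a dedicated test
pins both the exact `eta` recovery under tilt and the `2 psi` bias. In
clinical use this argues for levelling the tracing to the marked AOP
before picking landmarks.

### Degenerate-input policy

Hard classed errors by default: `||Pi − Ns|| <= ns_offset` (arcsin
argument at or above 1 — implausible landmarks or a wrong scale),
vertically aligned Ie/Dc, collinear occlusal mesh landmarks, and
`omega <= 0` (hinge axis at or below the occlusal plane) all raise
`degenerate_geometry`. A `permissive` flag turns only the exact
`omega = 0` limit into the limit-case return (`d_up = 0`,
`d_post = ||Ax − Ie||`); negative `omega` always errors.

## Photometric cant

The transverse inclination of the occlusal plane is quantified as the
signed angle between the occlusal line and the interpupillary line on a
frontal photograph (no scale needed for an angle). Sign convention:
**positive cant = patient-left side inferior**, measured in the y-down
photo frame. The dental midline offset in millimetres is reported only
when both midline points *and* a photo scale are supplied, since a
calibrated frontal photograph is not part of the routine record set.

Cant correction of the mounted scene rotates both jaws about the
antero-posterior axis through the incisor pivot by `+cant_deg`. Note the
sign: a positive (left-inferior) cant measured in the y-down photo frame
corresponds to a `−cant` rotation about +z in the y-up world frame, so
levelling requires `+cant`. (A formulation that rotates by `−cant` is
consistent only if the world x-axis points patient-right.) Cant
correction must precede the AOP rotation; when the maxilla was aligned
from its occlusal mesh landmarks (which levels the occlusal plane by
construction) no cant correction is needed — the correction exists for
scans aligned from facial references.

## Mounting pipeline

`align_maxilla()` replaces interactive drag-alignment with a closed-form
landmark fit: occlusal plane (through Ie, occ_right, occ_left) onto
y = 0 with the palate above, median raphe into the mid-sagittal plane
pointing anterior, Ie at the origin. Landmarks may be vertex indices or
coordinates; coordinates snap to the nearest vertex within 1 mm and are
rejected beyond that. The mandible is assumed bite-registered to the
maxilla (`register_bite()` provides the orthogonal-Procrustes fit with
reflections excluded) and follows passively through every mounting step —
its pose relative to the maxilla is preserved to machine precision.

`place_hinge_pivot()` clones the incisor pivot to
`Ie + (0, +d_up, −d_post)`; `mount_to_aop()` rotates everything about the
x-axis through Ie by `lambda`. The rotation sense is defined by the
anatomical outcome (hinge axis ends posterosuperior, ground plane becomes
AOP-parallel), not by a screen direction, and is verified against the
synthetic 3D construction: the mounted hinge height above Ie must equal
`d_up cos(lambda) + d_post sin(lambda)`.

## Planning

Preoperative jaws are immutable; every planned state is a `clone_jaw()`
copy (R's copy-on-modify makes clones cheap and isolated, "limited only
by storage"). `move_jaw()` applies rotation-about-centre then
translation; the centre may name a pivot, matching the workflow of
snapping the transform widget to a pivot. Displacements are reported per
pivot as signed post-minus-pre deltas in the mounted frame plus the
Euclidean norm — the digital planning-sheet table. Contact detection
formalizes visual mesh "merging" as signed vertex-to-mesh distance
(exact point-to-triangle minimum; sign by ray parity, meaningful for
closed meshes) thresholded at a default tolerance of **0.1 mm**,
reporting penetration depth rather than mere membership.

The final-splint **open rotation** (default **2 degrees**, configurable)
rotates the mandible about the hinge pivot in the mouth-opening sense
(lower incisor moves inferior and posterior). Splint export sets follow
the surgical scenario — `bimaxillary`: postop maxilla + preop mandible
(intermediate splint) + open-rotated postop mandible (final splint),
exactly three files; single-jaw scenarios: two files — written in the
common scene frame with **no re-centering**, so downstream CAD sees true
relative poses. STL is single precision; pivots and parameters round-trip
exactly through the JSON side-car (`scene.json`), meshes to ~1e-5 mm.

## The synthetic generator: what a green test establishes

`generate_synthetic_case()` builds a stated world with known truth:

* a watertight parabolic arch band (plus a midline palate plate carrying
  the raphe landmarks) with all named landmarks on exact mesh vertices;
  default dimensions are an average adult maxillary arch (width 60 mm,
  depth 45 mm);
* default mounting truth `lambda = 7.8` deg, `d_up = 35.8` mm,
  `d_post = 89.9` mm — the magnitude of a typical clinical mounting —
  with `Pi-Ns = 105` mm and `Ie-Dc = 40` mm;
* a constructed occlusion with a stated interocclusal gap (default
  0.05 mm: light scan-occlusion contact, inside the contact tolerance);
* the lateral orthographic projection of the construction into pixel
  landmarks (default 0.1 mm/px), optionally Gaussian-jittered
  (`jitter_sd`, default 0) for error-propagation studies;
* a frontal projection with seed-drawn camera roll carrying `cant_true`
  and `midline_offset_true`;
* an optional random scanner pose so the alignment step has real work.

Everything is deterministic given `seed`. What it does **not** emulate:
tooth morphology, cephalometric perspective magnification (orthographic
projection only; magnification is folded into the scale), soft tissue,
landmark identification error (unless `jitter_sd > 0`), and non-rigid
scan artefacts. A green round-trip test therefore establishes the
*internal* consistency of the trigonometry, mounting and planning chain —
not the clinical accuracy of landmark picking, which the arbitrary method
inherits from its analog ancestor.

## Numerical choices

* Rigid transforms store an explicit proper-orthogonal matrix; reflections
  are rejected at construction (`det = +1` to 1e-9), so no operation can
  silently mirror a jaw.
* Procrustes registration corrects the SVD sign to exclude reflections;
  collinear or duplicate point sets raise `degenerate_geometry`.
* Ray-parity inside tests use a fixed oblique direction so axis-aligned
  fixtures do not graze edges; contact distances at exactly the surface
  report 0 and count as contacts.
* JSON reports serialize with 9 significant digits — byte-identical
  across repeated runs, diff-stable in version control.
* Angles are stored in degrees at API boundaries and converted once.

## Known limitations

* The angle-sum bias under radiograph tilt (see above) is inherent to the
  printed formula set; the package documents and tests it rather than
  silently reformulating the published method.
* Contact detection is vertex-based: a penetration strictly between
  vertices of both meshes (coarse meshes) can be missed; for scan-density
  meshes this is immaterial.
* Whole-jaw moves only; segmental osteotomies, splint solid-body CAD,
  soft-tissue prediction and CBCT fusion are out of scope.
* Sign of `lambda` for a posteriorly divergent occlusal plane follows the
  same signed conventions but has no clinical reference case; the common
  anterior-divergent case is the tested path.
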
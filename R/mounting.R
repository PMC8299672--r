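# Articulator-equivalent mounting of jaw scans in the world frame.
#
# World frame convention, fixed once for the whole package: y up, +z
# anterior, +x toward the patient's left. "Distally" (posteriorly) is -z,
# "up" is +y. During alignment the ground plane (y = 0) coincides with the
# maxillary occlusal plane; after the final mounting rotation it parallels
# the axis-orbital plane (AOP) instead.

WORLD_FRAME <- list(y_up = TRUE, x = "patient-left", z = "anterior", units = "mm")

snap_to_vertex <- function(mesh, p, tol = 1) {
  p <- as_point3(p)
  d2 <- rowSums(sweep(mesh$vertices, 2L, p)^2)
  i <- which.min(d2)
  if (sqrt(d2[i]) > tol) {
    degenerate_geometry(sprintf(
      "landmark (%.2f, %.2f, %.2f) lies %.2f mm from the mesh surface (max %.1f mm)",
      p[1], p[2], p[3], sqrt(d2[i]), tol))
  }
  mesh$vertices[i, ]
}

resolve_mesh_landmark <- function(mesh, v) {
  if (length(v) == 1L && is.numeric(v)) {
    i <- as.integer(v)
    if (i < 1L || i > nrow(mesh$vertices)) {
      om_error("config_error", sprintf("vertex index %d out of range", i))
    }
    return(mesh$vertices[i, ])
  }
  snap_to_vertex(mesh, v)
}

#' Alignment transform for the maxilla
#'
#' Computes the rigid motion that brings the maxillary scan into the
#' canonical mounted pose: the occlusal plane (through the landmarks `Ie`,
#' `occ_right`, `occ_left`) onto the ground plane `y = 0` with the jaw body
#' above it, the median palatal raphe (`raphe_ant`, `raphe_post`) into the
#' mid-sagittal plane `x = 0` pointing anterior (+z), and the incisor edge
#' `Ie` to the origin. This replaces interactive grid alignment with a
#' closed-form landmark fit.
#'
#' @param mesh maxillary `tri_mesh`.
#' @param mesh_landmarks named list with entries `Ie`, `occ_right`,
#'   `occ_left`, `raphe_ant`, `raphe_post`; each a 3-vector within 1 mm of
#'   the surface (snapped to the nearest vertex) or a single vertex index.
#' @return `rigid_transform` to apply (via [transform_jaw()]) to the
#'   maxilla and, passively, the registered mandible.
#' @export
align_maxilla <- function(mesh, mesh_landmarks) {
  need <- c("Ie", "occ_right", "occ_left", "raphe_ant", "raphe_post")
  miss <- setdiff(need, names(mesh_landmarks))
  if (length(miss)) missing_landmark(paste("missing mesh landmarks:", paste(miss, collapse = ", ")))
  lm <- lapply(mesh_landmarks[need], function(v) resolve_mesh_landmark(mesh, v))

  u <- lm$occ_right - lm$Ie
  v <- lm$occ_left - lm$Ie
  n <- cross3(u, v)
  if (vnorm(n) < 1e-9 * max(vnorm(u), vnorm(v), 1)) {
    degenerate_geometry("Ie, occ_right, occ_left are collinear: occlusal plane undefined")
  }
  n <- normalize(n)
  # orient the occlusal normal toward the jaw body: the palate (raphe) lies
  # above the occlusal plane for a maxilla
  raphe_mid <- (lm$raphe_ant + lm$raphe_post) / 2
  if (sum(n * (raphe_mid - lm$Ie)) < 0) n <- -n
  ey <- n
  zr <- lm$raphe_ant - lm$raphe_post
  ez <- zr - sum(zr * ey) * ey
  if (vnorm(ez) < 1e-9) degenerate_geometry("raphe line is perpendicular to the occlusal plane")
  ez <- normalize(ez)
  ex <- cross3(ey, ez)
  R <- rbind(ex, ey, ez)                       # world -> canonical axes
  rigid_transform(R, -as.vector(R %*% lm$Ie))
}

#' Correct the transverse occlusal cant
#'
#' Rotates maxilla and mandible together about the antero-posterior
#' (z) axis through the maxillary `Ie` pivot so a measured cant is
#' levelled, leaving the Ie pivot fixed. A positive cant (patient-left
#' inferior, measured in the y-down photo frame) corresponds to a world
#' pose rotated by `-cant_deg` about +z, so the correction rotates by
#' `+cant_deg`. Applied before the AOP mounting rotation.
#'
#' @param scene `articulator_scene` (see [articulator_scene()]).
#' @param cant_deg measured cant in degrees (positive = patient-left
#'   inferior).
#' @return updated scene.
#' @export
apply_cant_correction <- function(scene, cant_deg) {
  stopifnot(inherits(scene, "articulator_scene"))
  if (!is.null(scene$lambda_applied)) {
    om_error("config_error", "cant correction must precede the AOP mounting rotation")
  }
  if (cant_deg == 0) return(scene)
  tf <- rotation_about_axis(c(0, 0, 1), cant_deg,
                            center = pivot_position(scene$maxilla, "Ie"))
  scene$maxilla <- transform_jaw(scene$maxilla, tf, "cant_correction")
  scene$mandible <- transform_jaw(scene$mandible, tf, "cant_correction")
  if (!is.null(scene$hinge_pivot)) {
    scene$hinge_pivot$position <- transform_points(tf, scene$hinge_pivot$position)
  }
  scene
}

#' Place the hinge-axis pivot from mounting parameters
#'
#' In the pre-rotation pose (occlusal plane = ground plane) the articulator
#' hinge axis sits `d_post` millimetres distally (-z) and `d_up`
#' millimetres up (+y) of the upper incisor pivot; this clones that pivot
#' and moves it accordingly.
#'
#' @param ie_pivot the maxillary incisor-edge [pivot()].
#' @param params `mounting_parameters`.
#' @return a [pivot()] named `"hinge_axis"`.
#' @export
place_hinge_pivot <- function(ie_pivot, params) {
  stopifnot(inherits(ie_pivot, "pivot"), inherits(params, "mounting_parameters"))
  pivot("hinge_axis",
        ie_pivot$position + c(0, params$d_up, -params$d_post),
        bound_to = ie_pivot$bound_to)
}

#' Assemble an articulator scene
#'
#' Bundles an aligned maxilla, the bite-registered mandible and (once
#' placed) the hinge-axis pivot. The mandible is assumed already expressed
#' in the maxilla's coordinates (bite-scan registration, see
#' [register_bite()]); it follows the maxilla passively through every
#' mounting step.
#'
#' @param maxilla,mandible `jaw_model`s in a common frame; the maxilla
#'   must carry an `"Ie"` pivot.
#' @param hinge_pivot optional hinge-axis [pivot()].
#' @return object of class `articulator_scene`.
#' @export
articulator_scene <- function(maxilla, mandible, hinge_pivot = NULL) {
  stopifnot(inherits(maxilla, "jaw_model"), inherits(mandible, "jaw_model"))
  if (is.null(maxilla$pivots[["Ie"]])) {
    missing_landmark("the maxilla must carry a pivot named 'Ie' (upper incisor edge)")
  }
  structure(list(maxilla = maxilla, mandible = mandible,
                 hinge_pivot = hinge_pivot,
                 frame = WORLD_FRAME, lambda_applied = NULL),
            class = "articulator_scene")
}

#' @export
print.articulator_scene <- function(x, ...) {
  cat("<articulator_scene>\n")
  print(x$maxilla); print(x$mandible)
  if (!is.null(x$hinge_pivot)) {
    cat(sprintf("hinge axis at (%.2f, %.2f, %.2f)\n",
                x$hinge_pivot$position[1], x$hinge_pivot$position[2],
                x$hinge_pivot$position[3]))
  }
  cat(if (is.null(x$lambda_applied)) "not yet mounted to AOP\n"
      else sprintf("mounted: lambda = %.2f deg\n", x$lambda_applied))
  invisible(x)
}

#' Rotate the scene so the ground plane parallels the AOP
#'
#' All jaws and pivots are rotated together about the x-axis through the
#' maxillary incisor pivot by the mounting angle lambda. The sense is fixed
#' anatomically: after mounting, the hinge axis lies posterosuperior to the
#' occlusal plane and the occlusal plane dips anteriorly below the
#' axis-orbital plane (a positive right-hand rotation about +x for positive
#' lambda).
#'
#' @param scene `articulator_scene` with the hinge pivot placed.
#' @param lambda_deg mounting angle (degrees), from
#'   [hinge_axis_parameters()].
#' @return the mounted scene (`lambda_applied` recorded).
#' @export
mount_to_aop <- function(scene, lambda_deg) {
  stopifnot(inherits(scene, "articulator_scene"))
  if (is.null(scene$hinge_pivot)) {
    om_error("config_error", "place the hinge pivot before mounting to the AOP")
  }
  tf <- rotation_about_axis(c(1, 0, 0), lambda_deg,
                            center = pivot_position(scene$maxilla, "Ie"))
  scene$maxilla <- transform_jaw(scene$maxilla, tf, "mount_to_aop")
  scene$mandible <- transform_jaw(scene$mandible, tf, "mount_to_aop")
  scene$hinge_pivot$position <- transform_points(tf, scene$hinge_pivot$position)
  scene$lambda_applied <- lambda_deg
  scene
}

#' Full virtual mounting pipeline
#'
#' Convenience wrapper: align the maxilla (mandible follows passively),
#' apply the cant correction, place the hinge-axis pivot and rotate the
#' scene to the AOP.
#'
#' @param maxilla,mandible `jaw_model`s in the scanner frame (mandible
#'   bite-registered to the maxilla).
#' @param mesh_landmarks the five maxillary alignment landmarks, see
#'   [align_maxilla()].
#' @param params `mounting_parameters` from the cephalogram.
#' @param cant_deg transverse cant to correct (degrees), default 0.
#' @return mounted `articulator_scene`.
#' @export
mount_scene <- function(maxilla, mandible, mesh_landmarks, params, cant_deg = 0) {
  tf <- align_maxilla(maxilla$mesh, mesh_landmarks)
  maxilla <- transform_jaw(maxilla, tf, "align_maxilla")
  mandible <- transform_jaw(mandible, tf, "align_maxilla")
  scene <- articulator_scene(maxilla, mandible)
  scene <- apply_cant_correction(scene, cant_deg)
  scene$hinge_pivot <- place_hinge_pivot(scene$maxilla$pivots[["Ie"]], params)
  mount_to_aop(scene, params$lambda_deg)
}
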
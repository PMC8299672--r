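# Face-bow trigonometry on a lateral cephalogram.
#
# All computations use the image frame of the tracing software: origin in
# the upper-left corner, x to the right, y increasing DOWNWARD, patient
# facing image-right (anterior at larger x). Angles are returned in degrees;
# distances in millimetres.

point2 <- function(x, y = NULL) {
  if (is.null(y)) { p <- as.numeric(x) } else { p <- c(as.numeric(x), as.numeric(y)) }
  if (length(p) != 2L || any(!is.finite(p))) {
    om_error("config_error", "a 2D landmark must be a finite (x, y) pair")
  }
  p
}

#' Face-bow hardware constants
#'
#' The anatomical face-bow fixes two dimensions: the nasal rest sits at a
#' constant perpendicular offset from the face-bow plane (30 mm), and the
#' articulator hinge axis lies a constant distance anterior of the ear rods
#' (10 mm).
#'
#' @param ns_offset perpendicular distance (mm) from the nasal rest Ns to
#'   the face-bow plane; default 30.
#' @param axis_anterior_offset distance (mm) from the ear-rod point Pi to
#'   the hinge axis Ax along the face-bow plane; default 10.
#' @return object of class `facebow_constants`.
#' @export
facebow_constants <- function(ns_offset = 30, axis_anterior_offset = 10) {
  if (!is.finite(ns_offset) || ns_offset <= 0 ||
      !is.finite(axis_anterior_offset) || axis_anterior_offset <= 0) {
    om_error("config_error", "face-bow constants must be strictly positive")
  }
  structure(list(ns_offset = ns_offset,
                 axis_anterior_offset = axis_anterior_offset),
            class = "facebow_constants")
}

#' Average bilateral landmark pair
#'
#' Cephalograms show double contours for paired structures; the landmark
#' used is the componentwise mean of the left and right markings.
#'
#' @param left,right (x, y) coordinate pairs.
#' @return (x, y) midpoint.
#' @export
average_bilateral <- function(left, right) {
  (point2(left) + point2(right)) / 2
}

resolve_landmark <- function(v, what) {
  if (is.null(v)) missing_landmark(sprintf("landmark '%s' is missing", what))
  if (is.list(v) && !is.null(v$left) && !is.null(v$right)) {
    return(average_bilateral(v$left, v$right))
  }
  point2(v)
}

#' Cephalometric landmark set
#'
#' The four landmarks driving the mounting computation: Pi (Porion
#' inferior, deepest point on the lower border of the external acoustic
#' meatus), Ns (nasal rest of the face-bow), Ie (upper incisor edge) and Dc
#' (distobuccal cusp of the first upper molar). Ie and Dc define the
#' maxillary occlusal plane. Each landmark may be a single `(x, y)` pair or
#' a `list(left =, right =)` pair of markings, which is averaged on
#' construction.
#'
#' @param Pi,Ns,Ie,Dc landmark coordinates (image convention, see Details).
#' @param mm_per_px scale; 1.0 means coordinates are already millimetres.
#' @return object of class `ceph_landmarks`.
#' @details Image convention: origin top-left, y increasing downward,
#'   patient facing image-right. Mirror left-facing tracings before
#'   constructing the set.
#' @export
ceph_landmarks <- function(Pi, Ns, Ie, Dc, mm_per_px = 1) {
  if (!is.finite(mm_per_px) || mm_per_px <= 0) {
    om_error("config_error", "mm_per_px must be a positive number")
  }
  lm <- structure(list(
    Pi = resolve_landmark(Pi, "Pi"),
    Ns = resolve_landmark(Ns, "Ns"),
    Ie = resolve_landmark(Ie, "Ie"),
    Dc = resolve_landmark(Dc, "Dc"),
    mm_per_px = mm_per_px
  ), class = "ceph_landmarks")
  if (all(lm$Pi == lm$Ns)) degenerate_geometry("Pi and Ns coincide")
  if (all(lm$Ie == lm$Dc)) degenerate_geometry("Ie and Dc coincide")
  lm
}

#' Convert pixel landmarks to millimetres
#'
#' @param landmarks `ceph_landmarks` in pixels (its `mm_per_px` is used).
#' @param mm_per_px optional override of the stored scale.
#' @return `ceph_landmarks` in mm with `mm_per_px = 1`.
#' @export
scale_landmarks <- function(landmarks, mm_per_px = landmarks$mm_per_px) {
  stopifnot(inherits(landmarks, "ceph_landmarks"))
  if (!is.finite(mm_per_px) || mm_per_px <= 0) {
    om_error("config_error", "mm_per_px must be a positive number")
  }
  ceph_landmarks(landmarks$Pi * mm_per_px, landmarks$Ns * mm_per_px,
                 landmarks$Ie * mm_per_px, landmarks$Dc * mm_per_px,
                 mm_per_px = 1)
}

#' Face-bow geometry from Pi and Ns
#'
#' Solves the right triangle Pi--Ns--b, where b is the foot of the
#' perpendicular from the nasal rest Ns onto the face-bow plane. Because
#' the hardware fixes `||Ns - b||` (30 mm), two marked points suffice to
#' recover the inclination of the face-bow plane:
#' \deqn{\alpha = \arcsin(ns\_offset / \|Pi-Ns\|)}
#' \deqn{\epsilon = \arctan(slope(Pi \to Ns)), \qquad \eta = \epsilon - \alpha}
#' `eta` is the angle of the face-bow plane (axis-orbital plane, AOP)
#' against the image horizontal.
#'
#' @param Pi,Ns landmark coordinates in mm (image convention).
#' @param constants `facebow_constants`.
#' @return object of class `facebow_geometry` with fields `dist_Pi_Ns`,
#'   `dist_Pi_b` (mm) and `alpha`, `epsilon`, `eta` (degrees).
#' @export
facebow_geometry <- function(Pi, Ns, constants = facebow_constants()) {
  Pi <- point2(Pi); Ns <- point2(Ns)
  d <- vnorm(Ns - Pi)
  if (d <= constants$ns_offset) {
    degenerate_geometry(sprintf(
      "||Pi-Ns|| = %.3f mm <= nasal-rest offset (%.1f mm): landmarks or scale implausible",
      d, constants$ns_offset))
  }
  if (Ns[1] == Pi[1]) {
    degenerate_geometry("Pi and Ns are vertically aligned; face-bow slope undefined")
  }
  alpha <- asin(constants$ns_offset / d)
  eps <- atan((Ns[2] - Pi[2]) / (Ns[1] - Pi[1]))
  eta <- eps - alpha
  structure(list(
    dist_Pi_Ns = d,
    dist_Pi_b = cos(alpha) * d,
    alpha = rad2deg(alpha),
    epsilon = rad2deg(eps),
    eta = rad2deg(eta)
  ), class = "facebow_geometry")
}

#' Occlusal plane inclination
#'
#' Angle theta between the maxillary occlusal plane (through the incisor
#' edge Ie and the distobuccal molar cusp Dc) and the image horizontal,
#' from the two-point slope. Positive theta (image y points down) means the
#' incisal end sits inferior to the molar end.
#'
#' @param Ie,Dc landmark coordinates in mm (image convention).
#' @return angle in degrees, in (-90, 90).
#' @export
occlusal_plane_angle <- function(Ie, Dc) {
  Ie <- point2(Ie); Dc <- point2(Dc)
  if (Ie[1] == Dc[1]) {
    degenerate_geometry("Ie and Dc are vertically aligned: occlusal plane slope undefined")
  }
  rad2deg(atan((Ie[2] - Dc[2]) / (Ie[1] - Dc[1])))
}

#' Mounting angle between face-bow plane and occlusal plane
#'
#' lambda = theta + eta: the angle through which the mounted scene must be
#' rotated so the ground plane parallels the axis-orbital plane.
#'
#' @param theta occlusal-plane angle (degrees).
#' @param eta face-bow plane angle (degrees).
#' @return lambda in degrees.
#' @export
mounting_angle <- function(theta, eta) theta + eta

#' Arbitrary hinge-axis position and full mounting parameters
#'
#' Places the articulator hinge axis Ax on the face-bow plane at the fixed
#' anterior offset from Pi, then resolves the triangle Ax--Ie--Dc' (Dc' =
#' foot of the perpendicular from Ax onto the occlusal plane):
#' \deqn{\omega = \phi - \theta}
#' \deqn{d_{up} = \sin\omega \cdot \|Ax-Ie\|, \qquad
#'       d_{post} = d_{up} / \tan\omega}
#' `d_up` is the perpendicular height of the hinge axis above the occlusal
#' plane; `d_post` the distance along the occlusal plane from the incisor
#' edge back to the foot of that perpendicular. These two distances place
#' the hinge-axis pivot relative to the maxillary scan.
#'
#' @param landmarks `ceph_landmarks` in mm (scale 1); pixel sets are
#'   rescaled automatically via their `mm_per_px`.
#' @param constants `facebow_constants`.
#' @param axis_direction `"facebow"` (default) places Ax along the
#'   face-bow plane direction eta, consistent with the triangle solution;
#'   `"strict"` uses the alpha direction instead (sub-millimetre
#'   difference for typical anatomy, kept for comparability).
#' @param permissive if `TRUE`, an exactly flat hinge-to-incisor line
#'   (omega = 0) returns the limit case `d_up = 0`,
#'   `d_post = ||Ax - Ie||` instead of erroring. Negative omega always
#'   errors.
#' @return object of class `mounting_parameters` with fields `theta`,
#'   `lambda_deg`, `phi`, `omega` (degrees), `dist_Ax_Ie`, `d_up`,
#'   `d_post` (mm), `Ax` (image coordinates) and the `facebow` geometry.
#' @export
hinge_axis_parameters <- function(landmarks,
                                  constants = facebow_constants(),
                                  axis_direction = c("facebow", "strict"),
                                  permissive = FALSE) {
  stopifnot(inherits(landmarks, "ceph_landmarks"))
  axis_direction <- match.arg(axis_direction)
  if (landmarks$mm_per_px != 1) landmarks <- scale_landmarks(landmarks)

  fb <- facebow_geometry(landmarks$Pi, landmarks$Ns, constants)
  theta <- occlusal_plane_angle(landmarks$Ie, landmarks$Dc)
  lambda <- mounting_angle(theta, fb$eta)

  dir_deg <- if (axis_direction == "facebow") fb$eta else fb$alpha
  dir <- deg2rad(dir_deg)
  # anterior is toward Ie; with the enforced image convention this is +x
  s <- if (landmarks$Ie[1] >= landmarks$Pi[1]) 1 else -1
  Ax <- landmarks$Pi + s * constants$axis_anterior_offset * c(cos(dir), sin(dir))

  if (landmarks$Ie[1] == Ax[1]) {
    degenerate_geometry("Ie lies vertically above/below the hinge axis: phi undefined")
  }
  phi <- rad2deg(atan((landmarks$Ie[2] - Ax[2]) / (landmarks$Ie[1] - Ax[1])))
  # ||Ax-Ie|| = (y_Ie - y_Ax)/sin(phi) for anterior-facing input; the
  # Euclidean norm is the same quantity and stays defined at phi = 0
  dist_Ax_Ie <- vnorm(landmarks$Ie - Ax)
  omega <- phi - theta

  if (omega < 0 || (omega == 0 && !permissive)) {
    degenerate_geometry(sprintf(
      "omega = %.4f deg: hinge axis at or below the occlusal plane; check landmarks", omega))
  }
  if (omega == 0) {
    d_up <- 0
    d_post <- dist_Ax_Ie
  } else {
    w <- deg2rad(omega)
    d_up <- sin(w) * dist_Ax_Ie
    d_post <- d_up / tan(w)
  }

  structure(list(
    theta = theta, lambda_deg = lambda, phi = phi, omega = omega,
    dist_Ax_Ie = dist_Ax_Ie, d_up = d_up, d_post = d_post,
    Ax = Ax, facebow = fb
  ), class = "mounting_parameters")
}

#' @export
print.mounting_parameters <- function(x, ...) {
  # reported to 0.1 deg / 0.1 mm like a planning sheet; stored values are
  # never rounded
  cat("Articulator mounting parameters\n")
  cat(sprintf("  occlusal plane vs horizontal (theta): %6.1f deg\n", x$theta))
  cat(sprintf("  face-bow plane vs horizontal (eta):   %6.1f deg\n", x$facebow$eta))
  cat(sprintf("  occlusal plane vs AOP (lambda):       %6.1f deg\n", x$lambda_deg))
  cat(sprintf("  hinge axis above occlusal plane:      %6.1f mm\n", x$d_up))
  cat(sprintf("  incisor edge to axis foot point:      %6.1f mm\n", x$d_post))
  cat(sprintf("  hinge axis to incisor edge:           %6.1f mm\n", x$dist_Ax_Ie))
  invisible(x)
}

#' @export
print.facebow_geometry <- function(x, ...) {
  cat("Face-bow geometry\n")
  cat(sprintf("  ||Pi-Ns|| %.2f mm, ||Pi-b|| %.2f mm\n", x$dist_Pi_Ns, x$dist_Pi_b))
  cat(sprintf("  alpha %.2f deg, epsilon %.2f deg, eta %.2f deg\n",
              x$alpha, x$epsilon, x$eta))
  invisible(x)
}
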
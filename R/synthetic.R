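# Synthetic ground-truth cases. A known 3D mounting configuration (mounting
# angle lambda, hinge-axis height d_up and foot distance d_post, face-bow
# length, occlusal cant) is turned into: toy jaw meshes with named
# landmarks, a lateral "cephalogram" by orthographic projection into the
# image convention, and frontal-photo landmarks. Recomputing the mounting
# parameters from the projected landmarks must reproduce the stored truth —
# that round trip is the package's core correctness machinery.
#
# The radiograph is constructed the way a cephalostat orients it: face-bow
# plane (AOP) horizontal, nasal rest on the inferior side of that plane.
# Under this orientation the face-bow trigonometry is exact. head_tilt_deg
# deviates from it: eta and omega (hence d_up/d_post) are still recovered
# exactly, but lambda = theta + eta picks up twice the tilt — which is why
# the knob defaults to 0 (see the methods vignette).

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Synthetic case configuration
#'
#' The stated world of the generator. Defaults reproduce the magnitude of a
#' typical clinical mounting: lambda 7.8 deg, hinge axis 35.8 mm above the
#' occlusal plane and 89.9 mm behind the incisor edge; arch dimensions are
#' an average adult maxillary arch. `head_tilt_deg` (radiograph head
#' posture) and `photo_roll_deg` (camera roll) are drawn once from the seed
#' when not supplied, so distinct seeds give distinct but fully
#' deterministic cases.
#'
#' @param lambda_true mounting angle occlusal plane vs AOP (degrees).
#' @param d_up_true hinge-axis height above the occlusal plane (mm).
#' @param d_post_true incisor edge to perpendicular foot distance (mm).
#' @param pi_ns_dist ear-rod to nasal-rest distance (mm); must exceed the
#'   30 mm nasal-rest offset.
#' @param dc_dist Ie-to-Dc distance along the occlusal plane (mm).
#' @param cant_true transverse occlusal cant (degrees, positive =
#'   patient-left inferior).
#' @param midline_offset_true dental midline offset (mm, positive toward
#'   patient-left).
#' @param arch_width distance between the posterior occlusal landmarks
#'   (mm).
#' @param arch_depth antero-posterior arch length (mm).
#' @param arch_band,arch_height cross-section of the toy arch solid (mm).
#' @param tooth_count controls mesh resolution (segments per hemi-arch).
#' @param gap_mm interocclusal gap of the constructed occlusion (mm).
#' @param head_tilt_deg radiograph head tilt away from the AOP-level
#'   cephalostat orientation (degrees). Default 0: the printed face-bow
#'   trigonometry is exact for an AOP-level image; a tilt biases the
#'   recovered lambda by twice the tilt while eta, omega, d_up and d_post
#'   stay exact (see the methods vignette).
#' @param photo_roll_deg frontal-photo camera roll; `NA` = drawn from the
#'   seed (uniform +/-5 deg). The cant is a relative angle and is invariant
#'   under roll.
#' @param jitter_sd Gaussian landmark jitter on the 2D projections (mm),
#'   default 0 (exact).
#' @param mm_per_px cephalogram scale used to express landmarks in pixels.
#' @param seed integer seed.
#' @return object of class `synthetic_case_config`.
#' @export
synthetic_case_config <- function(lambda_true = 7.8, d_up_true = 35.8,
                                  d_post_true = 89.9, pi_ns_dist = 105,
                                  dc_dist = 40,
                                  cant_true = 0, midline_offset_true = 0,
                                  arch_width = 60, arch_depth = 45,
                                  arch_band = 8, arch_height = 8,
                                  tooth_count = 14, gap_mm = 0.05,
                                  head_tilt_deg = 0, photo_roll_deg = NA,
                                  jitter_sd = 0, mm_per_px = 0.1, seed = 1L) {
  if (pi_ns_dist <= 30) om_error("config_error", "pi_ns_dist must exceed the 30 mm nasal-rest offset")
  if (d_up_true <= 0 || d_post_true <= 0) om_error("config_error", "hinge-axis distances must be positive")
  for (v in c(arch_width, arch_depth, arch_band, arch_height, dc_dist, mm_per_px)) {
    if (!is.finite(v) || v <= 0) om_error("config_error", "dimensions must be positive")
  }
  if (arch_band >= arch_width / 2 || arch_band >= arch_depth) {
    om_error("config_error", "arch_band must be smaller than half the width and the depth")
  }
  if (is.na(head_tilt_deg)) head_tilt_deg <- 0
  if (is.na(photo_roll_deg)) {
    photo_roll_deg <- with_seed(seed, stats::runif(1, -5, 5))
  }
  structure(list(
    lambda_true = lambda_true, d_up_true = d_up_true, d_post_true = d_post_true,
    pi_ns_dist = pi_ns_dist, dc_dist = dc_dist,
    cant_true = cant_true, midline_offset_true = midline_offset_true,
    arch_width = arch_width, arch_depth = arch_depth,
    arch_band = arch_band, arch_height = arch_height,
    tooth_count = as.integer(tooth_count), gap_mm = gap_mm,
    head_tilt_deg = head_tilt_deg, photo_roll_deg = photo_roll_deg,
    jitter_sd = jitter_sd, mm_per_px = mm_per_px, seed = as.integer(seed)
  ), class = "synthetic_case_config")
}

# Watertight prism between two polylines P and Q (n x 2 matrices of (x, z)
# points) extruded over y in [y0, y1]. Faces are flipped, if needed, so the
# enclosed volume is positive.
strip_prism <- function(P, Q, y0, y1) {
  n <- nrow(P)
  stopifnot(nrow(Q) == n, y1 > y0)
  mk <- function(poly2, y) cbind(poly2[, 1], y, poly2[, 2])
  V <- rbind(mk(P, y0), mk(Q, y0), mk(P, y1), mk(Q, y1))
  iP0 <- seq_len(n); iQ0 <- n + iP0; iP1 <- 2L * n + iP0; iQ1 <- 3L * n + iP0
  quads <- list()
  addq <- function(a, b, c, d) quads[[length(quads) + 1L]] <<- cbind(a, b, c, a, c, d)
  j <- seq_len(n - 1L)
  addq(iP0[j], iP0[j + 1L], iQ0[j + 1L], iQ0[j])   # bottom cap
  addq(iP1[j], iQ1[j], iQ1[j + 1L], iP1[j + 1L])   # top cap
  addq(iP0[j], iP1[j], iP1[j + 1L], iP0[j + 1L])   # outer wall
  addq(iQ0[j], iQ0[j + 1L], iQ1[j + 1L], iQ1[j])   # inner wall
  addq(iP0[1L], iQ0[1L], iQ1[1L], iP1[1L])         # end wall at start
  addq(iP0[n], iP1[n], iQ1[n], iQ0[n])             # end wall at end
  F <- matrix(t(do.call(rbind, quads)), ncol = 3L, byrow = TRUE)
  m <- tri_mesh(V, F)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

merge_meshes <- function(a, b) {
  tri_mesh(rbind(a$vertices, b$vertices),
           rbind(a$faces, b$faces + nrow(a$vertices)))
}

#' Generate a toy dental-arch jaw mesh
#'
#' A watertight parametric arch: a parabolic U-shaped band solid (plus, for
#' the maxilla, a midline palate plate carrying the raphe landmarks) in the
#' canonical mounted pose — occlusal surface on the ground plane `y = 0`
#' (the mandibular copy sits `gap_mm` below it), incisor edge on the
#' mid-sagittal plane at `z = arch_depth`, anterior +z, patient-left +x.
#' All named landmarks are exact mesh vertices. Fully deterministic.
#'
#' @param config `synthetic_case_config`.
#' @param jaw `"maxilla"` or `"mandible"`.
#' @return `jaw_model` with pivots `Ie`, `occ_left`, `occ_right` and (for
#'   the maxilla) `raphe_ant`, `raphe_post`.
#' @export
generate_arch_mesh <- function(config, jaw = c("maxilla", "mandible")) {
  stopifnot(inherits(config, "synthetic_case_config"))
  jaw <- match.arg(jaw)
  w2 <- config$arch_width / 2
  dep <- config$arch_depth
  b <- config$arch_band
  n <- 2L * config$tooth_count + 1L
  t <- seq(-1, 1, length.out = n)
  # incisor edge at the origin (the mounted-pose convention), arch
  # extending posteriorly (-z)
  outer <- cbind(w2 * t, dep * (1 - t^2) - dep)
  inner <- cbind((w2 - b) * t, (dep - b) * (1 - t^2) - dep)

  if (jaw == "maxilla") { y_occ <- 0; y_top <- config$arch_height }
  else { y_occ <- -config$gap_mm; y_top <- y_occ - config$arch_height }
  y0 <- min(y_occ, y_top); y1 <- max(y_occ, y_top)
  mesh <- strip_prism(outer, inner, y0, y1)

  piv <- list(
    Ie = c(0, y_occ, 0),
    occ_left = c(w2, y_occ, -dep),
    occ_right = c(-w2, y_occ, -dep))

  if (jaw == "maxilla") {
    z0 <- b - dep; z1 <- -b - 2
    plateP <- cbind(c(-1, 0, 1), c(z0, z0, z0))
    plateQ <- cbind(c(-1, 0, 1), c(z1, z1, z1))
    plate <- strip_prism(plateP, plateQ, y1 - 2, y1)
    mesh <- merge_meshes(mesh, plate)
    piv$raphe_ant <- c(0, y1, z1)
    piv$raphe_post <- c(0, y1, z0)
  }
  jaw_model(mesh, label = jaw, stage = "preop", pivots = piv)
}

# Sagittal ground-truth construction, patient frame (y up, z anterior),
# mid-sagittal x = 0. Pi at the origin; AOP (face-bow plane) horizontal
# before head tilt; nasal rest 30 mm on the inferior side of the face-bow
# plane (the configuration under which eta = epsilon - alpha is exact).
sagittal_truth_points <- function(config) {
  lam <- deg2rad(config$lambda_true)
  u_occ <- c(-sin(lam), cos(lam))   # (y, z) unit vector, anterior along occlusal plane
  n_occ <- c(cos(lam), sin(lam))    # unit normal, away from the occlusal plane upward
  Pi <- c(0, 0)
  Ax <- c(0, 10)
  Ns <- c(-30, sqrt(config$pi_ns_dist^2 - 900))
  Ie <- Ax + config$d_post_true * u_occ - config$d_up_true * n_occ
  Dc <- Ie - config$dc_dist * u_occ
  list(Pi = Pi, Ax = Ax, Ns = Ns, Ie = Ie, Dc = Dc)
}

#' Project the 3D ground-truth configuration to 2D cephalometric landmarks
#'
#' Orthographic projection of the sagittal construction onto the image
#' plane, after tilting the head by `head_tilt_deg` (so the face-bow plane
#' is generally oblique in the image, exercising the full trigonometry).
#' Image convention: origin top-left, y down, patient facing image-right.
#' Coordinates are expressed in pixels at `mm_per_px`, with optional
#' Gaussian jitter.
#'
#' @param config `synthetic_case_config`.
#' @return `ceph_landmarks` (pixel coordinates, `mm_per_px` recorded).
#' @export
lateral_project <- function(config) {
  stopifnot(inherits(config, "synthetic_case_config"))
  pts <- sagittal_truth_points(config)[c("Pi", "Ns", "Ie", "Dc")]
  psi <- deg2rad(config$head_tilt_deg)
  proj <- lapply(pts, function(p) {
    y <- p[1] * cos(psi) - p[2] * sin(psi)   # rotate about the x axis
    z <- p[1] * sin(psi) + p[2] * cos(psi)
    c(z + 100, 150 - y)                      # image frame: x anterior, y flipped
  })
  if (config$jitter_sd > 0) {
    proj <- with_seed(config$seed + 101L, lapply(proj, function(p) {
      p + stats::rnorm(2, sd = config$jitter_sd)
    }))
  }
  ceph_landmarks(proj$Pi / config$mm_per_px, proj$Ns / config$mm_per_px,
                 proj$Ie / config$mm_per_px, proj$Dc / config$mm_per_px,
                 mm_per_px = config$mm_per_px)
}

frontal_truth_landmarks <- function(config) {
  r <- deg2rad(config$photo_roll_deg)
  cant <- deg2rad(config$cant_true)
  u_pup <- c(cos(r), sin(r))                 # image direction toward patient-left
  u_occ <- c(cos(r + cant), sin(r + cant))
  pup_c <- c(90, 60); occ_c <- pup_c + 45 * c(-sin(r), cos(r))
  midline_ref <- occ_c - 10 * c(-sin(r), cos(r))
  frontal_landmarks(
    pupil_left = pup_c + 31 * u_pup, pupil_right = pup_c - 31 * u_pup,
    occ_left = occ_c + 25 * u_occ, occ_right = occ_c - 25 * u_occ,
    dental_midline = midline_ref + config$midline_offset_true * u_pup,
    facial_midline_ref = midline_ref,
    mm_per_px = 1)
}

#' Generate a complete synthetic case
#'
#' Bundles everything a planning session needs, with known truth: maxilla
#' and mandible meshes in a constructed occlusion (optionally displaced
#' into a random scanner pose), the five maxillary alignment landmarks, the
#' projected cephalometric and frontal landmark sets, and the ground-truth
#' mounting parameters.
#'
#' @param config `synthetic_case_config`.
#' @param scanner_pose if `TRUE` (default), both jaws are moved by a
#'   random (seed-determined) rigid motion emulating an arbitrary scanner
#'   export frame, so the alignment step has real work to do.
#' @return object of class `synthetic_case` with elements `maxilla`,
#'   `mandible`, `mesh_landmarks`, `ceph_landmarks`, `frontal_landmarks`,
#'   `truth` (lambda/d_up/d_post/..., hinge point in canonical and mounted
#'   frames) and `config`.
#' @export
generate_synthetic_case <- function(config = synthetic_case_config(),
                                    scanner_pose = TRUE) {
  stopifnot(inherits(config, "synthetic_case_config"))
  maxilla <- generate_arch_mesh(config, "maxilla")
  mandible <- generate_arch_mesh(config, "mandible")
  mesh_landmarks <- lapply(maxilla$pivots, `[[`, "position")

  lam <- deg2rad(config$lambda_true)
  omega <- rad2deg(atan2(config$d_up_true, config$d_post_true))
  # image-frame angles: a head tilt (flexion positive) adds to both the
  # occlusal and face-bow image angles
  theta <- config$lambda_true + config$head_tilt_deg
  truth <- list(
    lambda_deg = config$lambda_true,
    d_up = config$d_up_true,
    d_post = config$d_post_true,
    dist_Ax_Ie = sqrt(config$d_up_true^2 + config$d_post_true^2),
    omega = omega,
    theta = theta,
    eta = config$head_tilt_deg,
    phi = omega + theta,
    cant_deg = config$cant_true,
    midline_offset_mm = config$midline_offset_true,
    # hinge axis in the canonical (pre-AOP-rotation) world frame, Ie at origin
    hinge_canonical = c(0, config$d_up_true, -config$d_post_true),
    # its height above Ie once the scene is rotated to the AOP
    hinge_mounted_height = config$d_up_true * cos(lam) + config$d_post_true * sin(lam)
  )

  if (scanner_pose) {
    tf <- with_seed(config$seed + 202L, {
      ax <- stats::rnorm(3)
      compose_transforms(
        rigid_transform(translation = stats::runif(3, -20, 20)),
        rotation_about_axis(ax, stats::runif(1, -180, 180), center = c(0, 0, 0)))
    })
    maxilla <- transform_jaw(maxilla, tf, "scanner_pose")
    mandible <- transform_jaw(mandible, tf, "scanner_pose")
    mesh_landmarks <- lapply(mesh_landmarks, function(p) transform_points(tf, p))
  }

  structure(list(
    maxilla = maxilla, mandible = mandible,
    mesh_landmarks = mesh_landmarks,
    ceph_landmarks = lateral_project(config),
    frontal_landmarks = frontal_truth_landmarks(config),
    truth = truth, config = config
  ), class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> seed %d: lambda %.2f deg, d_up %.1f mm, d_post %.1f mm, cant %.1f deg\n",
              x$config$seed, x$truth$lambda_deg, x$truth$d_up, x$truth$d_post,
              x$truth$cant_deg))
  invisible(x)
}
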
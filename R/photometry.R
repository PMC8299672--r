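# Transverse assessment from a frontal photograph: occlusal cant against
# the interpupillary line, optional dental midline offset. Angles need no
# photo scale; the millimetre midline offset does.

#' Frontal-photo landmark set
#'
#' Pupils and the outermost visible occlusal contact points on each side,
#' in image convention (y down). Patient-left appears at larger image x in
#' a conventionally viewed (non-mirrored) frontal photograph.
#'
#' @param pupil_left,pupil_right,occ_left,occ_right mandatory (x, y) pairs;
#'   `*_left` means the patient's left side.
#' @param dental_midline,facial_midline_ref optional (x, y) pairs for the
#'   upper dental midline and a mid-sagittal reference point.
#' @param mm_per_px optional photo scale; required only for a millimetre
#'   midline offset.
#' @return object of class `frontal_landmarks`.
#' @export
frontal_landmarks <- function(pupil_left, pupil_right, occ_left, occ_right,
                              dental_midline = NULL, facial_midline_ref = NULL,
                              mm_per_px = NULL) {
  req <- list(pupil_left = pupil_left, pupil_right = pupil_right,
              occ_left = occ_left, occ_right = occ_right)
  for (nm in names(req)) {
    if (is.null(req[[nm]])) missing_landmark(sprintf("landmark '%s' is missing", nm))
    req[[nm]] <- point2(req[[nm]])
  }
  if (all(req$pupil_left == req$pupil_right)) degenerate_geometry("pupils coincide")
  if (all(req$occ_left == req$occ_right)) degenerate_geometry("occlusal points coincide")
  if (!is.null(mm_per_px) && (!is.finite(mm_per_px) || mm_per_px <= 0)) {
    om_error("config_error", "mm_per_px must be positive")
  }
  structure(c(req, list(
    dental_midline = if (is.null(dental_midline)) NULL else point2(dental_midline),
    facial_midline_ref = if (is.null(facial_midline_ref)) NULL else point2(facial_midline_ref),
    mm_per_px = mm_per_px
  )), class = "frontal_landmarks")
}

# angle of the right-to-left direction of a landmark pair, image frame
line_angle_rad <- function(right, left) atan2(left[2] - right[2], left[1] - right[1])

#' Occlusal cant and dental midline offset
#'
#' Quantifies the transverse inclination of the maxillary occlusal plane as
#' the signed angle between the occlusal line and the interpupillary line.
#' Sign convention: positive cant means the patient-left side of the
#' occlusal plane lies inferior to a line drawn parallel to the
#' interpupillary line. The midline offset (positive toward the patient's
#' left) is reported only when both midline points and a photo scale are
#' available; otherwise it is `NA`.
#'
#' @param landmarks `frontal_landmarks`.
#' @return object of class `transverse_assessment` with `cant_deg` and
#'   `midline_offset_mm` (possibly `NA`).
#' @export
occlusal_cant <- function(landmarks) {
  stopifnot(inherits(landmarks, "frontal_landmarks"))
  a_pup <- line_angle_rad(landmarks$pupil_right, landmarks$pupil_left)
  a_occ <- line_angle_rad(landmarks$occ_right, landmarks$occ_left)
  cant <- rad2deg(a_occ - a_pup)
  # lines are undirected: fold into (-90, 90]
  cant <- ((cant + 90) %% 180) - 90
  if (cant == -90) cant <- 90

  offset <- NA_real_
  if (!is.null(landmarks$dental_midline) && !is.null(landmarks$facial_midline_ref) &&
      !is.null(landmarks$mm_per_px)) {
    u <- normalize(c(landmarks$pupil_left - landmarks$pupil_right, 0))[1:2]
    offset <- sum((landmarks$dental_midline - landmarks$facial_midline_ref) * u) *
      landmarks$mm_per_px
  }
  structure(list(cant_deg = cant, midline_offset_mm = offset),
            class = "transverse_assessment")
}

#' @export
print.transverse_assessment <- function(x, ...) {
  cat(sprintf("Occlusal cant: %.1f deg (positive = patient-left inferior)\n", x$cant_deg))
  if (is.na(x$midline_offset_mm)) {
    cat("Dental midline offset: not measured (needs midline points + scale)\n")
  } else {
    cat(sprintf("Dental midline offset: %.1f mm toward patient-%s\n",
                abs(x$midline_offset_mm),
                if (x$midline_offset_mm >= 0) "left" else "right"))
  }
  invisible(x)
}
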
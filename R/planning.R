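# Virtual model surgery: clone jaws, apply planned rigid movements,
# measure per-pivot displacements, open-rotate the mandible for the final
# splint, and assemble the splint export sets. Preoperative jaws are never
# mutated; every planned state is a clone.

#' Planned rigid movement of one jaw
#'
#' A rotation about a stated centre followed by a translation. The centre
#' may be a pivot name (resolved on the jaw at application time, matching
#' the workflow of switching the transform widget onto a pivot) or an
#' explicit point.
#'
#' @param translation 3-vector (mm), default none.
#' @param axis rotation axis direction (unit up to normalization); required
#'   when `angle_deg != 0`.
#' @param angle_deg rotation angle (degrees), default 0.
#' @param center pivot name (character) or 3-vector; default the jaw's
#'   `"Ie"`-less origin `c(0,0,0)` is NOT assumed — a centre must be given
#'   with a nonzero rotation.
#' @return object of class `planned_move`.
#' @export
planned_move <- function(translation = c(0, 0, 0), axis = NULL, angle_deg = 0,
                         center = NULL) {
  translation <- as_point3(translation)
  if (angle_deg != 0) {
    if (is.null(axis)) om_error("config_error", "a rotation needs an axis")
    if (is.null(center)) om_error("config_error", "a rotation needs a center")
    axis <- normalize(as_point3(axis))
  }
  structure(list(translation = translation, axis = axis,
                 angle_deg = angle_deg, center = center),
            class = "planned_move")
}

#' Clone a jaw for planning
#'
#' Deep copy with `stage = "postop"`; the original stays untouched in its
#' unoperated position and remains the reference for displacement
#' measurements. Clones are independent and unlimited.
#'
#' @param jaw `jaw_model`.
#' @return the postop clone.
#' @export
clone_jaw <- function(jaw) {
  stopifnot(inherits(jaw, "jaw_model"))
  jaw$stage <- "postop"
  jaw
}

#' Apply a planned move to a jaw
#'
#' Rotation about the move's centre, then translation; mesh and pivots move
#' together.
#'
#' @param jaw `jaw_model` (normally a postop clone).
#' @param move `planned_move`.
#' @return moved `jaw_model`.
#' @export
move_jaw <- function(jaw, move) {
  stopifnot(inherits(jaw, "jaw_model"), inherits(move, "planned_move"))
  tf <- rigid_transform(translation = move$translation)
  if (move$angle_deg != 0) {
    ctr <- if (is.character(move$center)) pivot_position(jaw, move$center)
           else as_point3(move$center)
    tf <- compose_transforms(tf, rotation_about_axis(move$axis, move$angle_deg, ctr))
  }
  transform_jaw(jaw, tf, "planned_move")
}

#' Measure pivot displacements between stages
#'
#' Per-pivot pre/post coordinates, signed X/Y/Z deltas (post minus pre, in
#' the mounted world frame: x patient-left, y up, z anterior) and the
#' Euclidean displacement. Rows are ordered by pivot name for a stable
#' planning-sheet table.
#'
#' @param pre,post `jaw_model`s with identical pivot name sets.
#' @return `data.frame` of class `displacement_report`.
#' @export
measure_displacements <- function(pre, post) {
  stopifnot(inherits(pre, "jaw_model"), inherits(post, "jaw_model"))
  if (!setequal(names(pre$pivots), names(post$pivots))) {
    pivot_mismatch(sprintf("pivot sets differ: pre {%s} vs post {%s}",
                           paste(names(pre$pivots), collapse = ","),
                           paste(names(post$pivots), collapse = ",")))
  }
  nms <- sort(names(pre$pivots))
  rows <- lapply(nms, function(nm) {
    a <- pre$pivots[[nm]]$position
    b <- post$pivots[[nm]]$position
    d <- b - a
    data.frame(pivot = nm,
               pre_x = a[1], pre_y = a[2], pre_z = a[3],
               post_x = b[1], post_y = b[2], post_z = b[3],
               dx = d[1], dy = d[2], dz = d[3],
               euclidean = vnorm(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("displacement_report", "data.frame")
  out
}

#' Open rotation of the mandible for the final splint
#'
#' Rotates the (postoperative) mandible about the hinge-axis pivot in the
#' mouth-opening sense: the lower incisor moves inferiorly and posteriorly
#' while the hinge pivot stays fixed. Roughly two degrees creates the
#' interocclusal space for the final splint thickness.
#'
#' @param mandible `jaw_model`.
#' @param hinge the `"hinge_axis"` [pivot()].
#' @param angle_deg opening angle in degrees (>= 0), default 2.
#' @return rotated `jaw_model`.
#' @export
open_rotation <- function(mandible, hinge, angle_deg = 2) {
  stopifnot(inherits(mandible, "jaw_model"), inherits(hinge, "pivot"))
  if (angle_deg < 0) om_error("config_error", "open rotation angle must be >= 0")
  if (angle_deg == 0) return(mandible)
  # +x right-hand rotation moves anterior points (+z) below the hinge
  # downward and backward: the opening sense
  tf <- rotation_about_axis(c(1, 0, 0), angle_deg, center = hinge$position)
  transform_jaw(mandible, tf, "open_rotation")
}

#' Surgical plan container
#'
#' Holds the unoperated jaws, their planned (postop) clones and the hinge
#' pivot; input to splint export and the planning sheet.
#'
#' @param preop_maxilla,preop_mandible unoperated `jaw_model`s.
#' @param postop_maxilla,postop_mandible planned clones (either may be
#'   `NULL` for single-jaw surgery).
#' @param hinge_pivot the `"hinge_axis"` [pivot()].
#' @param open_rotation_deg final-splint opening angle, default 2.
#' @return object of class `surgical_plan`.
#' @export
surgical_plan <- function(preop_maxilla, preop_mandible,
                          postop_maxilla = NULL, postop_mandible = NULL,
                          hinge_pivot = NULL, open_rotation_deg = 2) {
  structure(list(preop_maxilla = preop_maxilla, preop_mandible = preop_mandible,
                 postop_maxilla = postop_maxilla, postop_mandible = postop_mandible,
                 hinge_pivot = hinge_pivot,
                 open_rotation_deg = open_rotation_deg),
            class = "surgical_plan")
}

need_stage <- function(plan, field, what) {
  j <- plan[[field]]
  if (is.null(j)) missing_stage(sprintf("scenario requires %s but the plan has none", what))
  j
}

#' Export the splint-fabrication STL set
#'
#' Writes the meshes a splint-design tool needs, all in the common mounted
#' scene frame and without any re-centering, so downstream CAD sees the
#' true relative poses:
#' \itemize{
#'   \item `lower_only`: preop maxilla + open-rotated postop mandible (2
#'     files).
#'   \item `upper_only`: postop maxilla + open-rotated preop mandible (2
#'     files).
#'   \item `bimaxillary`: postop maxilla, preop mandible (intermediate
#'     splint) and open-rotated postop mandible (final splint) — exactly 3
#'     files.
#' }
#'
#' @param plan `surgical_plan` with a hinge pivot.
#' @param scenario one of `"upper_only"`, `"lower_only"`, `"bimaxillary"`.
#' @param dir output directory (created if needed).
#' @param ascii write ASCII STL instead of binary.
#' @return object of class `splint_export_set`: scenario + a member table
#'   (jaw, stage, open_rotated, file).
#' @export
export_splint_set <- function(plan, scenario = c("bimaxillary", "upper_only", "lower_only"),
                              dir, ascii = FALSE) {
  stopifnot(inherits(plan, "surgical_plan"))
  scenario <- match.arg(scenario)
  if (is.null(plan$hinge_pivot)) missing_stage("splint export needs the hinge-axis pivot")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  rot <- function(mand) open_rotation(mand, plan$hinge_pivot, plan$open_rotation_deg)
  members <- switch(scenario,
    lower_only = list(
      list(jaw = need_stage(plan, "preop_maxilla", "a preop maxilla"),
           open_rotated = FALSE, file = "maxilla_preop.stl"),
      list(jaw = rot(need_stage(plan, "postop_mandible", "a postop mandible")),
           open_rotated = TRUE, file = "mandible_postop_open.stl")),
    upper_only = list(
      list(jaw = need_stage(plan, "postop_maxilla", "a postop maxilla"),
           open_rotated = FALSE, file = "maxilla_postop.stl"),
      list(jaw = rot(need_stage(plan, "preop_mandible", "a preop mandible")),
           open_rotated = TRUE, file = "mandible_preop_open.stl")),
    bimaxillary = list(
      list(jaw = need_stage(plan, "postop_maxilla", "a postop maxilla"),
           open_rotated = FALSE, file = "maxilla_postop.stl"),
      list(jaw = need_stage(plan, "preop_mandible", "a preop mandible"),
           open_rotated = FALSE, file = "mandible_preop.stl"),
      list(jaw = rot(need_stage(plan, "postop_mandible", "a postop mandible")),
           open_rotated = TRUE, file = "mandible_postop_open.stl")))

  tab <- do.call(rbind, lapply(members, function(m) {
    write_stl(m$jaw$mesh, file.path(dir, m$file), ascii = ascii,
              name = sub("\\.stl$", "", m$file))
    data.frame(jaw = m$jaw$label, stage = m$jaw$stage,
               open_rotated = m$open_rotated, file = m$file)
  }))
  structure(list(scenario = scenario, members = tab, dir = dir),
            class = "splint_export_set")
}

#' @export
print.splint_export_set <- function(x, ...) {
  cat(sprintf("<splint_export_set> %s: %d STL files in %s\n",
              x$scenario, nrow(x$members), x$dir))
  print(x$members)
  invisible(x)
}

#' Write the machine-readable planning sheet
#'
#' Serializes everything the planning team needs into `sheet.json` plus a
#' `displacements.csv` table: mounting parameters, photo assessment,
#' per-pivot displacement table, contact summary and the splint manifest.
#' Sections that were not computed are simply omitted.
#'
#' @param dir output directory.
#' @param mounting `mounting_parameters` (required).
#' @param photo optional `transverse_assessment`.
#' @param displacements optional `displacement_report` or named list of
#'   them (one per jaw).
#' @param contacts optional `contact_report`.
#' @param splints optional `splint_export_set`.
#' @return invisible list of written file paths.
#' @export
write_planning_sheet <- function(dir, mounting, photo = NULL,
                                 displacements = NULL, contacts = NULL,
                                 splints = NULL) {
  stopifnot(inherits(mounting, "mounting_parameters"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- list(
    software = paste("orthomount", as.character(utils::packageVersion("orthomount"))),
    frame = WORLD_FRAME,
    mounting = unclass_deep(mounting)
  )
  if (!is.null(photo)) sheet$photo <- unclass_deep(photo)
  files <- character(0)
  if (!is.null(displacements)) {
    if (inherits(displacements, "displacement_report")) {
      displacements <- list(jaw = displacements)
    }
    sheet$displacements <- lapply(displacements, function(d) as.list(as.data.frame(d)))
    csv <- file.path(dir, "displacements.csv")
    all_tab <- do.call(rbind, lapply(names(displacements), function(nm) {
      cbind(jaw = nm, as.data.frame(displacements[[nm]]))
    }))
    utils::write.csv(format(all_tab, digits = 9, trim = TRUE, scientific = FALSE),
                     csv, row.names = FALSE, quote = FALSE)
    files <- c(files, csv)
  }
  if (!is.null(contacts)) sheet$contacts <- contact_summary(contacts)
  if (!is.null(splints)) {
    sheet$splints <- list(scenario = splints$scenario,
                          members = as.list(splints$members))
  }
  json <- file.path(dir, "sheet.json")
  write_json_stable(sheet, json)
  invisible(c(sheet = json, files))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
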
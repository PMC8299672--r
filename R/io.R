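# Landmark file dialects, the scene archive, configuration. Millimetres
# everywhere; STL carries no units so scene.json declares them.

# JSON numbers are written with 9 significant digits so repeated runs
# produce byte-identical, diff-stable reports.
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(9),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read cephalometric landmarks from JSON or CSV
#'
#' JSON dialect: object with keys `"Pi"`, `"Ns"`, `"Ie"`, `"Dc"` (each
#' `[x, y]` or `{"left": [x, y], "right": [x, y]}`) and optional
#' `"mm_per_px"`. CSV dialect: columns `name,x,y[,side]`; rows with side
#' `left`/`right` are averaged.
#'
#' @param path file path (`.json` or `.csv`).
#' @return `ceph_landmarks`.
#' @export
read_ceph_landmarks <- function(path) {
  if (!file.exists(path)) format_error(sprintf("landmark file not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(read_landmarks_csv(path))
  }
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) format_error(sprintf("invalid JSON in %s: %s", path, conditionMessage(e))))
  get_pt <- function(nm) {
    v <- j[[nm]]
    if (is.null(v)) missing_landmark(sprintf("landmark '%s' missing in %s", nm, path))
    if (!is.null(v$left) && !is.null(v$right)) {
      list(left = unlist(v$left), right = unlist(v$right))
    } else {
      unlist(v)
    }
  }
  ceph_landmarks(get_pt("Pi"), get_pt("Ns"), get_pt("Ie"), get_pt("Dc"),
                 mm_per_px = if (is.null(j$mm_per_px)) 1 else j$mm_per_px)
}

read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y") %in% names(d))) {
    format_error("landmark CSV needs columns name,x,y[,side]")
  }
  one <- function(nm) {
    rows <- d[d$name == nm, , drop = FALSE]
    if (nrow(rows) == 0L) missing_landmark(sprintf("landmark '%s' missing in %s", nm, path))
    if (nrow(rows) == 1L) return(c(rows$x, rows$y))
    if (nrow(rows) == 2L) return(average_bilateral(c(rows$x[1], rows$y[1]),
                                                   c(rows$x[2], rows$y[2])))
    format_error(sprintf("landmark '%s' has %d rows (max 2)", nm, nrow(rows)))
  }
  scale_row <- d[d$name == "mm_per_px", , drop = FALSE]
  ceph_landmarks(one("Pi"), one("Ns"), one("Ie"), one("Dc"),
                 mm_per_px = if (nrow(scale_row)) scale_row$x[1] else 1)
}

#' Write cephalometric landmarks to JSON
#'
#' @param landmarks `ceph_landmarks`.
#' @param path output path.
#' @export
write_ceph_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "ceph_landmarks"))
  write_json_stable(list(Pi = landmarks$Pi, Ns = landmarks$Ns,
                         Ie = landmarks$Ie, Dc = landmarks$Dc,
                         mm_per_px = landmarks$mm_per_px), path)
}

#' Read frontal-photo landmarks from JSON
#'
#' Keys: `pupil_left`, `pupil_right`, `occ_left`, `occ_right` (mandatory),
#' `dental_midline`, `facial_midline_ref`, `mm_per_px` (optional).
#'
#' @param path file path.
#' @return `frontal_landmarks`.
#' @export
read_frontal_landmarks <- function(path) {
  if (!file.exists(path)) format_error(sprintf("landmark file not found: %s", path))
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) format_error(sprintf("invalid JSON in %s: %s", path, conditionMessage(e))))
  g <- function(nm) if (is.null(j[[nm]])) NULL else unlist(j[[nm]])
  frontal_landmarks(g("pupil_left"), g("pupil_right"), g("occ_left"), g("occ_right"),
                    dental_midline = g("dental_midline"),
                    facial_midline_ref = g("facial_midline_ref"),
                    mm_per_px = if (is.null(j$mm_per_px)) NULL else j$mm_per_px)
}

#' Serialize mounting parameters to JSON
#'
#' All intermediate angles and distances are written so the planning sheet
#' and downstream tools see the full computation.
#'
#' @param params `mounting_parameters`.
#' @param path output path.
#' @export
write_mounting_parameters <- function(params, path) {
  stopifnot(inherits(params, "mounting_parameters"))
  write_json_stable(unclass_deep(params), path)
}

## ---- configuration -------------------------------------------------------

om_default_config <- function() {
  list(ns_offset = 30, axis_anterior_offset = 10,
       open_rotation_deg = 2, contact_tolerance = 0.1)
}

#' Load the run configuration
#'
#' JSON file overriding the defaults: `ns_offset` (30 mm),
#' `axis_anterior_offset` (10 mm), `open_rotation_deg` (2),
#' `contact_tolerance` (0.1 mm). Unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param path optional path to a JSON config file; `NULL` = all defaults.
#' @return named list of resolved settings.
#' @export
load_config <- function(path = NULL) {
  cfg <- om_default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) config_error(sprintf("invalid config JSON: %s", conditionMessage(e))))
  unknown <- setdiff(names(j), names(cfg))
  if (length(unknown)) {
    config_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (nm in names(j)) {
    v <- j[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      config_error(sprintf("config key '%s' must be a positive number", nm))
    }
    cfg[[nm]] <- v
  }
  cfg
}

## ---- scene archive -------------------------------------------------------

jaw_to_meta <- function(jaw, file) {
  list(label = jaw$label, stage = jaw$stage, file = file,
       pivots = lapply(jaw$pivots, `[[`, "position"),
       log = lapply(jaw$log, function(l) list(op = l$op,
                                              rotation = as.vector(l$rotation),
                                              translation = l$translation)))
}

#' Save a scene as an STL + JSON archive
#'
#' Writes one STL per jaw plus `scene.json` recording pivots, frame
#' metadata, the applied mounting angle, per-jaw transform logs and the
#' software version. Reloading reproduces all pivot coordinates exactly
#' (pivots live in the JSON, not the single-precision STL).
#'
#' @param scene `articulator_scene`.
#' @param dir output directory (created if needed).
#' @param ascii write ASCII STL instead of binary.
#' @return `dir`, invisibly.
#' @export
save_scene <- function(scene, dir, ascii = FALSE) {
  stopifnot(inherits(scene, "articulator_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(maxilla = "maxilla.stl", mandible = "mandible.stl")
  write_stl(scene$maxilla$mesh, file.path(dir, files["maxilla"]), ascii = ascii)
  write_stl(scene$mandible$mesh, file.path(dir, files["mandible"]), ascii = ascii)
  meta <- list(
    software = paste("orthomount", as.character(utils::packageVersion("orthomount"))),
    units = "mm",
    frame = scene$frame,
    lambda_applied = scene$lambda_applied,
    hinge_pivot = if (is.null(scene$hinge_pivot)) NULL else
      list(name = scene$hinge_pivot$name, position = scene$hinge_pivot$position,
           bound_to = scene$hinge_pivot$bound_to),
    jaws = list(maxilla = jaw_to_meta(scene$maxilla, files[["maxilla"]]),
                mandible = jaw_to_meta(scene$mandible, files[["mandible"]]))
  )
  write_json_stable(meta, file.path(dir, "scene.json"))
  invisible(dir)
}

#' Load a scene archive
#'
#' @param dir directory written by [save_scene()].
#' @return `articulator_scene`.
#' @export
load_scene <- function(dir) {
  sj <- file.path(dir, "scene.json")
  if (!file.exists(sj)) format_error(sprintf("no scene.json in %s", dir))
  meta <- jsonlite::read_json(sj)
  read_jaw <- function(m) {
    f <- file.path(dir, m$file)
    if (!file.exists(f)) format_error(sprintf("scene.json references missing file %s", m$file))
    jaw_model(read_stl(f), label = m$label, stage = m$stage,
              pivots = lapply(m$pivots, unlist))
  }
  scene <- articulator_scene(read_jaw(meta$jaws$maxilla), read_jaw(meta$jaws$mandible))
  if (!is.null(meta$hinge_pivot)) {
    scene$hinge_pivot <- pivot(meta$hinge_pivot$name, unlist(meta$hinge_pivot$position),
                               meta$hinge_pivot$bound_to)
  }
  scene$lambda_applied <- meta$lambda_applied
  scene
}
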
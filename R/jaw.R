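# JawModel: a surface mesh with named measurement pivots bound to it.
# Every motion is applied jointly to mesh and pivots, so mesh-to-pivot
# distances are invariants of any planning sequence.

#' Pivot bound to a jaw
#'
#' @param name pivot name, unique within a jaw.
#' @param position 3-vector (mm).
#' @param bound_to jaw label the pivot belongs to.
#' @return object of class `pivot`.
#' @export
pivot <- function(name, position, bound_to = NA_character_) {
  structure(list(name = as.character(name),
                 position = as_point3(position),
                 bound_to = as.character(bound_to)),
            class = "pivot")
}

#' Jaw model: mesh plus pivots
#'
#' @param mesh `tri_mesh` in mm.
#' @param label `"maxilla"` or `"mandible"`.
#' @param stage `"preop"` (unoperated original) or `"postop"` (planning
#'   clone).
#' @param pivots named list of 3-vectors, or list of [pivot()] objects.
#' @return object of class `jaw_model`.
#' @export
jaw_model <- function(mesh, label = c("maxilla", "mandible"),
                      stage = c("preop", "postop"), pivots = list()) {
  label <- match.arg(label)
  stage <- match.arg(stage)
  stopifnot(inherits(mesh, "tri_mesh"))
  pv <- list()
  nms <- names(pivots)
  for (i in seq_along(pivots)) {
    p <- pivots[[i]]
    pv[[i]] <- if (inherits(p, "pivot")) p else pivot(nms[i], p, label)
    pv[[i]]$bound_to <- label
  }
  names(pv) <- vapply(pv, `[[`, character(1), "name")
  if (anyDuplicated(names(pv))) om_error("config_error", "pivot names must be unique within a jaw")
  structure(list(mesh = mesh, label = label, stage = stage, pivots = pv,
                 log = list()),
            class = "jaw_model")
}

#' @export
print.jaw_model <- function(x, ...) {
  cat(sprintf("<jaw_model> %s (%s): %d vertices, %d faces, pivots: %s\n",
              x$label, x$stage, nrow(x$mesh$vertices), nrow(x$mesh$faces),
              if (length(x$pivots)) paste(names(x$pivots), collapse = ", ") else "none"))
  invisible(x)
}

#' Add or replace a pivot on a jaw
#'
#' @param jaw `jaw_model`.
#' @param name pivot name.
#' @param position 3-vector (mm).
#' @return updated `jaw_model`.
#' @export
add_pivot <- function(jaw, name, position) {
  stopifnot(inherits(jaw, "jaw_model"))
  jaw$pivots[[name]] <- pivot(name, position, jaw$label)
  jaw
}

#' Pivot coordinates
#'
#' @param jaw `jaw_model`.
#' @param name pivot name.
#' @return 3-vector (mm).
#' @export
pivot_position <- function(jaw, name) {
  stopifnot(inherits(jaw, "jaw_model"))
  p <- jaw$pivots[[name]]
  if (is.null(p)) unknown_pivot(sprintf("jaw '%s' has no pivot named '%s'", jaw$label, name))
  p$position
}

#' All pivot positions of a jaw as a matrix
#'
#' @param jaw `jaw_model`.
#' @return n x 3 matrix of pivot coordinates (mm), rownames = pivot names.
#' @export
pivot_matrix <- function(jaw) {
  if (!length(jaw$pivots)) return(matrix(numeric(0), ncol = 3L))
  do.call(rbind, lapply(jaw$pivots, `[[`, "position"))
}

#' Apply a rigid transform to a jaw
#'
#' Mesh vertices and all bound pivots move by the same motion; the applied
#' transform is appended to the jaw's transform log.
#'
#' @param jaw `jaw_model`.
#' @param tf `rigid_transform`.
#' @param op label recorded in the transform log.
#' @return transformed `jaw_model`.
#' @export
transform_jaw <- function(jaw, tf, op = "transform") {
  stopifnot(inherits(jaw, "jaw_model"), inherits(tf, "rigid_transform"))
  jaw$mesh$vertices <- transform_points(tf, jaw$mesh$vertices)
  for (nm in names(jaw$pivots)) {
    jaw$pivots[[nm]]$position <- transform_points(tf, jaw$pivots[[nm]]$position)
  }
  jaw$log[[length(jaw$log) + 1L]] <- list(
    op = op, rotation = tf$rotation, translation = tf$translation)
  jaw
}
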
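# Rigid 3D motions and small vector helpers. All lengths in millimetres,
# all user-facing angles in degrees (radians are internal only).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) degenerate_geometry("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_point3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p))) {
    om_error("config_error", "expected a finite 3-vector")
  }
  p
}

#' Construct a rigid transform
#'
#' A proper rigid motion `p -> R p + t` in millimetres. The rotation must be
#' proper orthogonal (`det(R) = +1`); reflections are rejected because jaw
#' meshes must never be mirrored.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as_point3(translation))
  if (!all(dim(rotation) == c(3L, 3L))) {
    om_error("config_error", "rotation must be a 3x3 matrix")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    om_error("config_error", "rotation matrix is not orthogonal")
  }
  if (det(rotation) < 0) {
    om_error("config_error", "rotation matrix is a reflection (det = -1)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation (mm):", paste(signif(x$translation, 7), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf `rigid_transform`.
#' @param pts numeric n x 3 matrix (or length-3 vector) of points in mm.
#' @return Transformed points, same shape as input.
#' @export
transform_points <- function(tf, pts) {
  stopifnot(inherits(tf, "rigid_transform"))
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, nrow = 1L)
  out <- pts %*% t(tf$rotation)
  out <- sweep(out, 2L, tf$translation, "+")
  if (single) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform "first b, then a".
#'
#' @param a,b `rigid_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param tf `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.vector(rt %*% tf$translation))
}

#' Rotation about an arbitrary axis through a point
#'
#' Right-hand-rule rotation by `angle_deg` about the (unit) `axis` placed at
#' `center`; `center` is a fixed point of the motion.
#'
#' @param axis length-3 direction (normalized internally; must be non-zero
#'   when `angle_deg != 0`).
#' @param angle_deg rotation angle in degrees.
#' @param center fixed point of the rotation (mm), default origin.
#' @return `rigid_transform`.
#' @export
rotation_about_axis <- function(axis, angle_deg, center = c(0, 0, 0)) {
  center <- as_point3(center)
  if (angle_deg == 0) return(rigid_transform())
  u <- normalize(as_point3(axis))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3L, 3L)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, center - as.vector(R %*% center))
}

#' Least-squares rigid registration (orthogonal Procrustes, no reflection)
#'
#' Finds the proper rigid motion mapping `source` points onto `target`
#' points with minimal summed squared residuals (Kabsch algorithm; the SVD
#' sign is corrected so the solution is never a reflection). Used to express
#' a bite-scan registration of the mandible to the maxilla.
#'
#' @param source,target n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @return list with `transform` (`rigid_transform`) and `rms` residual (mm).
#' @export
register_bite <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target)) || ncol(source) != 3L) {
    om_error("config_error", "source and target must be matching n x 3 matrices")
  }
  n <- nrow(source)
  if (n < 3L) degenerate_geometry("at least 3 point pairs are required")
  cs <- colMeans(source); ct <- colMeans(target)
  X <- sweep(source, 2L, cs); Y <- sweep(target, 2L, ct)
  # collinearity check: rank of centred cloud must be >= 2
  if (sum(svd(X)$d > max(dim(X)) * .Machine$double.eps * max(vnorm(X))) < 2L ||
      sum(svd(Y)$d > max(dim(Y)) * .Machine$double.eps * max(vnorm(Y))) < 2L) {
    degenerate_geometry("point pairs are collinear or duplicated; registration is not unique")
  }
  H <- crossprod(X, Y)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.vector(R %*% cs)
  tf <- rigid_transform(R, t)
  res <- transform_points(tf, source) - target
  list(transform = tf, rms = sqrt(mean(rowSums(res^2))))
}
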
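# Occlusal contact detection by signed vertex-to-mesh distance. The visual
# "merging" of meshes in an interactive tool is formalized as thresholding:
# a vertex is in contact when its signed distance to the opposing mesh is
# at most the tolerance; negative distance means penetration.

# Closest point on each triangle (a, b, c: k x 3) to point p, Ericson's
# region classification vectorized over triangles.
closest_points_on_triangles <- function(p, a, b, c) {
  k <- nrow(a)
  ab <- b - a; ac <- c - a
  ap <- sweep(-a, 2L, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-b, 2L, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-c, 2L, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  out <- matrix(NA_real_, k, 3L)
  done <- rep(FALSE, k)
  set <- function(mask, pts) {
    mask <- mask & !done
    out[mask, ] <<- pts[mask, , drop = FALSE]
    done <<- done | mask
  }
  set(d1 <= 0 & d2 <= 0, a)                                   # vertex a
  set(d3 >= 0 & d4 <= d3, b)                                  # vertex b
  set(d6 >= 0 & d5 <= d6, c)                                  # vertex c
  v <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * v)                # edge ab
  w <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * w)                # edge ac
  w2 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + (c - b) * w2)  # edge bc
  denom <- 1 / (va + vb + vc)
  set(!done, a + ab * (vb * denom) + ac * (vc * denom))       # interior
  out
}

# Ray-triangle parity test (Moller-Trumbore), vectorized over triangles.
# Direction is a fixed irrational-ish vector so axis-aligned fixture
# geometry does not graze edges.
points_inside_mesh <- function(points, mesh) {
  fc <- face_corners(mesh)
  dir <- normalize(c(0.57735027, 0.21132487, 0.78867513))
  e1 <- fc$b - fc$a
  e2 <- fc$c - fc$a
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    tv <- sweep(-fc$a, 2L, p, "+")
    u <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    v <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
    t <- rowSums(e2 * qv) / det
    hits <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > 1e-12
    (sum(hits) %% 2L) == 1L
  }, logical(1))
}

#' Signed distance from points to a mesh
#'
#' Unsigned distance is the exact minimum over all triangles
#' (point-to-triangle closest-point computation); the sign is negative for
#' points inside the mesh (ray-parity test — meaningful only for closed
#' meshes).
#'
#' @param points n x 3 matrix (mm).
#' @param mesh `tri_mesh`.
#' @return numeric vector of signed distances (mm).
#' @export
signed_mesh_distance <- function(points, mesh) {
  single <- is.null(dim(points))
  if (single) points <- matrix(points, nrow = 1L)
  fc <- face_corners(mesh)
  d <- vapply(seq_len(nrow(points)), function(i) {
    cp <- closest_points_on_triangles(points[i, ], fc$a, fc$b, fc$c)
    sqrt(min(rowSums(sweep(cp, 2L, points[i, ])^2)))
  }, numeric(1))
  inside <- points_inside_mesh(points, mesh)
  d[inside] <- -d[inside]
  if (single) d[1] else d
}

#' Detect occlusal contacts between two jaws
#'
#' Symmetric evaluation: vertices of each mesh whose signed distance to the
#' opposing mesh is at most `tolerance` are reported, with their signed
#' distances (negative = penetrating). This is the quantitative counterpart
#' of colour-highlighted mesh collisions during interactive planning.
#'
#' @param upper,lower `jaw_model`s.
#' @param tolerance contact threshold (mm), default 0.1; must be > 0.
#' @return object of class `contact_report`: per-jaw data.frames
#'   (`vertex`, `distance`) plus the tolerance.
#' @export
detect_contacts <- function(upper, lower, tolerance = 0.1) {
  stopifnot(inherits(upper, "jaw_model"), inherits(lower, "jaw_model"))
  if (!is.finite(tolerance) || tolerance <= 0) {
    om_error("config_error", "contact tolerance must be > 0")
  }
  du <- signed_mesh_distance(upper$mesh$vertices, lower$mesh)
  dl <- signed_mesh_distance(lower$mesh$vertices, upper$mesh)
  iu <- which(du <= tolerance)
  il <- which(dl <= tolerance)
  structure(list(
    upper = data.frame(vertex = iu, distance = du[iu]),
    lower = data.frame(vertex = il, distance = dl[il]),
    tolerance = tolerance
  ), class = "contact_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("<contact_report> tolerance %.3g mm: %d upper / %d lower contact vertices\n",
              x$tolerance, nrow(x$upper), nrow(x$lower)))
  pen <- c(x$upper$distance, x$lower$distance)
  if (length(pen)) {
    cat(sprintf("  deepest penetration %.4f mm, closest approach %.4f mm\n",
                min(pen), max(pen)))
  }
  invisible(x)
}

contact_summary <- function(x) {
  stopifnot(inherits(x, "contact_report"))
  pen <- c(x$upper$distance, x$lower$distance)
  list(tolerance_mm = x$tolerance,
       n_upper = nrow(x$upper), n_lower = nrow(x$lower),
       deepest_penetration_mm = if (length(pen)) min(pen) else NA_real_)
}
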
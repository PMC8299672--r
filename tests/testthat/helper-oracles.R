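# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own computational paths: distances by constrained
# numerical minimization, rigid fits by direct parameter search, meshes by
# hand-listed topology.

# Axis-aligned cube as a tri_mesh, outward-oriented.
make_cube <- function(center = c(0, 0, 0), side = 10) {
  h <- side / 2
  s <- expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h))
  V <- sweep(as.matrix(s), 2L, center, "+")
  # index layout from expand.grid: x fastest, then y, then z
  F <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -h
    c(5, 6, 8), c(5, 8, 7),   # z = +h
    c(1, 2, 6), c(1, 6, 5),   # y = -h
    c(3, 7, 8), c(3, 8, 4),   # y = +h
    c(1, 5, 7), c(1, 7, 3),   # x = -h
    c(2, 4, 8), c(2, 8, 6))   # x = +h
  m <- tri_mesh(V, F)
  stopifnot(mesh_volume(m) > 0)
  m
}

# Unsigned point-to-triangle distance by barycentric grid search plus
# local refinement (independent of the package's closest-point algebra).
tri_point_dist_oracle <- function(p, a, b, c) {
  f <- function(uv) {
    u <- uv[1]; v <- uv[2]
    if (u < 0 || v < 0 || u + v > 1) return(Inf)
    q <- a + u * (b - a) + v * (c - a)
    sum((p - q)^2)
  }
  g <- seq(0, 1, length.out = 21)
  best <- c(0, 0); bestv <- f(c(0, 0))
  for (u in g) for (v in g) {
    if (u + v <= 1) {
      val <- f(c(u, v))
      if (val < bestv) { bestv <- val; best <- c(u, v) }
    }
  }
  opt <- stats::optim(best, function(uv) {
    u <- max(0, uv[1]); v <- max(0, uv[2])
    if (u + v > 1) { s <- u + v; u <- u / s; v <- v / s }
    q <- a + u * (b - a) + v * (c - a)
    sum((p - q)^2)
  }, method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 500))
  sqrt(min(bestv, opt$value))
}

# Signed distance of points to a closed mesh: unsigned oracle distance,
# sign by counting axis crossings on three independent ray directions
# (majority vote for robustness).
signed_dist_oracle <- function(pts, mesh) {
  fc <- list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
             b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
             c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    d <- min(vapply(seq_len(nrow(mesh$faces)), function(k) {
      tri_point_dist_oracle(p, fc$a[k, ], fc$b[k, ], fc$c[k, ])
    }, numeric(1)))
    if (inside_oracle(p, mesh)) -d else d
  }, numeric(1))
}

inside_oracle <- function(p, mesh) {
  dirs <- rbind(c(0.123, 0.456, 0.881), c(0.707, -0.301, 0.64), c(-0.2, 0.9, 0.387))
  votes <- apply(dirs, 1L, function(d) {
    d <- d / sqrt(sum(d^2))
    hits <- 0L
    for (k in seq_len(nrow(mesh$faces))) {
      a <- mesh$vertices[mesh$faces[k, 1], ]
      b <- mesh$vertices[mesh$faces[k, 2], ]
      cc <- mesh$vertices[mesh$faces[k, 3], ]
      e1 <- b - a; e2 <- cc - a
      pv <- c(d[2] * e2[3] - d[3] * e2[2], d[3] * e2[1] - d[1] * e2[3],
              d[1] * e2[2] - d[2] * e2[1])
      det <- sum(e1 * pv)
      if (abs(det) < 1e-12) next
      tv <- p - a
      u <- sum(tv * pv) / det
      qv <- c(tv[2] * e1[3] - tv[3] * e1[2], tv[3] * e1[1] - tv[1] * e1[3],
              tv[1] * e1[2] - tv[2] * e1[1])
      v <- sum(qv * d) / det
      tt <- sum(e2 * qv) / det
      if (u >= 0 && v >= 0 && u + v <= 1 && tt > 1e-12) hits <- hits + 1L
    }
    hits %% 2L == 1L
  })
  sum(votes) >= 2L
}

# Random valid synthetic configuration spanning the clinically plausible
# parameter space.
random_valid_config <- function(seed) {
  set.seed(seed)
  synthetic_case_config(
    lambda_true = runif(1, 2, 15),
    d_up_true = runif(1, 25, 55),
    d_post_true = runif(1, 70, 100),
    pi_ns_dist = runif(1, 90, 120),
    dc_dist = runif(1, 35, 50),
    mm_per_px = runif(1, 0.05, 0.2),
    seed = seed)
}

random_rigid <- function(seed, max_t = 20) {
  set.seed(seed)
  compose_transforms(
    rigid_transform(translation = runif(3, -max_t, max_t)),
    rotation_about_axis(rnorm(3), runif(1, -180, 180)))
}

# Least-squares rigid-motion solver driven only by scalar displacement
# targets: finds (rotation vector, translation) such that selected
# components of the per-point displacements match the targets. Independent
# of the package's transform code path (its own Rodrigues formula).
solve_target_move <- function(points, constraints) {
  rodrigues <- function(r) {
    th <- sqrt(sum(r^2))
    if (th < 1e-12) return(diag(3))
    u <- r / th
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  objective <- function(par) {
    R <- rodrigues(par[1:3]); t <- par[4:6]
    err <- vapply(constraints, function(cn) {
      pre <- points[[cn$point]]
      delta <- as.vector(R %*% pre) + t - pre
      delta[cn$axis] - cn$target
    }, numeric(1))
    sum(err^2) + 1e-10 * sum(par^2)
  }
  fit <- stats::nlminb(rep(0, 6), objective,
                       control = list(rel.tol = 1e-15, abs.tol = 1e-20,
                                      iter.max = 2000, eval.max = 4000))
  fit <- stats::nlminb(fit$par, objective,
                       control = list(rel.tol = 1e-15, abs.tol = 1e-20,
                                      iter.max = 2000, eval.max = 4000))
  fit$value <- fit$objective
  list(rotation = rodrigues(fit$par[1:3]), rotvec = fit$par[1:3],
       translation = fit$par[4:6], objective = fit$value)
}

pairwise_dists <- function(pts) as.vector(stats::dist(pts))
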
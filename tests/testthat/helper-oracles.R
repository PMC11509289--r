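# Independent oracles and small fixtures. Everything here is deliberately
# written against the naive definition (loops, closed forms, optimisation
# from scratch) and never calls the code path it is used to check.

# closest point on a single triangle, pure R: minimise |p - (a + s*ab + t*ac)|
# over the barycentric domain by constrained quadratic enumeration of the
# interior and all edges.
closest_on_triangle_r <- function(p, a, b, c) {
  ab <- b - a
  ac <- c - a
  # unconstrained minimiser of the quadratic in (s, t)
  g <- matrix(c(sum(ab * ab), sum(ab * ac), sum(ab * ac), sum(ac * ac)), 2, 2)
  rhs <- c(sum(ab * (p - a)), sum(ac * (p - a)))
  st <- tryCatch(solve(g, rhs), error = function(e) c(-1, -1))
  cand <- list()
  if (all(is.finite(st)) && st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
    cand[[length(cand) + 1]] <- a + st[1] * ab + st[2] * ac
  }
  # each edge: parameterise and clamp
  edge <- function(p0, p1) {
    d <- p1 - p0
    u <- sum((p - p0) * d) / sum(d * d)
    p0 + min(1, max(0, u)) * d
  }
  cand[[length(cand) + 1]] <- edge(a, b)
  cand[[length(cand) + 1]] <- edge(a, c)
  cand[[length(cand) + 1]] <- edge(b, c)
  d2 <- vapply(cand, function(q) sum((p - q)^2), 0)
  cand[[which.min(d2)]]
}

# brute-force nearest surface point: plain loop over every triangle
brute_force_nearest <- function(mesh, p) {
  best <- Inf
  best_pt <- NULL
  for (f in seq_len(nrow(mesh$faces))) {
    q <- closest_on_triangle_r(
      p,
      mesh$vertices[mesh$faces[f, 1], ],
      mesh$vertices[mesh$faces[f, 2], ],
      mesh$vertices[mesh$faces[f, 3], ]
    )
    d2 <- sum((p - q)^2)
    if (d2 < best) {
      best <- d2
      best_pt <- q
    }
  }
  list(point = best_pt, distance = sqrt(best))
}

# brute-force least-squares rigid fit: coarse Euler-angle grid then
# Nelder-Mead refinement; translation is profiled out in closed form.
brute_force_rigid_rms <- function(src, dst) {
  euler_rot <- function(ang) {
    rx <- rotation_about_axis(c(1, 0, 0), ang[1])
    ry <- rotation_about_axis(c(0, 1, 0), ang[2])
    rz <- rotation_about_axis(c(0, 0, 1), ang[3])
    rz %*% ry %*% rx
  }
  obj <- function(ang) {
    r <- euler_rot(ang)
    moved <- sweep(src %*% t(r), 2, colMeans(dst) - colMeans(src %*% t(r)), "+")
    sqrt(mean(rowSums((moved - dst)^2)))
  }
  grid <- seq(-180, 180, by = 30)
  best <- Inf
  best_ang <- c(0, 0, 0)
  for (a1 in grid) {
    for (a2 in seq(-90, 90, by = 30)) {
      for (a3 in grid) {
        v <- obj(c(a1, a2, a3))
        if (v < best) {
          best <- v
          best_ang <- c(a1, a2, a3)
        }
      }
    }
  }
  opt <- optim(best_ang, obj, control = list(reltol = 1e-14, maxit = 5000))
  opt <- optim(opt$par, obj, control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# canonical symmetric landmark fixture (spec of the APP construction)
canonical_lm <- function() {
  pelvic_landmarks(
    asis_left = c(-120, 0, 0), asis_right = c(120, 0, 0),
    pubic_left = c(-20, 0, -90), pubic_right = c(20, 0, -90)
  )
}

canonical_frame <- function(side = "right") build_app_frame(canonical_lm(), side)

# unit tetrahedron point set
unit_tetrahedron <- function() {
  rbind(
    c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)
  )
}

# icosahedron-based sphere mesh with exact vertex normals (radial)
sphere_mesh <- function(radius = 10, n_theta = 24L, n_phi = 24L) {
  theta <- seq(0, pi, length.out = n_theta + 1L)[2:n_theta]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[seq_len(n_phi)]
  grid <- expand.grid(theta = theta, phi = phi)
  ring <- cbind(
    sin(grid$theta) * cos(grid$phi),
    sin(grid$theta) * sin(grid$phi),
    cos(grid$theta)
  ) * radius
  v <- rbind(c(0, 0, radius), ring, c(0, 0, -radius))
  f <- hipnav:::sphere_grid_faces(n_theta, n_phi)
  surface_mesh(v, f)
}

# a seeded random rigid transform without touching the global RNG stream
seeded_transform <- function(seed, max_angle = 90, max_trans = 40) {
  hipnav:::with_seed(seed, random_transform(max_angle, max_trans))
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}

# small, fast scene configuration for pipeline tests
test_scene <- function(seed, ...) {
  args <- utils::modifyList(
    list(
      seed = seed, mesh_resolution = c(32L, 20L), n_raters = 1L,
      n_starts = 4L
    ),
    list(...)
  )
  do.call(scene_config, args)
}

fast_postop_params <- list(max_points = 250L, n_starts = 1L, max_iter = 60L)
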
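#' Synthetic study scene configuration
#'
#' Bundles every knob of the synthetic pelvis scene generator. The defaults
#' encode the study design the analysis assumes: 26 registration points per
#' alignment, at least three raters per side, a 40 deg inclination / 15 deg
#' anteversion cup target, and noise magnitudes documented as assumptions in
#' the methods vignette (probe noise 0.5 mm, post-op vertex noise 0.1 mm,
#' post-op displacement within 8 deg / 15 mm, overlay noise 0).
#'
#' @param seed integer master seed; every random stream below derives from it.
#' @param side operated hip, `"right"` or `"left"`.
#' @param mesh_resolution integer length-2 `(n_theta, n_phi)` sphere grid of
#'   the parametric hemipelvis surface.
#' @param cup_target a `cup_angles` (operative) ground-truth target.
#' @param cup_depth_mm signed implant depth of the ground-truth cup relative
#'   to the acetabular centre (mm; positive lateral).
#' @param acetabular_radius_mm radius of the carved acetabular cavity (mm).
#' @param point_noise_sigma_mm isotropic Gaussian probing noise (mm).
#' @param n_points registration points per rater (>= 6).
#' @param region_counts optional named integer vector of per-region point
#'   counts summing to `n_points`; default spreads 26 points as 8 on the
#'   iliac crest and 6 each on anterior wall, posterior wall and rim.
#' @param n_raters number of raters re-running the alignment (>= 1).
#' @param rater_pose_rot_deg,rater_pose_trans_mm magnitude bounds of each
#'   rater's arbitrary tracking-world pose.
#' @param postop_rot_deg,postop_trans_mm magnitude bounds of the rigid
#'   displacement between pre-op and post-op scan poses.
#' @param postop_vertex_noise_sigma_mm per-vertex Gaussian noise of the
#'   post-op surface (segmentation jitter, mm).
#' @param overlay_noise_deg,overlay_noise_mm manual template-overlay noise on
#'   the post-op cup pose (degrees on each angle / mm on the centre).
#' @param pelvic_tilt_deg preoperative pelvic tilt; 0 keeps the APP as the
#'   angle reference, non-zero switches the readout to the FPP.
#' @param n_starts,perturb_rot_deg,perturb_trans_mm multi-start settings of
#'   the patient alignment.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(seed = 1L,
                         side = c("right", "left"),
                         mesh_resolution = c(64L, 48L),
                         cup_target = cup_angles(15, 40, "operative"),
                         cup_depth_mm = 0,
                         acetabular_radius_mm = 26,
                         point_noise_sigma_mm = 0.5,
                         n_points = 26L,
                         region_counts = NULL,
                         n_raters = 3L,
                         rater_pose_rot_deg = 30,
                         rater_pose_trans_mm = 80,
                         postop_rot_deg = 8,
                         postop_trans_mm = 15,
                         postop_vertex_noise_sigma_mm = 0.1,
                         overlay_noise_deg = 0,
                         overlay_noise_mm = 0,
                         pelvic_tilt_deg = 0,
                         n_starts = 16L,
                         perturb_rot_deg = 15,
                         perturb_trans_mm = 20) {
  side <- match.arg(side)
  stopifnot(
    length(mesh_resolution) == 2L, all(mesh_resolution >= 8L),
    inherits(cup_target, "cup_angles"),
    acetabular_radius_mm > 0,
    point_noise_sigma_mm >= 0, postop_vertex_noise_sigma_mm >= 0,
    overlay_noise_deg >= 0, overlay_noise_mm >= 0,
    n_points >= 6L, n_raters >= 1L, n_starts >= 1L
  )
  if (is.null(region_counts)) {
    region_counts <- spread_region_counts(n_points)
  }
  if (sum(region_counts) != n_points) {
    stop("region_counts must sum to n_points", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), side = side,
      mesh_resolution = as.integer(mesh_resolution),
      cup_target = cup_target, cup_depth_mm = cup_depth_mm,
      acetabular_radius_mm = acetabular_radius_mm,
      point_noise_sigma_mm = point_noise_sigma_mm,
      n_points = as.integer(n_points), region_counts = region_counts,
      n_raters = as.integer(n_raters),
      rater_pose_rot_deg = rater_pose_rot_deg,
      rater_pose_trans_mm = rater_pose_trans_mm,
      postop_rot_deg = postop_rot_deg, postop_trans_mm = postop_trans_mm,
      postop_vertex_noise_sigma_mm = postop_vertex_noise_sigma_mm,
      overlay_noise_deg = overlay_noise_deg, overlay_noise_mm = overlay_noise_mm,
      pelvic_tilt_deg = pelvic_tilt_deg,
      n_starts = as.integer(n_starts),
      perturb_rot_deg = perturb_rot_deg, perturb_trans_mm = perturb_trans_mm
    ),
    class = "scene_config"
  )
}

pelvis_region_names <- c(
  "iliac_crest", "anterior_wall", "posterior_wall", "acetabular_rim"
)

spread_region_counts <- function(n_points) {
  base <- n_points %/% 4L
  counts <- rep(base, 4L)
  names(counts) <- pelvis_region_names
  extra <- n_points - 4L * base
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> seed %d, %s hip, %d points x %d raters, probe sigma %.2f mm\n",
    x$seed, x$side, x$n_points, x$n_raters, x$point_noise_sigma_mm
  ))
  invisible(x)
}

# ---- parametric pelvis -----------------------------------------------------

# Canonical (right-side) anatomy of the parametric scene, in mm:
# lateral = +x, anterior = +y, superior = +z; ASIS midpoint at the origin.
canonical_landmarks <- function() {
  pelvic_landmarks(
    asis_left = c(-115, 0, 0), asis_right = c(115, 0, 0),
    pubic_left = c(-22, 0, -92), pubic_right = c(22, 0, -92)
  )
}

# Hemipelvis blade: ellipsoid centre and semi-axes (lateral, anterior, superior)
pelvis_blade <- function() {
  list(center = c(72, -12, -10), semi = c(30, 62, 92))
}

# Orientation of the carved acetabular cavity in the canonical frame.
cavity_axis <- function() {
  inc <- deg2rad(45)
  av <- deg2rad(20)
  c(sin(inc), cos(inc) * sin(av), cos(inc) * cos(av))
}

#' Generate a synthetic hemipelvis surface with landmarks
#'
#' Deterministic-given-seed parametric stand-in for a CT-segmented pelvis: a
#' smoothly deformed ellipsoidal iliac blade with a spherical acetabular
#' cavity carved into its lateral aspect, plus anatomical landmarks at
#' parametrically defined sites. Four named regions (iliac crest, anterior
#' wall, posterior wall, acetabular rim) are labelled on the faces for
#' registration-point sampling. A left-side scene is the exact mirror image
#' of the right-side scene across the sagittal plane.
#'
#' @param config a `scene_config`.
#' @return List with `mesh` (a `surface_mesh` carrying `regions` and an
#'   `acetabulum` record with `center`, `radius`, `axis`) and `landmarks`
#'   (a `pelvic_landmarks`).
#' @export
generate_pelvis <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nth <- config$mesh_resolution[1]
  nph <- config$mesh_resolution[2]
  blade <- pelvis_blade()
  r_ac <- config$acetabular_radius_mm

  # unit-sphere grid (poles + interior rings), deformed ellipsoid radii
  theta <- seq(0, pi, length.out = nth + 1L)[2:nth] # interior rings
  phi <- seq(0, 2 * pi, length.out = nph + 1L)[seq_len(nph)]
  grid <- expand.grid(theta = theta, phi = phi)

  # seeded smooth low-frequency deformation of the radius; sin(theta) factor
  # keeps the poles single-valued
  coefs <- with_seed(child_seed(config$seed, "pelvis-shape"), {
    list(c = rnorm(4, 0, 0.015), d = runif(4, 0, 2 * pi), e = runif(4, 0, pi))
  })
  rho <- function(th, ph) {
    out <- rep(1, length(th))
    for (k in 1:4) {
      out <- out + coefs$c[k] * sin(th) * sin(k * th + coefs$e[k]) *
        cos(k * ph + coefs$d[k])
    }
    out
  }

  dirs <- cbind(
    sin(grid$theta) * cos(grid$phi),
    sin(grid$theta) * sin(grid$phi),
    cos(grid$theta)
  )
  scale <- rho(grid$theta, grid$phi)
  ring_v <- sweep(dirs * scale, 2, blade$semi, "*")
  ring_v <- sweep(ring_v, 2, blade$center, "+")
  v_top <- blade$center + c(0, 0, blade$semi[3])
  v_bot <- blade$center - c(0, 0, blade$semi[3])
  vertices <- rbind(v_top, ring_v, v_bot)
  rownames(vertices) <- NULL

  faces <- sphere_grid_faces(nth, nph)

  # carve the acetabular socket: a hemispherical cavity of radius r_ac whose
  # centre sits on the cavity axis just lateral of the bone surface. Vertices
  # inside the sphere are pushed medially ALONG the axis onto the sphere's
  # medial hemisphere -- an axial height-field carve that cannot fold
  # triangles (unlike radial projection about a centre on the surface).
  u0 <- cavity_axis()
  rel_m <- sweep(vertices, 2, blade$center)
  t_ax <- as.numeric(rel_m %*% u0)
  r_trans <- sqrt(pmax(rowSums(rel_m^2) - t_ax^2, 0))
  # mouth centre just lateral of the surface at the axis itself; on coarse
  # grids fall back to the vertices nearest the axis
  near_axis <- r_trans < 0.35 * r_ac & t_ax > 0
  if (sum(near_axis) < 4L) {
    lateral_side <- which(t_ax > 0)
    near_axis <- lateral_side[order(r_trans[lateral_side])[1:12]]
  }
  mouth_t <- max(t_ax[near_axis]) + 2
  ac_center <- blade$center + mouth_t * u0
  w <- sweep(vertices, 2, ac_center)
  wu <- as.numeric(w %*% u0)
  d_ac <- sqrt(rowSums(w^2))
  in_socket <- d_ac < r_ac
  push <- wu[in_socket] + sqrt(wu[in_socket]^2 + r_ac^2 - d_ac[in_socket]^2)
  vertices[in_socket, ] <- vertices[in_socket, , drop = FALSE] -
    outer(push, u0)

  regions <- label_pelvis_regions(vertices, faces, ac_center, u0, r_ac)
  for (nm in pelvis_region_names) {
    if (length(regions[[nm]]) < 3L) {
      stop(
        "mesh resolution too low: region '", nm,
        "' has fewer than 3 faces; increase mesh_resolution",
        call. = FALSE
      )
    }
  }

  landmarks <- canonical_landmarks()
  mesh <- surface_mesh(vertices, faces, regions)
  mesh$acetabulum <- list(center = ac_center, radius = r_ac, axis = u0)

  if (config$side == "left") {
    mesh <- mirror_mesh_x(mesh)
    landmarks <- pelvic_landmarks(
      asis_left = mirror_x(landmarks$asis_right),
      asis_right = mirror_x(landmarks$asis_left),
      pubic_left = mirror_x(landmarks$pubic_right),
      pubic_right = mirror_x(landmarks$pubic_left)
    )
  }
  list(mesh = mesh, landmarks = landmarks)
}

sphere_grid_faces <- function(nth, nph) {
  nth <- as.integer(nth)
  nph <- as.integer(nph)
  # vertex layout: 1 = top pole, then (nth-1) rings of nph, last = bottom pole
  ring <- function(i, j) 1L + (j - 1L) * (nth - 1L) + i # i-th ring row, j-th phi
  jn <- function(j) if (j == nph) 1L else j + 1L
  faces <- vector("list", 3L)
  top <- t(vapply(seq_len(nph), function(j) {
    c(1L, ring(1L, j), ring(1L, jn(j)))
  }, integer(3)))
  bottom_pole <- 1L + (nth - 1L) * nph + 1L
  bot <- t(vapply(seq_len(nph), function(j) {
    c(bottom_pole, ring(nth - 1L, jn(j)), ring(nth - 1L, j))
  }, integer(3)))
  quads <- list()
  for (i in seq_len(nth - 2L)) {
    for (j in seq_len(nph)) {
      a <- ring(i, j)
      b <- ring(i + 1L, j)
      c_ <- ring(i + 1L, jn(j))
      d <- ring(i, jn(j))
      quads[[length(quads) + 1L]] <- rbind(c(a, b, c_), c(a, c_, d))
    }
  }
  rbind(top, do.call(rbind, quads), bot)
}

label_pelvis_regions <- function(vertices, faces, ac_center, u0, r_ac) {
  cen <- (vertices[faces[, 1], ] + vertices[faces[, 2], ] + vertices[faces[, 3], ]) / 3
  rel <- sweep(cen, 2, ac_center)
  d <- sqrt(rowSums(rel^2))
  zmax <- max(vertices[, 3])
  crest <- cen[, 3] > zmax - 30
  cavity <- d <= 1.02 * r_ac
  rim <- !crest & !cavity & d < 1.8 * r_ac
  yq <- quantile(cen[, 2], c(0.25, 0.75))
  anterior <- !crest & !rim & !cavity & cen[, 2] > yq[2]
  posterior <- !crest & !rim & !cavity & cen[, 2] < yq[1]
  list(
    iliac_crest = which(crest),
    anterior_wall = which(anterior),
    posterior_wall = which(posterior),
    acetabular_rim = which(rim),
    acetabulum = which(cavity)
  )
}

mirror_x <- function(p) c(-p[1], p[2], p[3])

mirror_mesh_x <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  f <- mesh$faces[, c(1L, 3L, 2L)] # restore outward winding
  out <- surface_mesh(v, f, mesh$regions)
  if (!is.null(mesh$acetabulum)) {
    out$acetabulum <- list(
      center = mirror_x(mesh$acetabulum$center),
      radius = mesh$acetabulum$radius,
      axis = mirror_x(mesh$acetabulum$axis)
    )
  }
  out
}

# ---- implant / sampling / post-op -----------------------------------------

#' Implant a ground-truth cup into a synthetic pelvis
#'
#' The cup axis realises the requested operative angles in the given pelvic
#' frame; the centre sits at the acetabular centre offset by `depth_mm`
#' along the axis (positive lateral).
#'
#' @param mesh a pelvis `surface_mesh` carrying an `acetabulum` record.
#' @param frame the `pelvic_frame` the target angles refer to.
#' @param target operative `cup_angles`.
#' @param depth_mm signed implant depth (mm).
#' @return A `cup_pose` with `frame_id = "preop"`.
#' @export
implant_cup <- function(mesh, frame, target, depth_mm = 0) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(frame, "pelvic_frame"))
  if (is.null(mesh$acetabulum)) {
    stop("mesh carries no acetabulum record; generate it with generate_pelvis()",
      call. = FALSE
    )
  }
  axis <- axis_from_operative_angles(target, frame)
  if (sum(axis * frame$lateral) <= 0) {
    stop("implanted cup axis points medially", call. = FALSE)
  }
  cup_pose(mesh$acetabulum$center + depth_mm * axis, axis, frame_id = "preop")
}

#' Sample registration points on the pelvis surface
#'
#' Draws points uniformly (area-weighted) on the faces of the named regions,
#' displaces them by isotropic Gaussian probing noise, and optionally
#' re-expresses them in a rater-specific tracking frame. Deterministic for a
#' given seed.
#'
#' @param mesh a pelvis `surface_mesh` with regions.
#' @param region_counts named integer vector: points per region.
#' @param sigma_mm isotropic Gaussian noise SD (mm).
#' @param seed integer seed.
#' @param rater_transform optional `rigid_transform` mapping the rater's
#'   tracking frame to the model frame; when given, the returned points are
#'   expressed in the tracking frame (apply the transform to map them back).
#' @return A labelled `point_set`.
#' @export
sample_registration_points <- function(mesh, region_counts, sigma_mm = 0,
                                       seed = 1L, rater_transform = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(names(region_counts)) || length(region_counts) < 1L) {
    stop("region_counts must be a named vector", call. = FALSE)
  }
  pts <- with_seed(seed, {
    out <- list()
    for (rg in names(region_counts)) {
      k <- region_counts[[rg]]
      if (k < 1L) next
      fid <- mesh$regions[[rg]]
      if (is.null(fid) || !length(fid)) {
        stop("mesh has no faces in region '", rg, "'", call. = FALSE)
      }
      f <- mesh$faces[fid, , drop = FALSE]
      w <- triangle_areas(mesh$vertices, f)
      if (sum(w) <= 0) stop("region '", rg, "' has zero surface area", call. = FALSE)
      pick <- sample.int(nrow(f), k, replace = TRUE, prob = w)
      u <- runif(k)
      v <- runif(k)
      flip <- u + v > 1
      u[flip] <- 1 - u[flip]
      v[flip] <- 1 - v[flip]
      a <- mesh$vertices[f[pick, 1], , drop = FALSE]
      b <- mesh$vertices[f[pick, 2], , drop = FALSE]
      c_ <- mesh$vertices[f[pick, 3], , drop = FALSE]
      p <- a + u * (b - a) + v * (c_ - a)
      if (sigma_mm > 0) {
        p <- p + matrix(rnorm(3 * k, 0, sigma_mm), k, 3)
      }
      out[[rg]] <- p
    }
    out
  })
  points <- do.call(rbind, pts)
  labels <- rep(names(pts), vapply(pts, nrow, 0L))
  ps <- point_set(points, labels)
  if (!is.null(rater_transform)) {
    ps <- transform_point_set(invert_transform(rater_transform), ps)
  }
  ps
}

#' Simulate the post-operative scene
#'
#' The post-op scan sees the same rigid pelvis in a different scanner pose:
#' the pre-op mesh under a bounded random rigid displacement plus per-vertex
#' Gaussian noise. The post-op cup is the true cup under the same
#' displacement, optionally degraded by manual template-overlay noise on its
#' angles and centre. The displacement is returned as ground truth.
#'
#' @param preop_mesh the pre-op `surface_mesh`.
#' @param true_cup the ground-truth `cup_pose` (pre-op frame).
#' @param frame the pre-op `pelvic_frame` (used to apply overlay noise in
#'   anatomical angle coordinates).
#' @param config a `scene_config`.
#' @param seed integer seed.
#' @return List with `postop_mesh`, `postop_cup` (frame_id `"postop"`) and
#'   `displacement` (the `rigid_transform` pre-op -> post-op).
#' @export
simulate_postop <- function(preop_mesh, true_cup, frame, config, seed = 1L) {
  stopifnot(
    inherits(preop_mesh, "surface_mesh"), inherits(true_cup, "cup_pose"),
    inherits(frame, "pelvic_frame"), inherits(config, "scene_config")
  )
  out <- with_seed(seed, {
    centroid <- colMeans(preop_mesh$vertices)
    d0 <- random_transform(config$postop_rot_deg, config$postop_trans_mm)
    # rotate about the mesh centroid so the bound describes the actual motion
    disp <- rigid_transform(
      rotation = d0$rotation,
      translation = as.numeric(
        centroid - d0$rotation %*% centroid + d0$translation
      )
    )
    postop_mesh <- transform_mesh(disp, preop_mesh)
    sv <- config$postop_vertex_noise_sigma_mm
    if (sv > 0) {
      ac <- postop_mesh$acetabulum
      postop_mesh <- surface_mesh(
        postop_mesh$vertices +
          matrix(rnorm(length(postop_mesh$vertices), 0, sv),
            nrow(postop_mesh$vertices), 3
          ),
        postop_mesh$faces, postop_mesh$regions
      )
      postop_mesh$acetabulum <- ac
    }
    cup <- transform_cup_pose(disp, true_cup, "postop")
    if (config$overlay_noise_deg > 0 || config$overlay_noise_mm > 0) {
      frame_post <- transform_frame(disp, frame)
      ang <- operative_angles(cup_pose(cup$center, cup$axis, "postop-frame-eval"),
        frame_post
      )
      noisy <- cup_angles(
        ang$anteversion + rnorm(1, 0, config$overlay_noise_deg),
        ang$inclination + rnorm(1, 0, config$overlay_noise_deg),
        "operative"
      )
      cup <- cup_pose(
        cup$center + rnorm(3, 0, config$overlay_noise_mm),
        axis_from_operative_angles(noisy, frame_post),
        "postop"
      )
    }
    list(postop_mesh = postop_mesh, postop_cup = cup, displacement = disp)
  })
  out
}

#' Simulate a complete study case
#'
#' Assembles one synthetic surgery: pelvis and landmarks, pelvic frame (APP,
#' or FPP when the configuration sets a pelvic tilt), ground-truth cup,
#' per-rater noisy 26-point registration samples each in its own tracking
#' frame, the observed cup pose in each tracking frame, and the displaced,
#' noise-perturbed post-op scene. All ground-truth transforms are retained
#' under `ground_truth` for oracle checks; the analysis pipeline never reads
#' them.
#'
#' @param config a `scene_config`.
#' @return An object of class `synthetic_case`.
#' @export
simulate_case <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  pelvis <- generate_pelvis(config)
  app <- build_app_frame(pelvis$landmarks, config$side)
  frame <- if (config$pelvic_tilt_deg != 0) {
    apply_pelvic_tilt(app, config$pelvic_tilt_deg)
  } else {
    app
  }
  true_cup <- implant_cup(pelvis$mesh, frame, config$cup_target, config$cup_depth_mm)

  rater_transforms <- lapply(seq_len(config$n_raters), function(r) {
    with_seed(child_seed(config$seed, "rater-pose", r), {
      centroid <- colMeans(pelvis$mesh$vertices)
      t0 <- random_transform(config$rater_pose_rot_deg, config$rater_pose_trans_mm)
      rigid_transform(
        rotation = t0$rotation,
        translation = as.numeric(centroid - t0$rotation %*% centroid + t0$translation)
      )
    })
  })
  rater_samples <- lapply(seq_len(config$n_raters), function(r) {
    sample_registration_points(
      pelvis$mesh, config$region_counts, config$point_noise_sigma_mm,
      seed = child_seed(config$seed, "rater-points", r),
      rater_transform = rater_transforms[[r]]
    )
  })
  # the cup as each rater's tracking system observes it (its own frame)
  rater_cups <- lapply(seq_len(config$n_raters), function(r) {
    transform_cup_pose(
      invert_transform(rater_transforms[[r]]), true_cup,
      paste0("rater-", r)
    )
  })

  postop <- simulate_postop(
    pelvis$mesh, true_cup, frame, config,
    seed = child_seed(config$seed, "postop")
  )

  structure(
    list(
      config = config,
      preop_mesh = pelvis$mesh,
      landmarks = pelvis$landmarks,
      frame = frame,
      rater_samples = rater_samples,
      rater_cups = rater_cups,
      postop_mesh = postop$postop_mesh,
      postop_cup = postop$postop_cup,
      ground_truth = list(
        true_cup = true_cup,
        rater_transforms = rater_transforms,
        postop_displacement = postop$displacement
      )
    ),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "<synthetic_case> seed %d (%s hip): %d raters x %d points, sigma %.2f mm\n",
    x$config$seed, x$config$side, length(x$rater_samples),
    x$config$n_points, x$config$point_noise_sigma_mm
  ))
  invisible(x)
}

#' Strip ground truth from a case
#'
#' Returns the observables only, proving by construction that the analysis
#' pipeline cannot read the ground-truth transforms.
#'
#' @param case a `synthetic_case`.
#' @return The case with `ground_truth` removed.
#' @export
withhold_ground_truth <- function(case) {
  stopifnot(inherits(case, "synthetic_case"))
  case$ground_truth <- NULL
  case
}

#' Write a simulated case to a directory
#'
#' Writes `preop.stl`, `postop.stl`, `landmarks.csv`, per-rater
#' `rater_<k>_points.csv`, `truth.json` (ground-truth cup, rater poses,
#' post-op displacement) and `config.yaml`.
#'
#' @param case a `synthetic_case`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(case$preop_mesh, file.path(dir, "preop.stl"))
  write_mesh(case$postop_mesh, file.path(dir, "postop.stl"))
  write_landmarks(case$landmarks, file.path(dir, "landmarks.csv"))
  for (r in seq_along(case$rater_samples)) {
    write_points_csv(
      case$rater_samples[[r]],
      file.path(dir, sprintf("rater_%d_points.csv", r))
    )
  }
  write_cup_pose(case$postop_cup, file.path(dir, "postop_cup.json"))
  gt <- case$ground_truth
  truth <- list(
    true_cup = list(
      center = gt$true_cup$center, axis = gt$true_cup$axis,
      frame_id = gt$true_cup$frame_id
    ),
    rater_transforms = lapply(gt$rater_transforms, function(t) {
      list(
        rotation_row_major = as.numeric(t(t$rotation)),
        translation_mm = t$translation
      )
    }),
    postop_displacement = list(
      rotation_row_major = as.numeric(t(gt$postop_displacement$rotation)),
      translation_mm = gt$postop_displacement$translation
    )
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    digits = NA, auto_unbox = TRUE
  )
  yaml::write_yaml(scene_config_to_list(case$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

scene_config_to_list <- function(config) {
  out <- unclass(config)
  out$cup_target <- list(
    anteversion = config$cup_target$anteversion,
    inclination = config$cup_target$inclination,
    definition = config$cup_target$definition
  )
  out$region_counts <- as.list(config$region_counts)
  out
}

#' Build a scene configuration from a plain list (e.g. parsed YAML)
#'
#' @param lst named list of `scene_config` fields; missing fields keep their
#'   defaults.
#' @return A `scene_config`.
#' @export
scene_config_from_list <- function(lst) {
  args <- lst
  if (!is.null(args$cup_target) && !inherits(args$cup_target, "cup_angles")) {
    args$cup_target <- cup_angles(
      args$cup_target$anteversion, args$cup_target$inclination,
      args$cup_target$definition %||% "operative"
    )
  }
  if (!is.null(args$region_counts)) {
    args$region_counts <- unlist(args$region_counts)
  }
  do.call(scene_config, args[names(args) %in% names(formals(scene_config))])
}
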
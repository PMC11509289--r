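test_that("pelvis generation is deterministic given the seed", {
  cfg <- test_scene(7)
  a <- generate_pelvis(cfg)
  b <- generate_pelvis(cfg)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  expect_identical(a$mesh$regions, b$mesh$regions)
  expect_identical(a$landmarks, b$landmarks)
  c_ <- generate_pelvis(test_scene(8))
  expect_false(identical(a$mesh$vertices, c_$mesh$vertices))
})

test_that("the carved acetabular cavity has the configured radius", {
  p <- generate_pelvis(scene_config(seed = 3))
  ac <- p$mesh$acetabulum
  expect_equal(ac$radius, 26)
  # ray probes across the cup-seating cone: the cavity surface must sit at
  # the configured radius from the acetabular centre (within 2%)
  perp1 <- hipnav:::unit(hipnav:::cross3(ac$axis, c(0, 0, 1)))
  perp2 <- hipnav:::cross3(ac$axis, perp1)
  for (ang in c(0, 10, 20, 30)) {
    for (ph in seq(0, 2 * pi, length.out = 13)[-13]) {
      d <- -cos(ang * pi / 180) * ac$axis +
        sin(ang * pi / 180) * (cos(ph) * perp1 + sin(ph) * perp2)
      dev <- nearest_surface_point(p$mesh, ac$center + ac$radius * d)$distance
      expect_lt(dev, 0.02 * ac$radius)
    }
  }
})

test_that("left and right pelves are exact mirror images", {
  r <- generate_pelvis(test_scene(5, side = "right"))
  l <- generate_pelvis(test_scene(5, side = "left"))
  mirrored <- r$mesh$vertices
  mirrored[, 1] <- -mirrored[, 1]
  expect_equal(l$mesh$vertices, mirrored, tolerance = 1e-9)
  expect_equal(l$landmarks$asis_left, r$landmarks$asis_right * c(-1, 1, 1))
  expect_equal(
    l$mesh$acetabulum$center,
    r$mesh$acetabulum$center * c(-1, 1, 1),
    tolerance = 1e-12
  )
  # mirrored winding keeps faces non-degenerate
  expect_identical(nrow(l$mesh$faces), nrow(r$mesh$faces))
})

test_that("implanted cups realise the target angles and depth", {
  cfg <- test_scene(6)
  p <- generate_pelvis(cfg)
  frame <- build_app_frame(p$landmarks)
  cup <- implant_cup(p$mesh, frame, cup_angles(15, 40, "operative"), 0)
  ang <- operative_angles(cup, frame)
  expect_equal(ang$anteversion, 15, tolerance = 1e-9)
  expect_equal(ang$inclination, 40, tolerance = 1e-9)
  expect_equal(cup$center, p$mesh$acetabulum$center, tolerance = 1e-12)

  deep <- implant_cup(p$mesh, frame, cup_angles(15, 40, "operative"), 2)
  expect_equal(signed_depth_difference(deep, cup), 2, tolerance = 1e-12)
})

test_that("registration points respect regions, noise level and rater frames", {
  cfg <- test_scene(9)
  p <- generate_pelvis(cfg)
  pts0 <- sample_registration_points(p$mesh, cfg$region_counts, 0, seed = 1)
  expect_identical(nrow(pts0$points), 26L)
  expect_equal(
    table(pts0$labels)[names(cfg$region_counts)],
    table(rep(names(cfg$region_counts), cfg$region_counts))[names(cfg$region_counts)]
  )
  expect_lt(max(nearest_surface_point(p$mesh, pts0$points)$distance), 1e-9)

  # folded-normal oracle: mean point-to-surface distance of sigma-noised
  # points approximates E|N(0, sigma)| = sigma * sqrt(2/pi)
  big <- sample_registration_points(
    p$mesh, c(
      iliac_crest = 3000L, anterior_wall = 2500L,
      posterior_wall = 2500L, acetabular_rim = 2000L
    ),
    sigma_mm = 0.5, seed = 2
  )
  expect_equal(
    mean(nearest_surface_point(p$mesh, big$points)$distance),
    0.5 * sqrt(2 / pi),
    tolerance = 0.05 * 0.5 * sqrt(2 / pi)
  )

  # a rater frame re-expresses the points; mapping back restores them
  tr <- seeded_transform(77, 40, 60)
  pts_r <- sample_registration_points(p$mesh, cfg$region_counts, 0,
    seed = 1, rater_transform = tr
  )
  expect_equal(apply_transform(tr, pts_r$points), pts0$points, tolerance = 1e-9)
  expect_error(
    sample_registration_points(p$mesh, c(nowhere = 5L), 0, seed = 1),
    "no faces"
  )
})

test_that("post-op simulation displaces rigidly and records the ground truth", {
  cfg <- test_scene(10, postop_vertex_noise_sigma_mm = 0)
  p <- generate_pelvis(cfg)
  frame <- build_app_frame(p$landmarks)
  cup <- implant_cup(p$mesh, frame, cfg$cup_target, 0)

  still <- scene_config(
    seed = 10, mesh_resolution = c(32L, 20L),
    postop_rot_deg = 0, postop_trans_mm = 0, postop_vertex_noise_sigma_mm = 0
  )
  po <- simulate_postop(p$mesh, cup, frame, still, seed = 4)
  expect_equal(po$postop_mesh$vertices, p$mesh$vertices, tolerance = 1e-12)
  expect_equal(po$postop_cup$center, cup$center, tolerance = 1e-12)
  expect_identical(po$postop_cup$frame_id, "postop")

  po <- simulate_postop(p$mesh, cup, frame, cfg, seed = 5)
  d <- po$displacement
  expect_equal(po$postop_mesh$vertices, apply_transform(d, p$mesh$vertices),
    tolerance = 1e-12
  )
  # equivariance: angles in the displaced frame equal the pre-op angles
  frame_post <- transform_frame(d, frame)
  ang <- operative_angles(
    cup_pose(po$postop_cup$center, po$postop_cup$axis, "x"),
    frame_post
  )
  expect_equal(ang$anteversion, 15, tolerance = 1e-9)
  expect_equal(ang$inclination, 40, tolerance = 1e-9)
})

test_that("overlay noise perturbs the post-op angles with the configured SD", {
  cfg <- test_scene(11,
    overlay_noise_deg = 0.5, postop_vertex_noise_sigma_mm = 0
  )
  p <- generate_pelvis(cfg)
  frame <- build_app_frame(p$landmarks)
  cup <- implant_cup(p$mesh, frame, cfg$cup_target, 0)
  errs <- vapply(1:300, function(s) {
    po <- simulate_postop(p$mesh, cup, frame, cfg, seed = s)
    frame_post <- transform_frame(po$displacement, frame)
    ang <- operative_angles(
      cup_pose(po$postop_cup$center, po$postop_cup$axis, "x"), frame_post
    )
    c(ang$anteversion - 15, ang$inclination - 40)
  }, numeric(2))
  expect_equal(sd(errs[1, ]), 0.5, tolerance = 0.12)
  expect_equal(sd(errs[2, ]), 0.5, tolerance = 0.12)
  expect_equal(mean(errs[1, ]), 0, tolerance = 0.12)
})

test_that("simulated cases are reproducible and structurally complete", {
  cfg <- test_scene(12, n_raters = 3L)
  case <- simulate_case(cfg)
  expect_identical(length(case$rater_samples), 3L)
  expect_identical(length(case$rater_cups), 3L)
  # distinct samples, shared truth: every rater's observed cup maps back to
  # the one implanted cup through that rater's recorded pose
  expect_false(identical(case$rater_samples[[1]]$points, case$rater_samples[[2]]$points))
  for (r in 1:3) {
    back <- transform_cup_pose(
      case$ground_truth$rater_transforms[[r]], case$rater_cups[[r]], "preop"
    )
    expect_equal(back$center, case$ground_truth$true_cup$center, tolerance = 1e-9)
    expect_equal(back$axis, case$ground_truth$true_cup$axis, tolerance = 1e-9)
  }

  case2 <- simulate_case(cfg)
  expect_identical(case$preop_mesh$vertices, case2$preop_mesh$vertices)
  expect_identical(case$rater_samples, case2$rater_samples)
  expect_identical(case$postop_mesh$vertices, case2$postop_mesh$vertices)

  # serialized case directories are byte-identical across reruns
  d1 <- file.path(tempdir(), "case_a")
  d2 <- file.path(tempdir(), "case_b")
  write_case(case, d1)
  write_case(case2, d2)
  for (f in list.files(d1)) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
      info = f
    )
  }
})

test_that("the analysis pipeline runs on a case with ground truth withheld", {
  cfg <- test_scene(13)
  case <- withhold_ground_truth(simulate_case(cfg))
  expect_null(case$ground_truth)
  res <- assess_case(case, postop_params = fast_postop_params)
  expect_identical(nrow(res$errors), 1L)
  expect_true(all(is.finite(as.numeric(res$errors[1, 3:5]))))
})

test_that("scene configurations survive the YAML round trip", {
  cfg <- test_scene(14, point_noise_sigma_mm = 0.25, pelvic_tilt_deg = 5)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hipnav:::scene_config_to_list(cfg), path)
  back <- scene_config_from_list(yaml::read_yaml(path))
  expect_equal(back[setdiff(names(back), "cup_target")],
    cfg[setdiff(names(cfg), "cup_target")],
    tolerance = 1e-12
  )
  expect_equal(back$cup_target$anteversion, cfg$cup_target$anteversion)
})
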
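test_that("identical pre- and post-op scenes register to the identity", {
  mesh <- generate_pelvis(test_scene(21))$mesh
  res <- register_postop_to_preop(mesh, mesh, params = list(seed = 1))
  expect_transform_equal(res$transform, identity_transform(), 1e-6)
  expect_lt(res$accuracy_mm, 1e-8)
  expect_false(res$accuracy_warning)
})

test_that("a known scan displacement is recovered under vertex noise", {
  cfg <- test_scene(22)
  p <- generate_pelvis(cfg)
  frame <- build_app_frame(p$landmarks)
  cup <- implant_cup(p$mesh, frame, cfg$cup_target, 0)
  po <- simulate_postop(p$mesh, cup, frame, cfg, seed = 3)
  res <- register_postop_to_preop(po$postop_mesh, p$mesh,
    params = c(fast_postop_params, list(seed = 2))
  )
  err <- compose_transforms(res$transform, po$displacement)
  expect_lt(rotation_angle_deg(err), 0.1)
  expect_lt(hipnav:::vnorm(err$translation), 0.1)
  # folded-normal oracle for the residual surface agreement at sigma = 0.1,
  # and the sub-half-millimetre plausibility band for CT-scale noise
  expect_equal(res$accuracy_mm, 0.1 * sqrt(2 / pi), tolerance = 0.25 * 0.1 * sqrt(2 / pi))
  expect_lt(res$accuracy_mm, 0.5)
})

test_that("an accuracy ceiling raises the warning flag", {
  cfg <- test_scene(23)
  p <- generate_pelvis(cfg)
  frame <- build_app_frame(p$landmarks)
  cup <- implant_cup(p$mesh, frame, cfg$cup_target, 0)
  po <- simulate_postop(p$mesh, cup, frame, cfg, seed = 2)
  expect_warning(
    res <- register_postop_to_preop(po$postop_mesh, p$mesh,
      params = c(fast_postop_params, list(seed = 1, accuracy_ceiling_mm = 1e-3))
    ),
    "ceiling"
  )
  expect_true(res$accuracy_warning)
})

test_that("cup poses transform rigidly between coordinate systems", {
  pose <- cup_pose(c(90, 0, -60), hipnav:::unit(c(0.62, 0.26, 0.74)), "postop")
  expect_equal(
    transform_cup_pose(identity_transform(), pose)$center, pose$center
  )
  shift <- rigid_transform(translation = c(5, -2, 1))
  moved <- transform_cup_pose(shift, pose, "preop")
  expect_equal(moved$axis, pose$axis, tolerance = 1e-12) # translation-invariant axis
  expect_equal(moved$center, pose$center + c(5, -2, 1), tolerance = 1e-12)
  expect_identical(moved$frame_id, "preop")
  for (s in 1:4) {
    g <- seeded_transform(4000 + s)
    m2 <- transform_cup_pose(g, pose)
    expect_equal(hipnav:::vnorm(m2$axis), 1, tolerance = 1e-12)
    expect_equal(m2$center, apply_transform(g, pose$center), tolerance = 1e-9)
  }
})

test_that("navigation error follows the guide-minus-post-op convention", {
  frame <- canonical_frame()
  center <- c(90, 0, -60)
  guide <- cup_pose(center, axis_from_operative_angles(cup_angles(20, 40, "operative"), frame))
  same <- navigation_error(guide, guide, frame, case_id = 1, rater_id = 1)
  expect_equal(same$d_anteversion, 0)
  expect_equal(same$d_inclination, 0)
  expect_equal(same$d_depth, 0)

  postop <- cup_pose(center, axis_from_operative_angles(cup_angles(22, 40, "operative"), frame))
  err <- navigation_error(guide, postop, frame)
  expect_equal(err$d_anteversion, -2, tolerance = 1e-9)
  expect_equal(err$d_inclination, 0, tolerance = 1e-9)

  expect_error(
    navigation_error(guide, cup_pose(center, guide$axis, "postop"), frame),
    "different frames"
  )
})

test_that("a noiseless case yields zero navigation error end to end", {
  cfg <- test_scene(24,
    point_noise_sigma_mm = 0, postop_vertex_noise_sigma_mm = 0
  )
  res <- assess_case(simulate_case(cfg), postop_params = fast_postop_params)
  expect_lt(abs(res$errors$d_anteversion), 1e-6)
  expect_lt(abs(res$errors$d_inclination), 1e-6)
  expect_lt(abs(res$errors$d_depth), 1e-6)
})

repose_postop <- function(case, g) {
  case$postop_mesh <- transform_mesh(g, case$postop_mesh)
  case$postop_cup <- transform_cup_pose(g, case$postop_cup, "postop")
  case
}

test_that("navigation error is invariant to the post-op scan's world pose", {
  # with a noiseless post-op surface the registration optimum is exact, and
  # re-posing the scan changes nothing beyond numerical precision
  cfg <- test_scene(25, point_noise_sigma_mm = 0.3, postop_vertex_noise_sigma_mm = 0)
  case <- simulate_case(cfg)
  base <- assess_case(case, postop_params = fast_postop_params)
  g <- seeded_transform(26, 20, 40)
  res2 <- assess_case(repose_postop(case, g), postop_params = fast_postop_params)
  expect_equal(res2$errors$d_anteversion, base$errors$d_anteversion, tolerance = 1e-6)
  expect_equal(res2$errors$d_inclination, base$errors$d_inclination, tolerance = 1e-6)
  expect_equal(res2$errors$d_depth, base$errors$d_depth, tolerance = 1e-6)

  # with vertex noise the faceted-surface optimum is only defined to the
  # facet scale; re-posing shifts the errors far below the noise floor
  cfgn <- test_scene(28, point_noise_sigma_mm = 0.3)
  case_n <- simulate_case(cfgn)
  base_n <- assess_case(case_n, postop_params = fast_postop_params)
  res_n <- assess_case(repose_postop(case_n, g), postop_params = fast_postop_params)
  expect_equal(res_n$errors$d_anteversion, base_n$errors$d_anteversion, tolerance = 0.01)
  expect_equal(res_n$errors$d_inclination, base_n$errors$d_inclination, tolerance = 0.01)
  expect_equal(res_n$errors$d_depth, base_n$errors$d_depth, tolerance = 0.01)
})

test_that("a deliberate guide-side anteversion offset appears in the error", {
  cfg <- test_scene(27, point_noise_sigma_mm = 0, postop_vertex_noise_sigma_mm = 0)
  case <- simulate_case(cfg)
  for (delta in c(1, 5)) {
    res <- assess_case(case, offset_deg = delta, postop_params = fast_postop_params)
    expect_equal(res$errors$d_anteversion, delta, tolerance = 1e-6)
    expect_lt(abs(res$errors$d_inclination), 1e-6)
  }
})
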
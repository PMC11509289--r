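frame <- canonical_frame()

test_that("operative angles of axis-aligned cups match their definitions", {
  expect_equal(
    unclass(operative_angles(cup_pose(c(90, 0, -60), c(1, 0, 0)), frame))[c("anteversion", "inclination")],
    list(anteversion = 0, inclination = 90),
    tolerance = 1e-12
  )
  a <- operative_angles(cup_pose(c(90, 0, -60), c(0, 0, 1)), frame)
  expect_equal(a$anteversion, 0)
  expect_equal(a$inclination, 0)
  expect_error(
    operative_angles(cup_pose(c(90, 0, -60), c(-0.5, 0.2, 0.8)), frame),
    "medially"
  )
})

test_that("the radiographic 40/15 cup reads 38.39/19.28 operatively", {
  # construct the axis from the radiographic definition and evaluate the
  # closed forms independently
  ri <- 40 * pi / 180
  ra <- 15 * pi / 180
  axis <- c(sin(ri) * cos(ra), sin(ra), cos(ri) * cos(ra))
  ang <- operative_angles(cup_pose(c(90, 0, -60), axis), frame)
  oi_expected <- asin(sin(ri) * cos(ra)) * 180 / pi # 38.3929...
  oa_expected <- atan2(sin(ra), cos(ri) * cos(ra)) * 180 / pi # 19.2827...
  expect_equal(ang$inclination, oi_expected, tolerance = 1e-9)
  expect_equal(ang$anteversion, oa_expected, tolerance = 1e-9)
  expect_equal(ang$inclination, 38.39, tolerance = 0.01)
  expect_equal(ang$anteversion, 19.28, tolerance = 0.01)
})

test_that("axis_from_operative_angles inverts the angle readout", {
  expect_equal(
    axis_from_operative_angles(cup_angles(0, 0, "operative"), frame),
    frame$superior,
    tolerance = 1e-12
  )
  ax <- axis_from_operative_angles(cup_angles(19.2827299, 38.3928532, "operative"), frame)
  expect_equal(ax, c(0.6209, 0.2588, 0.7399), tolerance = 1e-3)
  # round trip over the full operative grid
  for (av in seq(-40, 40, by = 5)) {
    for (inc in seq(5, 85, by = 5)) {
      ax <- axis_from_operative_angles(cup_angles(av, inc, "operative"), frame)
      back <- operative_angles(cup_pose(c(90, 0, -60), ax), frame)
      expect_equal(back$anteversion, av, tolerance = 1e-9)
      expect_equal(back$inclination, inc, tolerance = 1e-9)
    }
  }
  expect_error(axis_from_operative_angles(cup_angles(0, 90, "operative"), frame), "90")
  expect_error(axis_from_operative_angles(cup_angles(10, 40, "radiographic"), frame), "operative")
})

test_that("angle-convention conversions satisfy the closed-form identities", {
  # zero anteversion: all conventions agree on inclination
  for (theta in c(10, 35, 60)) {
    r <- convert_definitions(cup_angles(0, theta, "operative"), "radiographic")
    expect_equal(r$anteversion, 0, tolerance = 1e-12)
    expect_equal(r$inclination, theta, tolerance = 1e-9)
  }
  # worked pair
  r <- convert_definitions(cup_angles(19.2827299, 38.3928532, "operative"), "radiographic")
  expect_equal(r$anteversion, 15, tolerance = 0.01)
  expect_equal(r$inclination, 40, tolerance = 0.01)
  # identities and round trips over the grid
  defs <- c("operative", "radiographic", "anatomic")
  for (av in seq(-40, 40, by = 10)) {
    for (inc in seq(5, 85, by = 10)) {
      op <- cup_angles(av, inc, "operative")
      rad <- convert_definitions(op, "radiographic")
      oa <- av * pi / 180
      oi <- inc * pi / 180
      expect_equal(tan(rad$inclination * pi / 180), tan(oi) / cos(oa), tolerance = 1e-9)
      expect_equal(sin(rad$anteversion * pi / 180), sin(oa) * cos(oi), tolerance = 1e-9)
      for (to in defs) {
        there <- convert_definitions(op, to)
        back <- convert_definitions(there, "operative")
        expect_equal(back$anteversion, av, tolerance = 1e-9)
        expect_equal(back$inclination, inc, tolerance = 1e-9)
      }
    }
  }
  expect_error(convert_definitions(cup_angles(0, 90, "operative"), "radiographic"), "90")
})

test_that("signed depth projects displacement onto the guide axis", {
  ax <- hipnav:::unit(c(0.6, 0.25, 0.74))
  ref <- cup_pose(c(90, -5, -60), ax)
  expect_equal(signed_depth_difference(ref, ref), 0)
  lateralised <- cup_pose(ref$center + 2 * ax, ax)
  expect_equal(signed_depth_difference(lateralised, ref), 2, tolerance = 1e-12)
  # perpendicular displacement is invisible to the depth metric
  perp <- hipnav:::unit(hipnav:::cross3(ax, c(0, 0, 1)))
  shifted <- cup_pose(ref$center + 3 * perp, ax)
  expect_equal(signed_depth_difference(shifted, ref), 0, tolerance = 1e-12)
  expect_error(
    signed_depth_difference(cup_pose(ref$center, ax, "postop"), ref),
    "different frames"
  )
})

test_that("signed depth is bounded by the 3D distance, equal iff axial", {
  for (s in 1:20) {
    d <- hipnav:::with_seed(1000 + s, rnorm(3, sd = 4))
    ax <- hipnav:::unit(hipnav:::with_seed(2000 + s, rnorm(3)))
    guide <- cup_pose(c(90, 0, -60) + d, ax)
    ref <- cup_pose(c(90, 0, -60), ax)
    depth <- signed_depth_difference(guide, ref)
    expect_lte(abs(depth), hipnav:::vnorm(d) + 1e-12)
  }
  ax <- hipnav:::unit(c(0.7, 0.1, 0.7))
  guide <- cup_pose(c(90, 0, -60) - 3.5 * ax, ax)
  expect_equal(
    signed_depth_difference(guide, cup_pose(c(90, 0, -60), ax)), -3.5,
    tolerance = 1e-12
  )
})

test_that("cup angles are invariant under a rigid motion of the whole scene", {
  pose <- cup_pose(c(90, 0, -60), hipnav:::unit(c(0.62, 0.26, 0.74)))
  a0 <- operative_angles(pose, frame)
  lm <- canonical_lm()
  for (s in 1:6) {
    g <- seeded_transform(3000 + s)
    pose_g <- transform_cup_pose(g, pose)
    frame_g <- build_app_frame(transform_landmarks(g, lm))
    ag <- operative_angles(pose_g, frame_g)
    expect_equal(ag$anteversion, a0$anteversion, tolerance = 1e-9)
    expect_equal(ag$inclination, a0$inclination, tolerance = 1e-9)
  }
})

test_that("mirroring the scene across the sagittal plane preserves the angles", {
  lm <- canonical_lm()
  mir <- function(p) c(-p[1], p[2], p[3])
  lm_l <- pelvic_landmarks(
    asis_left = mir(lm$asis_right), asis_right = mir(lm$asis_left),
    pubic_left = mir(lm$pubic_right), pubic_right = mir(lm$pubic_left)
  )
  frame_l <- build_app_frame(lm_l, side = "left")
  for (av in seq(-20, 30, by = 10)) {
    for (inc in seq(20, 60, by = 10)) {
      ax_r <- axis_from_operative_angles(cup_angles(av, inc, "operative"), frame)
      pose_l <- cup_pose(mir(c(90, 0, -60)), mir(ax_r))
      al <- operative_angles(pose_l, frame_l)
      expect_equal(al$anteversion, av, tolerance = 1e-9)
      expect_equal(al$inclination, inc, tolerance = 1e-9)
    }
  }
})

test_that("cup poses survive JSON and CSV round trips", {
  pose <- cup_pose(c(91.25, -4.5, -61.75), c(0.62, 0.26, 0.74), "preop")
  for (ext in c(".json", ".csv")) {
    path <- tempfile(fileext = ext)
    write_cup_pose(pose, path)
    back <- read_cup_pose(path)
    expect_equal(back$center, pose$center, tolerance = 1e-9)
    expect_equal(back$axis, pose$axis, tolerance = 1e-9)
    expect_identical(back$frame_id, "preop")
  }
})
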
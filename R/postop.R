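#' Register the post-op scene to pre-op coordinates
#'
#' Dense surface registration: the post-op mesh vertices act as the point
#' set and are aligned to the pre-op surface by multi-start ICP, standing in
#' for the volume registration between pre- and post-op scans of a rigid
#' pelvis. Returns the transform and the alignment accuracy (mean
#' nearest-surface distance of the aligned post-op vertices).
#'
#' @param postop_mesh,preop_mesh `surface_mesh` objects of the same pelvis.
#' @param params list: `max_points` (vertex subsample cap, default 1000),
#'   `n_starts` (default 4), `seed` (default 1), `perturb_rot_deg` /
#'   `perturb_trans_mm` (defaults 10 / 10), `accuracy_ceiling_mm` (default
#'   1.0; exceeding it sets a warning flag), plus ICP tolerances.
#' @return List with `transform` (post-op frame -> pre-op frame),
#'   `accuracy_mm`, `accuracy_warning` and the underlying
#'   `registration_result` as `fit`.
#' @export
register_postop_to_preop <- function(postop_mesh, preop_mesh, params = list()) {
  stopifnot(
    inherits(postop_mesh, "surface_mesh"),
    inherits(preop_mesh, "surface_mesh")
  )
  max_points <- params[["max_points"]] %||% 400L
  # coarse main-loop tolerance: the point-to-plane polish supplies the final
  # precision, so the point-to-point phase only needs to reach the basin
  params$tol_mm <- params[["tol_mm"]] %||% 1e-4
  params$max_iter <- params[["max_iter"]] %||% 80L
  nv <- nrow(postop_mesh$vertices)
  idx <- if (nv > max_points) {
    # deterministic even subsample across the vertex grid
    unique(round(seq(1L, nv, length.out = max_points)))
  } else {
    seq_len(nv)
  }
  pts <- point_set(postop_mesh$vertices[idx, , drop = FALSE])
  init <- rigid_transform(
    translation = colMeans(preop_mesh$vertices) - colMeans(pts$points)
  )
  fit <- multistart_register(
    pts, preop_mesh,
    n_starts = params[["n_starts"]] %||% 2L,
    seed = params[["seed"]] %||% 1L,
    perturb_rot_deg = params[["perturb_rot_deg"]] %||% 10,
    perturb_trans_mm = params[["perturb_trans_mm"]] %||% 10,
    init = init,
    params = params
  )
  accuracy <- alignment_accuracy(
    apply_transform(fit$transform, postop_mesh$vertices), preop_mesh
  )
  ceiling_mm <- params[["accuracy_ceiling_mm"]] %||% 1.0
  warn <- accuracy > ceiling_mm
  if (warn) {
    warning(sprintf(
      "post-op alignment accuracy %.3f mm exceeds the %.2f mm ceiling",
      accuracy, ceiling_mm
    ))
  }
  list(
    transform = fit$transform, accuracy_mm = accuracy,
    accuracy_warning = warn, fit = fit
  )
}

#' Navigation error of one measurement
#'
#' The difference between what the guide tool displayed and the post-op CT
#' examination value, both expressed in the pre-op pelvic frame:
#' `d_anteversion = guide - postop` (degrees, operative convention),
#' `d_inclination` likewise, and `d_depth` the signed depth of the guide cup
#' relative to the post-op cup along the guide axis (mm, positive lateral).
#'
#' @param guide guide-tool `cup_pose` (pre-op frame).
#' @param postop_in_preop post-op `cup_pose` transformed to the pre-op frame.
#' @param frame the pre-op `pelvic_frame` used for the angle readout.
#' @param case_id,rater_id identifiers carried into the study table.
#' @return A one-row `data.frame` (class `navigation_error`) with columns
#'   `case_id`, `rater_id`, `d_anteversion`, `d_inclination`, `d_depth`.
#' @export
navigation_error <- function(guide, postop_in_preop, frame,
                             case_id = NA, rater_id = NA) {
  stopifnot(
    inherits(guide, "cup_pose"), inherits(postop_in_preop, "cup_pose"),
    inherits(frame, "pelvic_frame")
  )
  if (!identical(guide$frame_id, postop_in_preop$frame_id)) {
    stop("guide and post-op poses are expressed in different frames ('",
      guide$frame_id, "' vs '", postop_in_preop$frame_id, "')",
      call. = FALSE
    )
  }
  ga <- operative_angles(guide, frame)
  pa <- operative_angles(postop_in_preop, frame)
  out <- data.frame(
    case_id = case_id, rater_id = rater_id,
    d_anteversion = ga$anteversion - pa$anteversion,
    d_inclination = ga$inclination - pa$inclination,
    d_depth = signed_depth_difference(guide, postop_in_preop)
  )
  class(out) <- c("navigation_error", class(out))
  out
}

#' Guide-tool readout for one rater
#'
#' Runs the patient alignment on a rater's probed points and maps the cup
#' pose observed in that rater's tracking frame into the pre-op model frame
#' — exactly what the navigation display shows the surgeon.
#'
#' @param points the rater's probed `point_set` (tracking frame).
#' @param mesh the pre-op `surface_mesh`.
#' @param rater_cup the `cup_pose` as measured in the rater's tracking frame.
#' @param config a `scene_config` providing the multi-start settings.
#' @param seed seed for the alignment multi-start.
#' @param offset_deg optional deliberate anteversion offset added to the
#'   displayed cup axis (degrees), used for linearity probes.
#' @param frame `pelvic_frame` (required when `offset_deg != 0`).
#' @return List with `cup` (guide `cup_pose` in `"preop"` frame),
#'   `alignment` (the `registration_result`).
#' @export
guide_readout <- function(points, mesh, rater_cup, config, seed = 1L,
                          offset_deg = 0, frame = NULL) {
  fit <- multistart_register(
    points, mesh,
    n_starts = config$n_starts, seed = seed,
    perturb_rot_deg = config$perturb_rot_deg,
    perturb_trans_mm = config$perturb_trans_mm,
    params = list(tol_mm = 1e-5, max_iter = 80L)
  )
  cup <- transform_cup_pose(fit$transform, rater_cup, "preop")
  if (offset_deg != 0) {
    if (is.null(frame)) stop("frame is required to apply an angle offset")
    ang <- operative_angles(cup, frame)
    cup <- cup_pose(
      cup$center,
      axis_from_operative_angles(
        cup_angles(ang$anteversion + offset_deg, ang$inclination, "operative"),
        frame
      ),
      "preop"
    )
  }
  list(cup = cup, alignment = fit)
}

#' Assess one simulated case end to end
#'
#' For each rater: patient alignment, guide readout; once per case: post-op
#' to pre-op registration and cup transfer; then the navigation errors
#' guide-minus-post-op per rater. Only observables are consumed — the case's
#' ground truth is ignored (and may be withheld).
#'
#' @param case a `synthetic_case`.
#' @param case_id identifier for the output rows.
#' @param offset_deg deliberate guide-side anteversion offset (degrees).
#' @param postop_params parameters for [register_postop_to_preop()].
#' @return List with `errors` (one `navigation_error` row per rater, with an
#'   `accuracy_mm` column), `postop` (the post-op registration), and
#'   `alignments` (per-rater registration results).
#' @export
assess_case <- function(case, case_id = case$config$seed, offset_deg = 0,
                        postop_params = list()) {
  stopifnot(inherits(case, "synthetic_case"))
  cfg <- case$config
  postop_params$seed <- postop_params[["seed"]] %||% child_seed(cfg$seed, "postop-reg")
  post <- register_postop_to_preop(case$postop_mesh, case$preop_mesh, postop_params)
  postop_cup_preop <- transform_cup_pose(post$transform, case$postop_cup, "preop")

  rows <- list()
  alignments <- list()
  for (r in seq_along(case$rater_samples)) {
    readout <- guide_readout(
      case$rater_samples[[r]], case$preop_mesh, case$rater_cups[[r]], cfg,
      seed = child_seed(cfg$seed, "align", r),
      offset_deg = offset_deg, frame = case$frame
    )
    err <- navigation_error(
      readout$cup, postop_cup_preop, case$frame,
      case_id = case_id, rater_id = r
    )
    err$accuracy_mm <- post$accuracy_mm
    err$alignment_rms_mm <- readout$alignment$rms_residual
    rows[[r]] <- err
    alignments[[r]] <- readout$alignment
  }
  list(
    errors = do.call(rbind, rows),
    postop = post,
    alignments = alignments
  )
}
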
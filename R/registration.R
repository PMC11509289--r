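#' Sparse point-to-surface rigid registration (patient alignment)
#'
#' Iterative closest point: alternate exact nearest-surface correspondence
#' with a Kabsch least-squares rigid update until the RMS point-to-surface
#' residual stops changing. This is the intra-operative "patient alignment"
#' that matches probed bone points to the CT-derived pelvis model by
#' minimising the overall point-to-surface distance; the objective is
#' guaranteed non-increasing across iterations and this is asserted on every
#' run.
#'
#' @param points a `point_set` in the probe (source) frame.
#' @param mesh the `surface_mesh` model (target frame).
#' @param init initial `rigid_transform` from the points' frame to the
#'   model frame.
#' @param params list of tolerances: `tol_mm` (RMS change threshold, default
#'   `1e-6`) and `max_iter` (default 200).
#' @return A `registration_result`: `transform` (points-frame to
#'   model-frame), `rms_residual`, `mean_residual`, `per_point_residuals`
#'   (mm), `iterations`, `converged`, and the per-iteration `trace` of RMS
#'   values.
#' @export
icp_point_to_surface <- function(points, mesh, init = identity_transform(),
                                 params = list()) {
  stopifnot(inherits(points, "point_set"), inherits(mesh, "surface_mesh"))
  if (nrow(points$points) < 6L) {
    stop("at least 6 registration points are required", call. = FALSE)
  }
  tol <- params[["tol_mm"]] %||% 1e-6
  max_iter <- params[["max_iter"]] %||% 200L

  p <- points$points
  t_cur <- init
  trace <- numeric(0)
  rms_prev <- Inf
  converged <- FALSE
  iters <- 0L
  res <- NULL
  for (k in seq_len(max_iter)) {
    iters <- k
    moved <- apply_transform(t_cur, p)
    res <- mesh_query(mesh, moved)
    rms <- sqrt(mean(res$distance^2))
    if (rms > rms_prev + 1e-9) {
      stop(
        "ICP objective increased (", format(rms_prev), " -> ", format(rms),
        " mm): monotonicity invariant breached"
      )
    }
    trace <- c(trace, rms)
    if (is.finite(rms_prev) && abs(rms_prev - rms) < tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    # Kabsch against the fixed correspondences: minimises point-to-point
    # distance to the current foot points, which upper-bounds the new
    # point-to-surface objective -- hence monotone descent.
    t_cur <- kabsch_align(p, res$point)
  }
  # Point-to-plane polish: point-to-point ICP converges only linearly and can
  # stall at facet-scale local minima; a few Gauss-Newton steps against the
  # foot-point tangent planes settle the fit to machine precision. Steps are
  # accepted only if the point-to-surface RMS does not increase, preserving
  # the monotone objective.
  if (isTRUE(params[["polish"]] %||% TRUE)) {
    pol <- icp_polish(p, mesh, t_cur, trace[length(trace)],
      max_iter = params[["polish_iter"]] %||% 30L
    )
    t_cur <- pol$transform
    trace <- c(trace, pol$trace)
    res <- mesh_query(mesh, apply_transform(t_cur, p))
  }
  registration_result(
    transform = t_cur,
    per_point_residuals = res$distance,
    iterations = iters, converged = converged, trace = trace
  )
}

icp_polish <- function(p, mesh, t_cur, rms_cur, max_iter = 30L) {
  trace <- numeric(0)
  for (k in seq_len(max_iter)) {
    moved <- apply_transform(t_cur, p)
    res <- mesh_query(mesh, moved)
    normals <- face_normals(mesh$vertices, mesh$faces[res$face, , drop = FALSE])
    r <- rowSums((moved - res$point) * normals)
    jac <- cbind(
      # d(residual)/d(rotation vector): (p x n)
      moved[, 2] * normals[, 3] - moved[, 3] * normals[, 2],
      moved[, 3] * normals[, 1] - moved[, 1] * normals[, 3],
      moved[, 1] * normals[, 2] - moved[, 2] * normals[, 1],
      normals
    )
    delta <- tryCatch(
      solve(crossprod(jac) + 1e-12 * diag(6), -crossprod(jac, r)),
      error = function(e) NULL
    )
    if (is.null(delta)) break
    accepted <- FALSE
    step <- 1
    for (h in 1:8) { # backtracking: accept only a non-increasing objective
      d <- delta * step
      w <- d[1:3]
      ang <- vnorm(w)
      rot <- if (ang < 1e-12) diag(3) else rotation_about_axis(w, rad2deg(ang))
      t_try <- compose_transforms(rigid_transform(rot, d[4:6]), t_cur)
      rms_try <- sqrt(mean(mesh_query(mesh, apply_transform(t_try, p))$distance^2))
      if (rms_try <= rms_cur * (1 + 1e-12) + 1e-15) {
        accepted <- TRUE
        t_cur <- t_try
        rms_cur <- rms_try
        trace <- c(trace, rms_try)
        break
      }
      step <- step / 2
    }
    # converge in parameter space (radians + mm): Gauss-Newton is quadratic
    # near the optimum, so this settles the fit to machine precision
    if (!accepted || vnorm(delta * step) < 1e-10) break
  }
  list(transform = t_cur, trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

registration_result <- function(transform, per_point_residuals, iterations,
                                converged, trace, extra = list()) {
  out <- c(
    list(
      transform = transform,
      rms_residual = sqrt(mean(per_point_residuals^2)),
      mean_residual = mean(per_point_residuals),
      per_point_residuals = as.numeric(per_point_residuals),
      iterations = as.integer(iterations),
      converged = isTRUE(converged),
      trace = as.numeric(trace)
    ),
    extra
  )
  class(out) <- "registration_result"
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> rms %.4f mm, mean %.4f mm, %d iterations (%s)\n",
    x$rms_residual, x$mean_residual, x$iterations,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Coarse alignment from region centroids
#'
#' Kabsch superposition of the per-region centroids of a labelled point set
#' onto the corresponding mesh-region centroids. With fewer than three
#' regions the rotation is unconstrained and a translation-only centroid
#' match is returned.
#'
#' @param points a labelled `point_set`.
#' @param mesh a `surface_mesh` with named `regions`.
#' @return A `rigid_transform` initial guess (points-frame to model-frame).
#' @export
coarse_align_regions <- function(points, mesh) {
  stopifnot(inherits(points, "point_set"), inherits(mesh, "surface_mesh"))
  labs <- points$labels
  common <- if (is.null(labs) || is.null(mesh$regions)) {
    character(0)
  } else {
    intersect(unique(labs), names(mesh$regions))
  }
  if (length(common) >= 3L) {
    src <- t(vapply(common, function(r) {
      colMeans(points$points[labs == r, , drop = FALSE])
    }, numeric(3)))
    dst <- t(vapply(common, function(r) {
      region_centroid(mesh, r)
    }, numeric(3)))
    fit <- try(kabsch_align(src, dst), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      return(fit)
    }
  }
  # degenerate or unlabelled: translation-only centroid match
  rigid_transform(
    translation = colMeans(mesh$vertices) - colMeans(points$points)
  )
}

region_centroid <- function(mesh, region) {
  fid <- mesh$regions[[region]]
  if (is.null(fid) || !length(fid)) {
    stop("mesh has no region '", region, "'", call. = FALSE)
  }
  f <- mesh$faces[fid, , drop = FALSE]
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c_ <- mesh$vertices[f[, 3], , drop = FALSE]
  w <- triangle_areas(mesh$vertices, f)
  colSums((a + b + c_) / 3 * w) / sum(w)
}

#' Multi-start sparse registration
#'
#' Runs ICP from a coarse region-centroid alignment plus `n_starts - 1`
#' randomly perturbed initialisations, returning the result with the
#' smallest RMS point-to-surface residual. This stands in for the navigation
#' system's global search over the same objective and is deterministic for a
#' given seed.
#'
#' @param points a labelled `point_set`.
#' @param mesh a `surface_mesh` with regions.
#' @param n_starts number of ICP starts (the first is the unperturbed coarse
#'   alignment).
#' @param seed integer seed for the perturbation draws.
#' @param perturb_rot_deg,perturb_trans_mm perturbation magnitudes around the
#'   coarse alignment.
#' @param init optional explicit initial transform overriding the coarse
#'   region alignment.
#' @param params ICP tolerances (see [icp_point_to_surface()]); additionally
#'   `polish_top` (how many leading starts receive the point-to-plane
#'   polish, default 3) and `polish_iter`.
#' @return The best `registration_result`, with `start_rms` (per-start final
#'   RMS residuals) attached.
#' @export
multistart_register <- function(points, mesh, n_starts = 16L, seed = 1L,
                                perturb_rot_deg = 15, perturb_trans_mm = 20,
                                init = NULL, params = list()) {
  stopifnot(inherits(points, "point_set"), inherits(mesh, "surface_mesh"))
  base_init <- init %||% coarse_align_regions(points, mesh)
  starts <- list(base_init)
  if (n_starts > 1L) {
    perturbs <- with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i) {
        random_transform(perturb_rot_deg, perturb_trans_mm)
      })
    })
    # perturb about the point-set centroid so rotations do not fling the
    # points far from the surface
    centroid <- colMeans(apply_transform(base_init, points$points))
    for (p in perturbs) {
      r <- p$rotation
      t_about <- rigid_transform(
        rotation = r,
        translation = as.numeric(centroid - r %*% centroid + p$translation)
      )
      starts <- c(starts, list(compose_transforms(t_about, base_init)))
    }
  }
  # per-start runs skip the point-to-plane polish; only the winner is polished
  start_params <- params
  start_params$polish <- FALSE
  results <- vector("list", length(starts))
  errors <- character(length(starts))
  for (i in seq_along(starts)) {
    fit <- try(icp_point_to_surface(points, mesh, starts[[i]], start_params),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) {
      errors[i] <- as.character(fit)
    } else {
      results[[i]] <- fit
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) {
    stop(
      "all ", length(starts), " registration starts failed:\n",
      paste(unique(errors[nzchar(errors)]), collapse = "\n")
    )
  }
  rms <- vapply(results, function(r) if (is.null(r)) Inf else r$rms_residual, 0)
  if (isTRUE(params[["polish"]] %||% TRUE)) {
    # polish the leading starts (plus the unperturbed coarse start): the
    # point-to-plane refinement can rescue a basin that ranks behind on the
    # unpolished objective
    k <- min(params[["polish_top"]] %||% 3L, sum(is.finite(rms)))
    cand <- unique(c(order(rms)[seq_len(k)], if (is.finite(rms[1])) 1L))
    best <- NULL
    for (i in cand) {
      pol <- icp_polish(
        points$points, mesh, results[[i]]$transform, results[[i]]$rms_residual,
        max_iter = params[["polish_iter"]] %||% 30L
      )
      res <- mesh_query(mesh, apply_transform(pol$transform, points$points))
      fit <- registration_result(
        transform = pol$transform,
        per_point_residuals = res$distance,
        iterations = results[[i]]$iterations,
        converged = results[[i]]$converged,
        trace = c(results[[i]]$trace, pol$trace)
      )
      if (is.null(best) || fit$rms_residual < best$rms_residual) best <- fit
    }
  } else {
    best <- results[[which.min(rms)]]
  }
  best$start_rms <- rms
  best
}

#' Control-screw validation of an alignment
#'
#' After patient alignment, the surgeon re-probes a fixed bone screw; the
#' residual between the aligned probe position and the screw's model-side
#' position validates the registration. The check passes when the residual
#' is at or below the tolerance (inclusive).
#'
#' @param measured probed screw position (length-3, probe frame, mm).
#' @param model_point screw position in the model frame (length-3, mm).
#' @param t alignment `rigid_transform` (probe frame to model frame).
#' @param tol_mm pass tolerance in mm (default 1.0).
#' @return List with `pass` (logical) and `residual` (mm).
#' @export
control_screw_check <- function(measured, model_point, t, tol_mm = 1.0) {
  stopifnot(inherits(t, "rigid_transform"))
  if (!is.numeric(tol_mm) || tol_mm <= 0) {
    stop("tol_mm must be positive", call. = FALSE)
  }
  residual <- vnorm(apply_transform(t, as.numeric(measured)) - as.numeric(model_point))
  list(pass = residual <= tol_mm, residual = residual)
}
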
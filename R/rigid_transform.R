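#' Rigid transforms in 3D
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation in millimetres. It is the
#' currency of the whole pipeline: patient alignment, post-op-to-pre-op
#' registration and cup-pose transfer all produce or consume one.
#'
#' @param rotation 3x3 proper orthonormal rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 17), c(1, 2, 3))
#' apply_transform(t1, c(10, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L))) {
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != 3L) {
    stop("translation must have length 3", call. = FALSE)
  }
  stopifnot_finite(rotation, "rotation")
  stopifnot_finite(translation, "translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal (tolerance 1e-9)", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (det = +1); reflections are not rigid motions",
      call. = FALSE
    )
  }
  structure(
    list(rotation = rotation, translation = translation),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat(sprintf(
    "  rotation angle: %.4f deg, translation: [%.3f, %.3f, %.3f] mm\n",
    rotation_angle_deg(x), x$translation[1], x$translation[2], x$translation[3]
  ))
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` that leaves every point unchanged.
#' @export
identity_transform <- function() rigid_transform()

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; used to build test transforms and perturbation starts.
#'
#' @param axis numeric length-3 rotation axis (any non-zero vector).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit(as.numeric(axis))
  th <- deg2rad(angle_deg)
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param x a length-3 vector or an n x 3 matrix of points (mm).
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(t, x) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.matrix(x)) {
    sweep(x %*% t(t$rotation), 2, t$translation, "+")
  } else {
    as.numeric(t$rotation %*% x + t$translation)
  }
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`:
#' `T(x) = a(b(x))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(
    rotation = a$rotation %*% b$rotation,
    translation = as.numeric(a$rotation %*% b$translation + a$translation)
  )
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rt <- t(t$rotation)
  rigid_transform(rotation = rt, translation = as.numeric(-rt %*% t$translation))
}

#' Geodesic rotation magnitude of a transform
#'
#' The angle of the single rotation equivalent to the transform's rotation
#' part, in `[0, 180]` degrees. A convenient scalar diagnostic for
#' registration error.
#'
#' @param t a `rigid_transform` (or bare 3x3 rotation matrix).
#' @return Rotation magnitude in degrees.
#' @export
rotation_angle_deg <- function(t) {
  r <- if (inherits(t, "rigid_transform")) t$rotation else t
  # clamp: round-off can push the trace marginally outside [-1, 3]
  ctheta <- (sum(diag(r)) - 1) / 2
  rad2deg(acos(min(1, max(-1, ctheta))))
}

#' Random rigid transform (seeded)
#'
#' Uniform random rotation axis, rotation angle uniform in
#' `[0, max_angle_deg]`, translation uniform in a cube. Used for
#' perturbation starts and equivariance checks.
#'
#' @param max_angle_deg largest rotation magnitude (degrees).
#' @param max_translation_mm largest per-component translation (mm).
#' @return A `rigid_transform`.
#' @export
random_transform <- function(max_angle_deg = 180, max_translation_mm = 50) {
  ax <- rnorm(3)
  while (vnorm(ax) < 1e-6) ax <- rnorm(3)
  rigid_transform(
    rotation = rotation_about_axis(ax, runif(1, 0, max_angle_deg)),
    translation = runif(3, -max_translation_mm, max_translation_mm)
  )
}

#' Serialize / deserialize a transform as JSON
#'
#' The rotation is stored row-major as a flat 9-vector alongside the
#' 3-vector translation, so files are portable across tools.
#'
#' @param t a `rigid_transform`.
#' @param path file path to write to / read from.
#' @return `read_transform_json` returns a `rigid_transform`;
#'   `write_transform_json` returns `path` invisibly.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  obj <- list(
    rotation_row_major = as.numeric(t(t$rotation)),
    translation_mm = t$translation
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(
    rotation = matrix(obj$rotation_row_major, 3, 3, byrow = TRUE),
    translation = obj$translation_mm
  )
}
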
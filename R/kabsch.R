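#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rigid transform `T` minimising
#' `sum_i || T(src_i) - dst_i ||^2` over proper rotations and translations.
#' The SVD sign correction rejects reflections, so an anatomical surface can
#' never be mirrored by an alignment step.
#'
#' @param src,dst `point_set` objects (or n x 3 matrices) of equal length
#'   n >= 3, in corresponding order.
#' @return A `rigid_transform` mapping `src` onto `dst`.
#' @examples
#' src <- matrix(rnorm(30), 10, 3)
#' t0 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 17), c(1, 2, 3))
#' t_hat <- kabsch_align(src, apply_transform(t0, src))
#' rotation_angle_deg(compose_transforms(invert_transform(t_hat), t0)) # ~0
#' @export
kabsch_align <- function(src, dst) {
  p <- if (inherits(src, "point_set")) src$points else as.matrix(src)
  q <- if (inherits(dst, "point_set")) dst$points else as.matrix(dst)
  if (nrow(p) != nrow(q)) {
    stop("src and dst must contain the same number of points", call. = FALSE)
  }
  if (nrow(p) < 3L) {
    stop("at least 3 point correspondences are required", call. = FALSE)
  }
  stopifnot_finite(p, "src")
  stopifnot_finite(q, "dst")
  pc <- colMeans(p)
  qc <- colMeans(q)
  p0 <- sweep(p, 2, pc)
  q0 <- sweep(q, 2, qc)
  h <- crossprod(p0, q0) # 3x3 covariance
  if (qr(h)$rank < 2L) {
    stop("degenerate correspondence geometry: covariance rank < 2 ",
      "(points are collinear or coincident)",
      call. = FALSE
    )
  }
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(rotation = r, translation = as.numeric(qc - r %*% pc))
}

#' Root-mean-square residual of a correspondence fit
#'
#' @param t a `rigid_transform`.
#' @param src,dst corresponding point matrices / `point_set`s.
#' @return RMS of `|| t(src_i) - dst_i ||` in mm.
#' @export
kabsch_rms <- function(t, src, dst) {
  p <- if (inherits(src, "point_set")) src$points else as.matrix(src)
  q <- if (inherits(dst, "point_set")) dst$points else as.matrix(dst)
  sqrt(mean(rowSums((apply_transform(t, p) - q)^2)))
}
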
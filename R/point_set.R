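#' Labelled 3D point sets
#'
#' An ordered set of 3D points in millimetres with optional per-point region
#' labels. Intra-operative registration points (the probed bone-surface
#' points) are carried as a `point_set`; the labels record which pelvic
#' region each point was taken from and drive the coarse alignment prior.
#'
#' @param points n x 3 numeric matrix of coordinates (mm), n >= 1.
#' @param labels optional character vector of per-point region tags.
#' @return An object of class `point_set` with elements `points` and `labels`.
#' @export
point_set <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L) {
    stop("points must be an n x 3 matrix with n >= 1", call. = FALSE)
  }
  storage.mode(points) <- "double"
  stopifnot_finite(points, "points")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(points)) {
      stop("labels must match the number of points", call. = FALSE)
    }
  }
  structure(list(points = points, labels = labels), class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf(
    "<point_set> %d points%s\n", nrow(x$points),
    if (is.null(x$labels)) "" else sprintf(" in %d regions", length(unique(x$labels)))
  ))
  invisible(x)
}

#' Apply a rigid transform to a point set
#' @param t a `rigid_transform`.
#' @param ps a `point_set`.
#' @return The transformed `point_set` (labels preserved).
#' @export
transform_point_set <- function(t, ps) {
  stopifnot(inherits(ps, "point_set"))
  point_set(apply_transform(t, ps$points), ps$labels)
}

#' Read / write point sets as CSV
#'
#' Columns `label,x,y,z` with coordinates in mm; `label` may be empty.
#'
#' @param ps a `point_set`.
#' @param path CSV file path.
#' @return `read_points_csv` returns a `point_set`; `write_points_csv`
#'   returns `path` invisibly.
#' @export
write_points_csv <- function(ps, path) {
  stopifnot(inherits(ps, "point_set"))
  df <- data.frame(
    label = if (is.null(ps$labels)) rep("", nrow(ps$points)) else ps$labels,
    x = ps$points[, 1], y = ps$points[, 2], z = ps$points[, 3]
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("point CSV must have columns x, y, z", call. = FALSE)
  }
  labels <- if ("label" %in% names(df) && any(nzchar(df$label))) df$label else NULL
  point_set(as.matrix(df[, need]), labels)
}
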
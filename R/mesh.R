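#' Triangulated bone surface
#'
#' A triangle mesh with vertices in millimetres, the container for segmented
#' bone surfaces. Watertightness is not required; degenerate (zero-area)
#' faces are rejected.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param regions optional named list mapping region names to integer vectors
#'   of face indices (used by the registration-point sampler).
#' @param min_area smallest admissible triangle area (mm^2).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, regions = NULL, min_area = 1e-9) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    stop("vertices and faces must have 3 columns", call. = FALSE)
  }
  stopifnot_finite(vertices, "vertices")
  if (nrow(faces) < 1L) stop("mesh must have at least one face", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of vertex range", call. = FALSE)
  }
  areas <- triangle_areas(vertices, faces)
  if (any(areas <= min_area)) {
    stop(sum(areas <= min_area), " degenerate (zero-area) faces", call. = FALSE)
  }
  if (!is.null(regions)) {
    stopifnot(is.list(regions), !is.null(names(regions)))
    for (r in regions) {
      if (length(r) && (min(r) < 1L || max(r) > nrow(faces))) {
        stop("region face indices out of range", call. = FALSE)
      }
    }
  }
  structure(
    list(
      vertices = vertices, faces = faces, regions = regions,
      # lazily built spatial index; environment so copies share the cache
      cache = new.env(parent = emptyenv())
    ),
    class = "surface_mesh"
  )
}

# nearest-surface query through the mesh's cached spatial index
mesh_query <- function(mesh, queries) {
  idx <- mesh$cache$index
  if (is.null(idx) || !cpp_index_valid(idx)) {
    idx <- cpp_mesh_index(mesh$vertices, mesh$faces)
    mesh$cache$index <- idx
  }
  cpp_index_query(idx, queries)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<surface_mesh> %d vertices, %d faces%s\n",
    nrow(x$vertices), nrow(x$faces),
    if (is.null(x$regions)) {
      ""
    } else {
      paste0(", regions: ", paste(names(x$regions), collapse = ", "))
    }
  ))
  invisible(x)
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Apply a rigid transform to a mesh
#' @param t a `rigid_transform`.
#' @param mesh a `surface_mesh`.
#' @return The transformed `surface_mesh` (faces and regions preserved).
#' @export
transform_mesh <- function(t, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  out <- surface_mesh(apply_transform(t, mesh$vertices), mesh$faces, mesh$regions)
  if (!is.null(mesh$acetabulum)) {
    out$acetabulum <- list(
      center = apply_transform(t, mesh$acetabulum$center),
      radius = mesh$acetabulum$radius,
      axis = as.numeric(t$rotation %*% mesh$acetabulum$axis)
    )
  }
  out
}

#' Exact nearest point on a surface
#'
#' For each query point, the exact closest point on any triangle of the mesh
#' (interior, edge or vertex) and its Euclidean distance, computed by exact
#' closest-point-on-triangle tests with centroid-distance culling.
#'
#' @param mesh a `surface_mesh`.
#' @param p a length-3 point or n x 3 matrix of query points (mm).
#' @return For a single point, a list with `point`, `distance` (mm) and
#'   `face`; for a matrix, the same fields vectorised over queries.
#' @export
nearest_surface_point <- function(mesh, p) {
  stopifnot(inherits(mesh, "surface_mesh"))
  single <- !is.matrix(p)
  q <- if (single) matrix(as.numeric(p), 1, 3) else as.matrix(p)
  stopifnot_finite(q, "query points")
  res <- mesh_query(mesh, q)
  if (single) {
    list(
      point = as.numeric(res$point[1, ]), distance = res$distance[1],
      face = res$face[1]
    )
  } else {
    res
  }
}

#' Mean point-to-surface alignment accuracy
#'
#' Mean nearest-surface distance from a set of points (or the vertices of an
#' aligned mesh) to a reference surface, in mm — the score used to judge how
#' well two pelvis surfaces agree after registration. Note the measure is
#' asymmetric: `alignment_accuracy(A, B)` generally differs from
#' `alignment_accuracy(B, A)`; report both when comparing meshes.
#'
#' @param points_a a `point_set`, n x 3 matrix, or `surface_mesh` (its
#'   vertices are used).
#' @param mesh_b the reference `surface_mesh`.
#' @return Mean distance in mm.
#' @export
alignment_accuracy <- function(points_a, mesh_b) {
  stopifnot(inherits(mesh_b, "surface_mesh"))
  p <- if (inherits(points_a, "surface_mesh")) {
    points_a$vertices
  } else if (inherits(points_a, "point_set")) {
    points_a$points
  } else {
    as.matrix(points_a)
  }
  if (nrow(p) < 1L) stop("no query points", call. = FALSE)
  mean(mesh_query(mesh_b, p)$distance)
}

# ---- STL / PLY input-output ------------------------------------------------

#' Read and write surface meshes (STL, PLY)
#'
#' `write_mesh` writes ASCII STL or ASCII PLY by file extension; `read_mesh`
#' reads ASCII or binary STL and ASCII PLY. STL stores no connectivity, so
#' on reading, vertices closer than `weld_tol` are merged.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path ending in `.stl` or `.ply`.
#' @param weld_tol vertex-merge tolerance for STL reading (mm).
#' @return `read_mesh` returns a `surface_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    write_stl_ascii(mesh, path)
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    write_ply_ascii(mesh, path)
  } else {
    stop("unsupported mesh format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, weld_tol = 1e-6) {
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    read_stl(path, weld_tol)
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    read_ply_ascii(path)
  } else {
    stop("unsupported mesh format: ", path, call. = FALSE)
  }
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  n <- cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(v, f)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid hipnav", con)
  fmt <- function(x) sprintf("%.9g", x)
  lines <- character(7 * nrow(f))
  k <- 1L
  for (i in seq_len(nrow(f))) {
    lines[k] <- paste(
      "  facet normal", fmt(n[i, 1]), fmt(n[i, 2]), fmt(n[i, 3])
    )
    lines[k + 1L] <- "    outer loop"
    for (j in 1:3) {
      p <- v[f[i, j], ]
      lines[k + 1L + j] <- paste("      vertex", fmt(p[1]), fmt(p[2]), fmt(p[3]))
    }
    lines[k + 5L] <- "    endloop"
    lines[k + 6L] <- "  endfacet"
    k <- k + 7L
  }
  writeLines(lines, con)
  writeLines("endsolid hipnav", con)
}

weld_vertices <- function(tri_vertices, weld_tol) {
  key <- apply(round(tri_vertices / max(weld_tol, 1e-12)), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  list(vertices = tri_vertices[first, , drop = FALSE], index = idx)
}

read_stl <- function(path, weld_tol = 1e-6) {
  # sniff: binary STL has an 80-byte header then uint32 facet count
  head <- readBin(path, "raw", n = 84)
  is_ascii <- grepl("^solid", rawToChar(head[1:5]))
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
      as.numeric(x[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    nums <- matrix(NA_real_, 3 * nf, 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      nums[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", n = 2) # attribute byte count
    }
  }
  if (is.null(nums) || nrow(nums) %% 3 != 0) {
    stop("malformed STL file: ", path, call. = FALSE)
  }
  w <- weld_vertices(nums, weld_tol)
  faces <- matrix(w$index, ncol = 3, byrow = TRUE)
  surface_mesh(w$vertices, faces)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment hipnav surface mesh",
    paste("element vertex", nrow(v)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

read_ply_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!identical(txt[1], "ply")) stop("not a PLY file: ", path, call. = FALSE)
  endh <- match("end_header", txt)
  if (is.na(endh)) stop("PLY header not terminated", call. = FALSE)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", txt, value = TRUE)[1]))
  body <- txt[(endh + 1):length(txt)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- do.call(rbind, lapply(vparts, function(x) as.numeric(x[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- do.call(rbind, lapply(fparts, function(x) as.integer(x[2:4]) + 1L))
  surface_mesh(v, f)
}
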
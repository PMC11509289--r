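#' Acetabular cup pose
#'
#' A cup pose is the centre of rotation of the cup (mm) plus the unit opening
#' axis, pointing out of the acetabulum (laterally for an implanted cup).
#' `frame_id` records which coordinate system the pose is expressed in;
#' operations that combine two poses require matching frames.
#'
#' @param center length-3 cup centre (mm).
#' @param axis length-3 opening axis; normalised to unit length on input.
#' @param frame_id character tag of the coordinate system (e.g. `"preop"`).
#' @return An object of class `cup_pose`.
#' @export
cup_pose <- function(center, axis, frame_id = "preop") {
  center <- as.numeric(center)
  axis <- as.numeric(axis)
  if (length(center) != 3L || length(axis) != 3L) {
    stop("center and axis must have length 3", call. = FALSE)
  }
  stopifnot_finite(center, "center")
  stopifnot_finite(axis, "axis")
  structure(
    list(center = center, axis = unit(axis), frame_id = as.character(frame_id)),
    class = "cup_pose"
  )
}

#' @export
print.cup_pose <- function(x, ...) {
  cat(sprintf(
    "<cup_pose> [%s] center (%.2f, %.2f, %.2f) mm, axis (%.4f, %.4f, %.4f)\n",
    x$frame_id, x$center[1], x$center[2], x$center[3],
    x$axis[1], x$axis[2], x$axis[3]
  ))
  invisible(x)
}

#' Cup orientation angles
#'
#' Anteversion and inclination of the cup axis under one of the three
#' standard conventions (Murray): `"operative"` (the navigation display),
#' `"radiographic"` or `"anatomic"`.
#'
#' @param anteversion,inclination angles in degrees.
#' @param definition one of `"operative"`, `"radiographic"`, `"anatomic"`.
#' @return An object of class `cup_angles`.
#' @export
cup_angles <- function(anteversion, inclination,
                       definition = c("operative", "radiographic", "anatomic")) {
  definition <- match.arg(definition)
  anteversion <- as.numeric(anteversion)
  inclination <- as.numeric(inclination)
  stopifnot_finite(c(anteversion, inclination), "angles")
  if (anteversion <= -90 || anteversion >= 90) {
    stop("anteversion must lie in (-90, 90) degrees", call. = FALSE)
  }
  if (inclination < 0 || inclination > 90) {
    stop("inclination must lie in [0, 90] degrees", call. = FALSE)
  }
  structure(
    list(
      anteversion = anteversion, inclination = inclination,
      definition = definition
    ),
    class = "cup_angles"
  )
}

#' @export
print.cup_angles <- function(x, ...) {
  cat(sprintf(
    "<cup_angles> %s: anteversion %.2f deg, inclination %.2f deg\n",
    x$definition, x$anteversion, x$inclination
  ))
  invisible(x)
}

# Components of the cup axis on the (lateral, anterior, superior) triad.
axis_components <- function(pose, frame) {
  stopifnot(inherits(pose, "cup_pose"), inherits(frame, "pelvic_frame"))
  c(
    l = sum(pose$axis * frame$lateral),
    a = sum(pose$axis * frame$anterior),
    s = sum(pose$axis * frame$superior)
  )
}

# Unit axis from (lateral, anterior, superior) components in a frame.
axis_from_components <- function(comp, frame) {
  unit(
    comp[1] * frame$lateral + comp[2] * frame$anterior + comp[3] * frame$superior
  )
}

# (l, a, s) components for angles under each convention. With unit axis
# components l (lateral), a (anterior), s (superior):
#   operative:    inclination = asin(l),  anteversion = atan2(a, s)
#   radiographic: inclination = atan2(l, s), anteversion = asin(a)
#   anatomic:     inclination = acos(s),  anteversion = atan2(a, l)
angles_to_las <- function(angles) {
  av <- deg2rad(angles$anteversion)
  inc <- deg2rad(angles$inclination)
  switch(angles$definition,
    operative = c(sin(inc), cos(inc) * sin(av), cos(inc) * cos(av)),
    radiographic = c(sin(inc) * cos(av), sin(av), cos(inc) * cos(av)),
    anatomic = c(sin(inc) * cos(av), sin(inc) * sin(av), cos(inc))
  )
}

las_to_angles <- function(las, definition) {
  l <- las[1]
  a <- las[2]
  s <- las[3]
  ang <- switch(definition,
    operative = c(atan2(a, s), asin(min(1, max(-1, l)))),
    radiographic = c(asin(min(1, max(-1, a))), atan2(l, s)),
    anatomic = c(atan2(a, l), acos(min(1, max(-1, s))))
  )
  cup_angles(rad2deg(ang[1]), rad2deg(ang[2]), definition)
}

#' Operative cup angles of a pose in a pelvic frame
#'
#' The operative convention is what the navigation display reports: with
#' unit-axis components `(l, a, s)` on the frame's (lateral, anterior,
#' superior) axes, operative inclination is `asin(l)` and operative
#' anteversion `atan2(a, s)`, both in degrees.
#'
#' @param pose a `cup_pose` expressed in the frame's coordinates, axis
#'   pointing laterally (out of the acetabulum).
#' @param frame a `pelvic_frame`.
#' @param definition angle convention for the readout (default operative).
#' @return A `cup_angles`.
#' @examples
#' lm <- pelvic_landmarks(c(-120, 0, 0), c(120, 0, 0), c(-20, 0, -90), c(20, 0, -90))
#' f <- build_app_frame(lm)
#' operative_angles(cup_pose(c(90, 0, -60), c(1, 0, 0)), f) # inclination 90
#' @export
operative_angles <- function(pose, frame, definition = "operative") {
  comp <- axis_components(pose, frame)
  if (comp["l"] < 0) {
    stop("cup axis points medially (lateral component <= 0) after side ",
      "normalization; flip the axis or check the operated side",
      call. = FALSE
    )
  }
  las_to_angles(as.numeric(comp), match.arg(definition, c(
    "operative", "radiographic", "anatomic"
  )))
}

#' Cup axis from operative angles
#'
#' Inverse of [operative_angles()]: builds the unit opening axis in world
#' coordinates whose operative anteversion/inclination in `frame` equal the
#' given angles. Used to implant ground-truth cups in simulations.
#'
#' @param angles a `cup_angles` with `definition = "operative"`, inclination
#'   in `[0, 90)`.
#' @param frame a `pelvic_frame`.
#' @return Unit length-3 axis vector.
#' @export
axis_from_operative_angles <- function(angles, frame) {
  stopifnot(inherits(angles, "cup_angles"))
  if (angles$definition != "operative") {
    stop("angles must use the operative definition", call. = FALSE)
  }
  if (angles$inclination >= 90) {
    stop("operative inclination must lie below 90 degrees", call. = FALSE)
  }
  axis_from_components(angles_to_las(angles), frame)
}

#' Convert cup angles between conventions
#'
#' Maps angles between the operative, radiographic and anatomic conventions
#' through the shared unit-axis representation, so the closed-form identities
#' `tan(RI) = tan(OI) / cos(OA)` and `sin(RA) = sin(OA) * cos(OI)` hold by
#' construction (R = radiographic, O = operative, I = inclination,
#' A = anteversion).
#'
#' @param angles a `cup_angles`.
#' @param to target convention.
#' @return A `cup_angles` in the target convention.
#' @examples
#' convert_definitions(cup_angles(15, 40, "radiographic"), "operative")
#' @export
convert_definitions <- function(angles,
                                to = c("operative", "radiographic", "anatomic")) {
  stopifnot(inherits(angles, "cup_angles"))
  to <- match.arg(to)
  if (angles$inclination >= 90 - 1e-12) {
    stop("conversion is undefined at inclination 90 degrees", call. = FALSE)
  }
  if (identical(angles$definition, to)) {
    return(angles)
  }
  las_to_angles(angles_to_las(angles), to)
}

#' Signed cup depth difference
#'
#' Displacement of one cup relative to another along the cup opening axis:
#' `(guide.center - reference.center) . guide.axis` in mm. Positive values
#' mean the guide cup sits lateral (shallower) and negative medial (deeper)
#' relative to the reference — unlike a plain 3D distance, the sign is
#' clinically meaningful. Displacement perpendicular to the axis does not
#' contribute.
#'
#' @param guide,reference `cup_pose` objects in the same `frame_id`.
#' @return Signed depth difference in mm.
#' @export
signed_depth_difference <- function(guide, reference) {
  stopifnot(inherits(guide, "cup_pose"), inherits(reference, "cup_pose"))
  if (!identical(guide$frame_id, reference$frame_id)) {
    stop("cup poses are expressed in different frames ('", guide$frame_id,
      "' vs '", reference$frame_id, "')",
      call. = FALSE
    )
  }
  sum((guide$center - reference$center) * guide$axis)
}

#' Read / write cup poses as JSON or CSV
#'
#' Fields `center_x..z` (mm), `axis_x..z` and `frame_id`.
#'
#' @param pose a `cup_pose`.
#' @param path file path (`.json` or `.csv` by extension).
#' @return `read_cup_pose` returns a `cup_pose`.
#' @export
write_cup_pose <- function(pose, path) {
  stopifnot(inherits(pose, "cup_pose"))
  rec <- list(
    center_x = pose$center[1], center_y = pose$center[2], center_z = pose$center[3],
    axis_x = pose$axis[1], axis_y = pose$axis[2], axis_z = pose$axis[3],
    frame_id = pose$frame_id
  )
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(as.data.frame(rec), path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_cup_pose
#' @export
read_cup_pose <- function(path) {
  rec <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    as.list(read.csv(path, stringsAsFactors = FALSE)[1, ])
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cup_pose(
    c(rec$center_x, rec$center_y, rec$center_z),
    c(rec$axis_x, rec$axis_y, rec$axis_z),
    rec$frame_id
  )
}

#' Transform a cup pose into another coordinate system
#'
#' The centre is mapped by the full rigid transform; the axis by the
#' rotation only, preserving unit norm.
#'
#' @param t a `rigid_transform` from the pose's frame to `new_frame_id`.
#' @param pose a `cup_pose`.
#' @param new_frame_id frame tag of the result.
#' @return The transformed `cup_pose`.
#' @export
transform_cup_pose <- function(t, pose, new_frame_id = pose$frame_id) {
  stopifnot(inherits(t, "rigid_transform"), inherits(pose, "cup_pose"))
  cup_pose(
    apply_transform(t, pose$center),
    as.numeric(t$rotation %*% pose$axis),
    new_frame_id
  )
}
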
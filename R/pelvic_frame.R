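#' Pelvic landmarks
#'
#' The four landmarks that define the anterior pelvic plane (APP): both
#' anterior superior iliac spines (ASIS) and both pubic tubercles. The APP is
#' the standard reference plane through the two ASIS and the pubic midpoint
#' (approximately the symphysis).
#'
#' @param asis_left,asis_right,pubic_left,pubic_right length-3 coordinates (mm).
#' @return An object of class `pelvic_landmarks`.
#' @export
pelvic_landmarks <- function(asis_left, asis_right, pubic_left, pubic_right) {
  lm <- list(
    asis_left = as.numeric(asis_left), asis_right = as.numeric(asis_right),
    pubic_left = as.numeric(pubic_left), pubic_right = as.numeric(pubic_right)
  )
  for (nm in names(lm)) {
    if (length(lm[[nm]]) != 3L) stop(nm, " must have length 3", call. = FALSE)
    stopifnot_finite(lm[[nm]], nm)
  }
  if (vnorm(lm$asis_left - lm$asis_right) < 1e-6) {
    stop("left and right ASIS coincide", call. = FALSE)
  }
  structure(lm, class = "pelvic_landmarks")
}

landmark_matrix <- function(lm) {
  rbind(lm$asis_left, lm$asis_right, lm$pubic_left, lm$pubic_right)
}

#' Apply a rigid transform to landmarks
#' @param t a `rigid_transform`.
#' @param lm a `pelvic_landmarks`.
#' @return Transformed `pelvic_landmarks`.
#' @export
transform_landmarks <- function(t, lm) {
  stopifnot(inherits(lm, "pelvic_landmarks"))
  pelvic_landmarks(
    apply_transform(t, lm$asis_left), apply_transform(t, lm$asis_right),
    apply_transform(t, lm$pubic_left), apply_transform(t, lm$pubic_right)
  )
}

#' Anatomical pelvic coordinate frame
#'
#' Orthonormal frame with lateral, anterior and superior axes and an origin,
#' of kind `"APP"` (anterior pelvic plane) or `"FPP"` (functional pelvic
#' plane, i.e. APP rotated by the pelvic tilt about the inter-ASIS axis).
#' The lateral axis points toward the operated side, so one set of angle
#' formulas serves left and right hips; anterior is positive forward and
#' superior positive cranial. For a right hip the triad is right-handed
#' (`lateral x anterior = superior`); for a left hip the mirrored lateral
#' axis makes it left-handed, which the component-based angle formulas never
#' consult.
#'
#' @param origin length-3 origin (mm).
#' @param lateral,anterior,superior unit axes (mm-frame directions).
#' @param kind `"APP"` or `"FPP"`.
#' @param tilt_deg pelvic tilt applied (0 for APP).
#' @param side `"right"` or `"left"` operated hip.
#' @return An object of class `pelvic_frame`.
#' @export
pelvic_frame <- function(origin, lateral, anterior, superior,
                         kind = c("APP", "FPP"), tilt_deg = 0,
                         side = c("right", "left")) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  ax <- rbind(unit(lateral), unit(anterior), unit(superior))
  if (max(abs(ax %*% t(ax) - diag(3))) > 1e-9) {
    stop("frame axes must be mutually orthonormal (tolerance 1e-9)", call. = FALSE)
  }
  hand <- if (side == "right") 1 else -1
  if (vnorm(cross3(ax[1, ], ax[2, ]) - hand * ax[3, ]) > 1e-9) {
    stop("frame handedness inconsistent with operated side", call. = FALSE)
  }
  structure(
    list(
      origin = as.numeric(origin), lateral = ax[1, ], anterior = ax[2, ],
      superior = ax[3, ], kind = kind, tilt_deg = tilt_deg, side = side
    ),
    class = "pelvic_frame"
  )
}

#' @export
print.pelvic_frame <- function(x, ...) {
  cat(sprintf(
    "<pelvic_frame> %s (%s hip), tilt %.1f deg\n", x$kind, x$side, x$tilt_deg
  ))
  invisible(x)
}

#' Build the anterior pelvic plane frame from landmarks
#'
#' The APP contains both ASIS and the midpoint of the pubic landmarks. The
#' origin is the ASIS midpoint; the lateral axis runs along the inter-ASIS
#' line toward the operated side; the anterior axis is the plane normal
#' pointing forward; the superior axis completes the triad in-plane,
#' pointing cranially.
#'
#' @param landmarks a `pelvic_landmarks`.
#' @param side operated hip, `"right"` or `"left"`.
#' @return An `"APP"` `pelvic_frame`.
#' @examples
#' lm <- pelvic_landmarks(
#'   asis_left = c(-120, 0, 0), asis_right = c(120, 0, 0),
#'   pubic_left = c(-20, 0, -90), pubic_right = c(20, 0, -90)
#' )
#' build_app_frame(lm) # identity axes
#' @export
build_app_frame <- function(landmarks, side = c("right", "left")) {
  stopifnot(inherits(landmarks, "pelvic_landmarks"))
  side <- match.arg(side)
  origin <- (landmarks$asis_left + landmarks$asis_right) / 2
  inter_asis <- landmarks$asis_right - landmarks$asis_left
  pubic_mid <- (landmarks$pubic_left + landmarks$pubic_right) / 2
  v <- pubic_mid - origin
  n <- cross3(inter_asis, v) # plane normal; inter-ASIS x (toward pubis)
  if (vnorm(n) < 1e-6 * vnorm(inter_asis) * max(vnorm(v), 1)) {
    stop("landmarks are collinear: the anterior pelvic plane is undefined",
      call. = FALSE
    )
  }
  anterior <- unit(n)
  # Orient the normal anteriorly. The pubic midpoint lies inferior to the ASIS
  # line, so cross(right-ward inter-ASIS, ASIS->pubis) already points forward
  # for an anatomically posed pelvis; keep that convention exactly so the
  # construction stays equivariant under rigid motions.
  lateral <- unit(inter_asis) * (if (side == "right") 1 else -1)
  superior <- unit(cross3(unit(inter_asis), anterior))
  pelvic_frame(origin, lateral, anterior, superior,
    kind = "APP", tilt_deg = 0, side = side
  )
}

#' Tilt the APP into the functional pelvic plane
#'
#' Rotates an APP frame about its lateral (inter-ASIS) axis by the
#' preoperative pelvic tilt, yielding the functional pelvic plane (FPP).
#' Positive tilt is anterior tilt: the superior axis leans forward.
#'
#' @param frame an `"APP"` `pelvic_frame`.
#' @param tilt_deg pelvic tilt in degrees, `|tilt| <= 90`.
#' @return An `"FPP"` `pelvic_frame` recording `tilt_deg`.
#' @export
apply_pelvic_tilt <- function(frame, tilt_deg) {
  stopifnot(inherits(frame, "pelvic_frame"))
  if (frame$kind != "APP") {
    stop("pelvic tilt is applied to an APP frame", call. = FALSE)
  }
  if (abs(tilt_deg) > 90) {
    stop("|tilt_deg| > 90 is non-physiological", call. = FALSE)
  }
  # anterior tilt = superior axis rotates toward anterior; rotate about the
  # inter-ASIS direction with the sign that moves superior forward.
  axis <- cross3(frame$superior, frame$anterior) # = +/- lateral direction
  r <- rotation_about_axis(axis, tilt_deg)
  pelvic_frame(
    frame$origin,
    as.numeric(r %*% frame$lateral),
    as.numeric(r %*% frame$anterior),
    as.numeric(r %*% frame$superior),
    kind = "FPP", tilt_deg = tilt_deg, side = frame$side
  )
}

#' Apply a rigid transform to a pelvic frame
#' @param t a `rigid_transform`.
#' @param frame a `pelvic_frame`.
#' @return The frame expressed after the rigid motion.
#' @export
transform_frame <- function(t, frame) {
  stopifnot(inherits(frame, "pelvic_frame"))
  pelvic_frame(
    apply_transform(t, frame$origin),
    as.numeric(t$rotation %*% frame$lateral),
    as.numeric(t$rotation %*% frame$anterior),
    as.numeric(t$rotation %*% frame$superior),
    kind = frame$kind, tilt_deg = frame$tilt_deg, side = frame$side
  )
}

#' Read / write landmarks (CSV or JSON)
#'
#' CSV columns: `name,x,y,z` (mm) with names `asis_left`, `asis_right`,
#' `pubic_left`, `pubic_right`; JSON is a name -> xyz mapping.
#'
#' @param lm a `pelvic_landmarks`.
#' @param path file path (`.csv` or `.json`, by extension).
#' @return `read_landmarks` returns a `pelvic_landmarks`.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "pelvic_landmarks"))
  nm <- c("asis_left", "asis_right", "pubic_left", "pubic_right")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lapply(lm[nm], as.numeric), path, digits = NA)
  } else {
    m <- landmark_matrix(lm)
    df <- data.frame(name = nm, x = m[, 1], y = m[, 2], z = m[, 3])
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pelvic_landmarks(obj$asis_left, obj$asis_right, obj$pubic_left, obj$pubic_right)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    row <- function(nm) {
      i <- match(nm, df$name)
      if (is.na(i)) stop("landmark '", nm, "' missing from ", path, call. = FALSE)
      as.numeric(df[i, c("x", "y", "z")])
    }
    pelvic_landmarks(
      row("asis_left"), row("asis_right"), row("pubic_left"), row("pubic_right")
    )
  }
}
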
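#' Build the local anatomical coordinate frame from the landmark quartet
#'
#' The frame removes between-participant differences in translation and
#' orientation before slicing. Its origin is the midpoint between the xiphoid
#' process and the 9th thoracic vertebra (the torso centre). The *transverse*
#' axis is the unit vector from xiphoid to T9 — note this is the
#' anterior-posterior direction; the naming follows the scanning convention,
#' not the conventional anatomical planes. The *sagittal* axis is the
#' left-to-right ASIS vector orthogonalised against the transverse axis
#' (Gram-Schmidt, transverse kept exact); the *longitudinal* axis is their
#' cross product, sign-corrected so it points from the ASIS level toward the
#' xiphoid level (toward the head). When the correction is needed both the
#' sagittal and longitudinal axes are negated, preserving right-handedness.
#'
#' @param landmarks Landmark tibble as returned by [read_landmarks()], in mm.
#' @param orthogonalise Which defining vector to keep exact when the two are
#'   not orthogonal: `"keep-transverse"` (default) or `"keep-sagittal"` for
#'   sensitivity checks.
#'
#' @return An object of class `torso_frame`: list with `origin` (length-3),
#'   `axes` (3x3 matrix whose columns are the transverse, sagittal and
#'   longitudinal unit vectors) and `handedness` (+1).
#' @export
build_frame <- function(landmarks, orthogonalise = c("keep-transverse", "keep-sagittal")) {
  orthogonalise <- match.arg(orthogonalise)
  landmarks <- as_landmark_set(landmarks)
  xip <- landmark_point(landmarks, "xiphoid_process")
  t9 <- landmark_point(landmarks, "t9_vertebra")
  al <- landmark_point(landmarks, "asis_left")
  ar <- landmark_point(landmarks, "asis_right")

  v1 <- unname(t9 - xip)          # transverse: xiphoid -> T9 (antero-posterior)
  v2 <- unname(ar - al)           # sagittal: ASIS left -> right
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("coincident defining landmarks", call. = FALSE)
  u1 <- v1 / n1; u2 <- v2 / n2
  cosang <- abs(sum(u1 * u2))
  if (cosang > cos(pi / 180)) {
    stop("degenerate landmark geometry: xiphoid-T9 and ASIS vectors are within 1 degree ",
         "of parallel", call. = FALSE)
  }
  if (orthogonalise == "keep-transverse") {
    transverse <- u1
    s <- u2 - sum(u2 * transverse) * transverse
    sagittal <- s / sqrt(sum(s^2))
  } else {
    sagittal <- u2
    t <- u1 - sum(u1 * sagittal) * sagittal
    transverse <- t / sqrt(sum(t^2))
  }
  longitudinal <- cross3(transverse, sagittal)

  origin <- (xip + t9) / 2
  asis_mid <- (al + ar) / 2
  if (sum((xip - asis_mid) * longitudinal) < 0) {
    # point the longitudinal axis at the xiphoid level; negate the sagittal
    # axis too so the triple stays right-handed
    longitudinal <- -longitudinal
    sagittal <- -sagittal
  }
  axes <- cbind(transverse = transverse, sagittal = sagittal,
                longitudinal = longitudinal)
  rownames(axes) <- c("x", "y", "z")
  structure(
    list(origin = unname(origin), axes = axes, handedness = 1),
    class = "torso_frame"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.torso_frame <- function(x, ...) {
  cat("<torso_frame>\n origin (mm):", format(x$origin, digits = 6), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

#' Express a point cloud in anatomical coordinates
#'
#' Subtracts the frame origin and projects onto the frame axes. Component
#' order in the result: transverse (antero-posterior), sagittal (left-right),
#' longitudinal (inferior-superior, positive toward the xiphoid).
#'
#' @param cloud Tibble with `x`, `y`, `z` columns (mm, scanner coordinates).
#' @param frame A `torso_frame`.
#' @return Tibble with `x`, `y`, `z` columns in frame coordinates; `z` is the
#'   longitudinal coordinate.
#' @export
to_anatomical <- function(cloud, frame) {
  stopifnot(inherits(frame, "torso_frame"))
  m <- as.matrix(cloud[, c("x", "y", "z")])
  m <- sweep(m, 2, frame$origin) %*% frame$axes
  dimnames(m) <- NULL
  out <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  attr(out, "source_id") <- attr(cloud, "source_id")
  out
}

#' Serialize / deserialize a frame for audit logs
#'
#' @param frame A `torso_frame`.
#' @return `frame_to_json()` a JSON string; `frame_from_json()` the frame.
#' @export
frame_to_json <- function(frame) {
  jsonlite::toJSON(
    list(origin = frame$origin, axes = unname(frame$axes),
         axis_order = colnames(frame$axes), handedness = frame$handedness),
    digits = NA, auto_unbox = TRUE
  )
}

#' @rdname frame_to_json
#' @param json JSON string produced by `frame_to_json()`.
#' @export
frame_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  axes <- obj$axes
  if (!is.matrix(axes)) axes <- do.call(rbind, axes)
  colnames(axes) <- obj$axis_order
  rownames(axes) <- c("x", "y", "z")
  structure(list(origin = obj$origin, axes = axes, handedness = obj$handedness),
            class = "torso_frame")
}
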
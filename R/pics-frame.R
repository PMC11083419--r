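#' Assemble a bony-landmark set
#'
#' Bundles the four bony landmarks that define the 3D Pelvic Inclination
#' Correction System for one subject: the inferior pubic point (IPP, the
#' frame origin), the sacrococcygeal articulation (SCJ) and the left and
#' right ischial spines. Coordinates are in scanner space, millimetres, and
#' must come from a right-handed scanner frame (e.g. LPS or RAS); the frame
#' construction relies on handedness to orient the caudal axis.
#'
#' @param ipp,scj,is_left,is_right Numeric length-3 vectors (x, y, z in mm).
#' @param frame Coordinate frame tag, `"scanner"` (default) or `"pics"`.
#' @return A tibble with columns `landmark`, `x_mm`, `y_mm`, `z_mm`, `frame`.
#' @examples
#' landmark_set(c(0, 0, 0), c(100, 0, 0), c(10, -5, -45), c(10, -5, 45))
#' @export
landmark_set <- function(ipp, scj, is_left, is_right, frame = "scanner") {
  pts <- list(ipp = ipp, scj = scj, is_left = is_left, is_right = is_right)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 3 || !all(is.finite(p))) {
      abort(paste0("landmark '", nm, "' must be a finite numeric length-3 vector"))
    }
  }
  frame <- match.arg(frame, lam_frames)
  tibble::tibble(
    landmark = lam_landmark_names,
    x_mm = unname(vapply(pts, `[`, numeric(1), 1)),
    y_mm = unname(vapply(pts, `[`, numeric(1), 2)),
    z_mm = unname(vapply(pts, `[`, numeric(1), 3)),
    frame = frame)
}

landmark_coords <- function(landmarks, name) {
  row <- landmarks[landmarks$landmark == name, , drop = FALSE]
  if (nrow(row) != 1) abort(paste0("landmark set must contain exactly one '", name, "'"))
  unname(c(row$x_mm, row$y_mm, row$z_mm))
}

#' Build the subject-specific 3D-PICS coordinate frame
#'
#' Constructs the pelvis-fixed orthonormal frame from four bony landmarks.
#' The construction is:
#' \itemize{
#'   \item lateral axis: `z_hat = unit(is_right - is_left)` (+ right);
#'   \item antero-posterior axis: `x_hat` is `scj - ipp` with its lateral
#'     component removed (Gram-Schmidt), normalised (+ posterior);
#'   \item cranio-caudal axis: `y_hat = z_hat x x_hat` (+ caudal in a
#'     right-handed scanner frame).
#' }
#' The origin is the inferior pubic point, so the IPP maps to (0, 0, 0) and
#' the PICS xz-plane (the near-horizontal pelvic plane) contains both the
#' IPP and the SCJ and is parallel to the interspinous axis.
#'
#' @param landmarks A landmark tibble from [landmark_set()] (scanner frame).
#' @param min_angle_deg Degeneracy threshold: the SCJ-IPP vector must make
#'   an angle of at least this many degrees with the interspinous axis.
#' @return An object of class `pics_frame`: list with `origin` (numeric 3,
#'   scanner mm) and `basis` (3 x 3 matrix whose columns are
#'   `x_hat`, `y_hat`, `z_hat`; orthonormal, determinant +1).
#' @examples
#' lm <- landmark_set(c(0, 0, 0), c(100, 0, 0), c(10, -5, -45), c(10, -5, 45))
#' build_pics_frame(lm)
#' @export
build_pics_frame <- function(landmarks, min_angle_deg = 1) {
  if (any(landmarks$frame != "scanner")) {
    abort("landmarks must be tagged 'scanner' to build a PICS frame")
  }
  ipp <- landmark_coords(landmarks, "ipp")
  scj <- landmark_coords(landmarks, "scj")
  is_l <- landmark_coords(landmarks, "is_left")
  is_r <- landmark_coords(landmarks, "is_right")

  spine_axis <- is_r - is_l
  spine_len <- vec_norm(spine_axis)
  if (spine_len < 1e-6) {
    abort("degenerate landmarks: ischial spines coincide (is_left ~ is_right)")
  }
  z_hat <- spine_axis / spine_len

  sagittal_vec <- scj - ipp
  sag_len <- vec_norm(sagittal_vec)
  if (sag_len < 1e-6) {
    abort("degenerate landmarks: sacrococcygeal articulation coincides with inferior pubic point (scj ~ ipp)")
  }
  # reject near-parallel SCJ-IPP vector and spine axis (frame would be
  # numerically undefined)
  cos_ang <- abs(sum(sagittal_vec / sag_len * z_hat))
  if (cos_ang > cos(min_angle_deg * pi / 180)) {
    abort("degenerate landmarks: scj-ipp direction is within 1 degree of the is_left-is_right axis")
  }

  x_raw <- sagittal_vec - sum(sagittal_vec * z_hat) * z_hat
  x_hat <- x_raw / vec_norm(x_raw)
  y_hat <- cross3(z_hat, x_hat)

  basis <- cbind(x_hat = x_hat, y_hat = y_hat, z_hat = z_hat)
  rownames(basis) <- NULL
  structure(list(origin = ipp, basis = basis), class = "pics_frame")
}

#' @export
print.pics_frame <- function(x, ...) {
  cat("3D-PICS frame\n")
  cat("  origin (scanner mm):", format(x$origin, digits = 6), "\n")
  cat("  x_hat (posterior): ", format(x$basis[, 1], digits = 4), "\n")
  cat("  y_hat (caudal):    ", format(x$basis[, 2], digits = 4), "\n")
  cat("  z_hat (right):     ", format(x$basis[, 3], digits = 4), "\n")
  invisible(x)
}

vec_norm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

check_frame_tag <- function(points, expected) {
  if (!"frame" %in% names(points)) abort("point table lacks a 'frame' column")
  if (any(points$frame != expected)) {
    abort(paste0("points must be tagged '", expected, "' for this transform"))
  }
}

#' Transform points between scanner and PICS space
#'
#' `to_pics()` maps scanner-space points into the subject's PICS frame,
#' `p' = B^T (p - origin)`; `from_pics()` is the exact inverse. Both are
#' rigid maps: distances and angles are preserved and a round trip
#' reproduces the input to floating-point accuracy.
#'
#' @param points A tibble with columns `x_mm`, `y_mm`, `z_mm` and `frame`
#'   (other columns pass through).
#' @param frame A `pics_frame` from [build_pics_frame()].
#' @return The points tibble with transformed coordinates and the `frame`
#'   column switched.
#' @examples
#' lm <- landmark_set(c(0, 0, 0), c(100, 0, 0), c(10, -5, -45), c(10, -5, 45))
#' fr <- build_pics_frame(lm)
#' pts <- tibble::tibble(x_mm = 1, y_mm = 2, z_mm = 3, frame = "scanner")
#' to_pics(pts, fr)
#' @export
to_pics <- function(points, frame) {
  stopifnot(inherits(frame, "pics_frame"))
  check_frame_tag(points, "scanner")
  xyz <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  out <- unname(sweep(xyz, 2, frame$origin) %*% frame$basis)
  points$x_mm <- out[, 1]
  points$y_mm <- out[, 2]
  points$z_mm <- out[, 3]
  points$frame <- "pics"
  points
}

#' @rdname to_pics
#' @export
from_pics <- function(points, frame) {
  stopifnot(inherits(frame, "pics_frame"))
  check_frame_tag(points, "pics")
  xyz <- as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
  out <- unname(sweep(xyz %*% t(frame$basis), 2, -frame$origin))
  points$x_mm <- out[, 1]
  points$y_mm <- out[, 2]
  points$z_mm <- out[, 3]
  points$frame <- "scanner"
  points
}

#' Serialize a PICS frame to and from JSON
#'
#' The frame is stored as its origin plus the nine basis entries
#' (column-major), enough to reconstruct the rigid map exactly.
#'
#' @param frame A `pics_frame`.
#' @param path File path; for `pics_frame_from_json()` the file to read.
#' @return `pics_frame_from_json()` returns a `pics_frame`.
#' @export
pics_frame_to_json <- function(frame, path) {
  stopifnot(inherits(frame, "pics_frame"))
  jsonlite::write_json(
    list(origin = frame$origin, basis = as.vector(frame$basis)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname pics_frame_to_json
#' @export
pics_frame_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- matrix(raw$basis, nrow = 3, ncol = 3)
  if (max(abs(t(basis) %*% basis - diag(3))) > 1e-9 || det(basis) < 0) {
    abort("stored basis is not a proper orthonormal matrix")
  }
  structure(list(origin = raw$origin, basis = basis), class = "pics_frame")
}
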
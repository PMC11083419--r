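#' Straight-line muscle length
#'
#' Length of a muscle course as the Euclidean distance (mm) between its
#' origin and insertion point in PICS space.
#'
#' @param origin,insertion Numeric length-3 vectors (x, y, z in mm).
#' @return Length in mm. A zero-length (coincident) course returns 0 with a
#'   warning: downstream code flags it as degenerate rather than failing.
#' @examples
#' muscle_length(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
muscle_length <- function(origin, insertion) {
  stopifnot(length(origin) == 3, length(insertion) == 3)
  len <- vec_norm(insertion - origin)
  if (len == 0) warn("degenerate muscle course: origin and insertion coincide")
  len
}

# Unit normals of the three PICS planes. The sagittal plane is the
# xy-plane (normal = right), the transversal plane the xz-plane (normal =
# inferior/caudal), the coronal plane the yz-plane (normal = posterior).
plane_normals <- list(
  sagittal    = c(0, 0, 1),
  transversal = c(0, 1, 0),
  coronal     = c(1, 0, 0))

#' Signed angle between a muscle course and a PICS plane
#'
#' The direction vector of a muscle is insertion minus origin. Its angle to
#' a PICS plane is `asin(d . n / |d|)` in degrees, where `n` is the plane's
#' unit normal: posterior for the coronal plane, inferior (caudal) for the
#' transversal plane and right for the sagittal plane. Courses pointing
#' posterior / caudal / right therefore get positive angles; opposite
#' directions get negative angles. The range is \[-90, 90\] degrees.
#'
#' @param d Numeric length-3 direction vector (mm), non-zero.
#' @param plane `"sagittal"`, `"transversal"` or `"coronal"`.
#' @return Angle in degrees.
#' @examples
#' plane_angle(c(0, 1, 0), "transversal") # +90: course points straight caudal
#' plane_angle(c(1, 0, 0), "transversal") # 0: course lies in the xz-plane
#' @export
plane_angle <- function(d, plane = c("sagittal", "transversal", "coronal")) {
  plane <- match.arg(plane)
  stopifnot(length(d) == 3)
  len <- vec_norm(d)
  if (len == 0) abort("plane_angle is undefined for a zero direction vector")
  s <- sum(d * plane_normals[[plane]]) / len
  # clamp against rounding just outside [-1, 1]
  asin(max(-1, min(1, s))) * 180 / pi
}

#' Quarter points of the pubovisceral origin line
#'
#' The PVM has a single fan-like origin annotated by its first
#' (cranio-lateral) and last (caudo-medial) point. A straight line between
#' them is divided into four equal parts; the three interior division
#' points serve as the origins of the PAM, PPM and PVaM courses.
#'
#' @param origin_first,origin_last Numeric length-3 vectors (mm), distinct.
#' @return A 3 x 3 matrix with rows `q1`, `q2`, `q3`:
#'   `qk = origin_first + (k/4) (origin_last - origin_first)`.
#' @examples
#' pvm_quarter_points(c(0, 0, 0), c(4, 0, 0))
#' @export
pvm_quarter_points <- function(origin_first, origin_last) {
  stopifnot(length(origin_first) == 3, length(origin_last) == 3)
  if (vec_norm(origin_last - origin_first) == 0) {
    abort("degenerate PVM origin line: first and last origin point coincide")
  }
  d <- origin_last - origin_first
  q <- t(vapply(1:3, function(k) origin_first + (k / 4) * d, numeric(3)))
  dimnames(q) <- list(c("q1", "q2", "q3"), c("x_mm", "y_mm", "z_mm"))
  q
}

#' Course-pairing configuration
#'
#' Controls how origin and insertion subpoints are paired into muscle
#' courses. The defaults pair subpoint k with subpoint k for COC/ICM/PRM
#' and assign the PVM quarter points in origin order q1 -> PAM, q2 -> PPM,
#' q3 -> PVaM, which reproduces the reference-cohort length ordering
#' (PAM longest, PVaM shortest of the PVM group).
#'
#' @param subpoints `"match"` (k with k) or `"cross"` (1 with 2, 2 with 1).
#' @param quarter_assignment Named character vector mapping `q1`, `q2`, `q3`
#'   to the three PVM insertion structures.
#' @param report `"mean"` collapses a course pair into one averaged value
#'   per structure/side; `"both"` keeps individual courses.
#' @return A list of class `course_pairing`.
#' @export
course_pairing <- function(subpoints = c("match", "cross"),
                           quarter_assignment = c(q1 = "PAM", q2 = "PPM", q3 = "PVaM"),
                           report = c("mean", "both")) {
  subpoints <- match.arg(subpoints)
  report <- match.arg(report)
  if (!setequal(names(quarter_assignment), c("q1", "q2", "q3")) ||
      !setequal(quarter_assignment, c("PAM", "PPM", "PVaM"))) {
    abort("quarter_assignment must map q1..q3 onto PAM, PPM, PVaM")
  }
  structure(list(subpoints = subpoints,
                 quarter_assignment = quarter_assignment,
                 report = report),
            class = "course_pairing")
}

point_xyz <- function(points, structure, role, side, subpoint) {
  hit <- points$structure == structure & points$role == role &
    points$side == side & points$subpoint == subpoint
  if (sum(hit) == 0) return(NULL)
  if (sum(hit) > 1) {
    abort(paste("duplicate annotation for", structure, role, side, subpoint))
  }
  c(points$x_mm[hit], points$y_mm[hit], points$z_mm[hit])
}

course_row <- function(subject_id, structure, side, course_id, origin, insertion) {
  if (is.null(origin) || is.null(insertion)) {
    return(tibble::tibble(
      subject_id = subject_id, structure = structure, side = side,
      course_id = course_id,
      origin_x = NA_real_, origin_y = NA_real_, origin_z = NA_real_,
      insertion_x = NA_real_, insertion_y = NA_real_, insertion_z = NA_real_,
      length_mm = NA_real_, angle_sagittal_deg = NA_real_,
      angle_transversal_deg = NA_real_, angle_coronal_deg = NA_real_,
      flag = "missing"))
  }
  d <- insertion - origin
  len <- vec_norm(d)
  degenerate <- len == 0
  tibble::tibble(
    subject_id = subject_id, structure = structure, side = side,
    course_id = course_id,
    origin_x = origin[1], origin_y = origin[2], origin_z = origin[3],
    insertion_x = insertion[1], insertion_y = insertion[2], insertion_z = insertion[3],
    length_mm = len,
    angle_sagittal_deg = if (degenerate) NA_real_ else plane_angle(d, "sagittal"),
    angle_transversal_deg = if (degenerate) NA_real_ else plane_angle(d, "transversal"),
    angle_coronal_deg = if (degenerate) NA_real_ else plane_angle(d, "coronal"),
    flag = if (degenerate) "degenerate" else "ok")
}

#' Build the muscle courses of one subject
#'
#' Pairs annotated origin and insertion points into straight-line muscle
#' courses in PICS space, per body side:
#' \itemize{
#'   \item COC: the single origin runs to both insertion subpoints
#'     (two courses per side);
#'   \item ICM and PRM: origin subpoint k runs to the midline insertion
#'     subpoint k;
#'   \item PVM: the origin line (subpoint 1 to 2) is divided by
#'     [pvm_quarter_points()]; q1 -> PAM insertion (same side), q2 -> PPM
#'     insertion (midline), q3 -> PVaM insertions (same side, both
#'     subpoints).
#' }
#' Missing points yield a `"missing"`-flagged row rather than an error, so
#' partially annotated subjects are summarized over the courses available.
#'
#' @param subject A point tibble (one subject, PICS frame) with columns
#'   `subject_id`, `structure`, `role`, `side`, `subpoint`,
#'   `x_mm`, `y_mm`, `z_mm`, `frame`.
#' @param pairing A [course_pairing()] configuration.
#' @return A tibble with one row per course: endpoints, `length_mm`, the
#'   three plane angles (degrees) and a `flag` column.
#' @export
build_courses <- function(subject, pairing = course_pairing()) {
  check_frame_tag(subject, "pics")
  sid <- unique(subject$subject_id)
  if (length(sid) != 1) abort("build_courses expects exactly one subject")
  rows <- list()
  sub_of <- function(k) if (pairing$subpoints == "match") k else 3 - k

  for (side in c("left", "right")) {
    # COC: one origin point, two insertion subpoints
    o <- point_xyz(subject, "COC", "origin", side, 1)
    for (k in 1:2) {
      i <- point_xyz(subject, "COC", "insertion", side, k)
      rows[[length(rows) + 1]] <-
        course_row(sid, "COC", side, paste0("o1-i", k), o, i)
    }
    # ICM / PRM: lateral origins to midline insertions, subpoint-paired
    for (st in c("ICM", "PRM")) {
      for (k in 1:2) {
        o <- point_xyz(subject, st, "origin", side, k)
        i <- point_xyz(subject, st, "insertion", "midline", sub_of(k))
        rows[[length(rows) + 1]] <-
          course_row(sid, st, side, paste0("o", k, "-i", sub_of(k)), o, i)
      }
    }
    # PVM: quarter points of the origin line feed PAM / PPM / PVaM
    o1 <- point_xyz(subject, "PVM", "origin", side, 1)
    o2 <- point_xyz(subject, "PVM", "origin", side, 2)
    q <- if (!is.null(o1) && !is.null(o2) && vec_norm(o2 - o1) > 0) {
      pvm_quarter_points(o1, o2)
    } else NULL
    for (qk in c("q1", "q2", "q3")) {
      st <- pairing$quarter_assignment[[qk]]
      q_origin <- if (is.null(q)) NULL else q[qk, ]
      ins_side <- if (st == "PPM") "midline" else side
      found_any <- FALSE
      for (k in 1:2) {
        i <- point_xyz(subject, st, "insertion", ins_side, k)
        if (is.null(i)) next
        found_any <- TRUE
        rows[[length(rows) + 1]] <-
          course_row(sid, st, side, paste0(qk, "-i", k), q_origin, i)
      }
      if (!found_any) {
        rows[[length(rows) + 1]] <-
          course_row(sid, st, side, paste0(qk, "-i1"), q_origin, NULL)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-subject muscle morphometry
#'
#' Summarizes the muscle courses of one subject into one row per
#' (structure, side): with the default `report = "mean"` pairing, the
#' length and each plane angle are the mean over the structure's course
#' pair (e.g. the two COC insertion subpoints). Note the per-course angle
#' identity `sin^2 + sin^2 + sin^2 = 1` holds for each course but not for
#' averaged angles.
#'
#' @inheritParams build_courses
#' @return A tibble with columns `subject_id`, `structure`, `side`,
#'   `length_mm`, `angle_sagittal_deg`, `angle_transversal_deg`,
#'   `angle_coronal_deg`, `n_courses`, `flag`.
#' @export
subject_morphometry <- function(subject, pairing = course_pairing()) {
  courses <- build_courses(subject, pairing)
  if (pairing$report == "both") return(courses)
  courses |>
    dplyr::group_by(.data$subject_id, .data$structure, .data$side) |>
    dplyr::summarise(
      length_mm = mean(.data$length_mm[.data$flag == "ok"]),
      angle_sagittal_deg = mean(.data$angle_sagittal_deg[.data$flag == "ok"]),
      angle_transversal_deg = mean(.data$angle_transversal_deg[.data$flag == "ok"]),
      angle_coronal_deg = mean(.data$angle_coronal_deg[.data$flag == "ok"]),
      n_courses = sum(.data$flag == "ok"),
      flag = if (all(.data$flag == "ok")) "ok" else
        paste(unique(.data$flag[.data$flag != "ok"]), collapse = ";"),
      .groups = "drop")
}

#' Morphometry of a whole cohort
#'
#' Applies [subject_morphometry()] to every subject of a multi-subject
#' point table.
#'
#' @param cohort A point tibble (PICS frame) with one or more subjects.
#' @inheritParams build_courses
#' @return Row-bound per-subject morphometry results.
#' @export
cohort_morphometry <- function(cohort, pairing = course_pairing()) {
  check_frame_tag(cohort, "pics")
  split(cohort, cohort$subject_id) |>
    lapply(subject_morphometry, pairing = pairing) |>
    dplyr::bind_rows()
}
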
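#' Read and write annotation point tables
#'
#' The on-disk dialect is a UTF-8 comma-separated table with one leading
#' metadata comment line (`# handedness=...`), a header, and one row per
#' annotated point: `subject_id, structure, role, side, subpoint, x_mm,
#' y_mm, z_mm, frame`. Coordinates are serialized at full double
#' precision, so a write/read round trip is lossless. The handedness code
#' declares the orientation convention of the scanner frame (must be a
#' right-handed code such as `RAS` or `LPS`); it is metadata, never
#' guessed from the data.
#'
#' @param points A point tibble.
#' @param path File path.
#' @param handedness Orientation code written to the metadata line.
#' @return `read_points()` returns the point tibble with the handedness
#'   code attached as attribute `"handedness"`.
#' @export
write_points <- function(points, path, handedness = "RAS") {
  cols <- c("subject_id", "structure", "role", "side", "subpoint",
            "x_mm", "y_mm", "z_mm", "frame")
  missing_cols <- setdiff(cols, names(points))
  if (length(missing_cols) > 0) {
    abort(paste0("point table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# handedness=", handedness), con)
  writeLines(readr::format_csv(points[, cols]), con, sep = "")
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1)
  handedness <- if (startsWith(first, "#")) {
    sub("^#\\s*handedness=", "", first)
  } else {
    warn("point file has no metadata line; assuming handedness=RAS")
    "RAS"
  }
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           structure = readr::col_character(),
                           role = readr::col_character(),
                           side = readr::col_character(),
                           subpoint = readr::col_integer(),
                           x_mm = readr::col_double(),
                           y_mm = readr::col_double(),
                           z_mm = readr::col_double(),
                           frame = readr::col_character()))
  required <- c("subject_id", "structure", "role", "side", "subpoint",
                "x_mm", "y_mm", "z_mm", "frame")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("point file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  check_enum <- function(values, allowed, what) {
    bad <- which(!values %in% allowed)
    if (length(bad) > 0) {
      abort(paste0("invalid ", what, " '", values[bad[1]], "' in row ",
                   bad[1], " of ", path))
    }
  }
  check_enum(tab$structure, lam_structures, "structure")
  check_enum(tab$role, lam_roles, "role")
  check_enum(tab$side, lam_sides, "side")
  check_enum(tab$subpoint, c(1L, 2L), "subpoint")
  check_enum(tab$frame, lam_frames, "frame")
  if (!all(is.finite(c(tab$x_mm, tab$y_mm, tab$z_mm)))) {
    abort(paste0("non-finite coordinate in ", path))
  }
  key <- paste(tab$subject_id, tab$structure, tab$role, tab$side, tab$subpoint)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(paste0("duplicate point key in row ", dup[1], ": ", key[dup[1]]))
  }
  mixed <- tapply(tab$frame, tab$subject_id, function(f) length(unique(f)) > 1)
  if (any(mixed)) {
    abort(paste0("mixed coordinate frames for subject(s): ",
                 paste(names(mixed)[mixed], collapse = ", ")))
  }
  attr(tab, "handedness") <- handedness
  tab
}

#' Read and write landmark tables
#'
#' Same CSV dialect as [write_points()] but with a `landmark` column
#' (`ipp`, `scj`, `is_left`, `is_right`) and an optional `subject_id`.
#'
#' @param landmarks A landmark tibble.
#' @param path File path.
#' @param handedness Orientation code for the metadata line.
#' @export
write_landmarks <- function(landmarks, path, handedness = "RAS") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# handedness=", handedness), con)
  writeLines(readr::format_csv(landmarks), con, sep = "")
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!"landmark" %in% names(tab)) abort("landmark file lacks 'landmark' column")
  bad <- which(!tab$landmark %in% lam_landmark_names)
  if (length(bad) > 0) {
    abort(paste0("invalid landmark '", tab$landmark[bad[1]], "' in row ", bad[1]))
  }
  tab$subpoint <- NULL
  tab
}

#' Export muscle courses as plottable polylines
#'
#' Writes each muscle course as a named origin-to-insertion point sequence
#' in JSON, a plotting-stack-agnostic analogue of a 3D muscle-course
#' figure.
#'
#' @param courses A course tibble from [build_courses()].
#' @param path Output JSON path.
#' @export
courses_to_polyline_json <- function(courses, path) {
  ok <- courses[courses$flag == "ok", , drop = FALSE]
  polys <- lapply(seq_len(nrow(ok)), function(i) {
    r <- ok[i, ]
    list(name = paste(r$subject_id, r$structure, r$side, r$course_id, sep = "/"),
         points = list(c(r$origin_x, r$origin_y, r$origin_z),
                       c(r$insertion_x, r$insertion_y, r$insertion_z)))
  })
  jsonlite::write_json(polys, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
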
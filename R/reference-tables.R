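#' Packaged reference tables for the levator ani point roster
#'
#' `lam_coordinate_reference()` returns the per-point 3D-PICS coordinate
#' summary of the reference cohort of 35 nulliparous women: for each of the
#' 29 origin/insertion points of the LAM subdivisions, the mean and standard
#' deviation of the x (anterior-posterior, + posterior), y (cranio-caudal,
#' + caudal) and z (lateral, + right) coordinates in millimetres.
#' `lam_icc_reference()` returns the published inter-rater reliability of the
#' same roster: one ICC(2,k) estimate with 95% confidence bounds per point
#' and axis (87 rows).
#'
#' The coordinate table doubles as the default sampling distribution of the
#' synthetic-cohort generator (see [sim_params()]), so simulated cohorts are
#' centred on the reference anatomy.
#'
#' @return A tibble. For `lam_coordinate_reference()`: columns `structure`,
#'   `role`, `side`, `subpoint`, `mean_x`, `sd_x`, `mean_y`, `sd_y`,
#'   `mean_z`, `sd_z` (29 rows). For `lam_icc_reference()`: columns
#'   `structure`, `role`, `side`, `subpoint`, `axis`, `estimate`, `ci_low`,
#'   `ci_high` (87 rows; bounds are floored at 0 as published).
#' @examples
#' tab <- lam_coordinate_reference()
#' nrow(tab) # 29 points
#' @export
lam_coordinate_reference <- function() {
  path <- system.file("extdata", "coordinate_reference_table.csv",
                      package = "lamorph", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           structure = readr::col_character(),
                           role = readr::col_character(),
                           side = readr::col_character(),
                           subpoint = readr::col_integer(),
                           .default = readr::col_double()))
  validate_point_table(tab)
  tab
}

#' @rdname lam_coordinate_reference
#' @export
lam_icc_reference <- function() {
  path <- system.file("extdata", "icc_reference_table.csv",
                      package = "lamorph", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    structure = readr::col_character(),
                    role = readr::col_character(),
                    side = readr::col_character(),
                    subpoint = readr::col_integer(),
                    axis = readr::col_character(),
                    .default = readr::col_double()))
}

# A point-distribution table must index each (structure, role, side,
# subpoint) key exactly once and have non-negative SDs.
validate_point_table <- function(tab) {
  required <- c("structure", "role", "side", "subpoint",
                "mean_x", "sd_x", "mean_y", "sd_y", "mean_z", "sd_z")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("point-distribution table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  key <- paste(tab$structure, tab$role, tab$side, tab$subpoint)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate point key(s): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  sds <- c(tab$sd_x, tab$sd_y, tab$sd_z)
  if (any(sds < 0)) abort("negative SD in point-distribution table")
  bad <- !tab$structure %in% lam_structures
  if (any(bad)) {
    abort(paste0("unknown structure(s): ",
                 paste(unique(tab$structure[bad]), collapse = ", ")))
  }
  invisible(tab)
}
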
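#' Per-point coordinate summary of a cohort
#'
#' For every (structure, role, side, subpoint) key and axis, the mean and
#' sample SD (n - 1 denominator) of the PICS coordinates across subjects.
#' Subjects missing a point are excluded cell-wise, so partially annotated
#' cohorts are summarized over whatever is available.
#'
#' @param cohort A multi-subject point tibble in PICS frame.
#' @return A tibble with columns `structure`, `role`, `side`, `subpoint`,
#'   `axis` (x/y/z), `mean`, `sd`, `n`. The default 29-point roster gives
#'   87 rows.
#' @export
summarize_coordinates <- function(cohort) {
  if (nrow(cohort) == 0) abort("empty cohort")
  check_frame_tag(cohort, "pics")
  cohort |>
    tidyr::pivot_longer(c("x_mm", "y_mm", "z_mm"),
                        names_to = "axis", values_to = "value") |>
    dplyr::mutate(axis = sub("_mm$", "", .data$axis)) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$structure, .data$role, .data$side,
                    .data$subpoint, .data$axis) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Convert a wide point-distribution table to a long coordinate summary
#'
#' Reshapes a `mean_x`/`sd_x`/... reference table (as returned by
#' [lam_coordinate_reference()]) into the long per-axis format produced by
#' [summarize_coordinates()], so both feed [sd_threshold_count()].
#'
#' @param tab A wide point-distribution table.
#' @return A long summary tibble (`axis`, `mean`, `sd`).
#' @export
as_coordinate_summary <- function(tab) {
  validate_point_table(tab)
  tab |>
    tidyr::pivot_longer(dplyr::matches("^(mean|sd)_[xyz]$"),
                        names_to = c(".value", "axis"), names_sep = "_") |>
    dplyr::select(dplyr::all_of(c("structure", "role", "side", "subpoint",
                                  "axis", "mean", "sd")))
}

#' Count coordinate cells with SD at or below a threshold
#'
#' How many of the per-point, per-axis SD cells of a coordinate summary
#' are `<=` the threshold (inclusive). On the default 29-point roster
#' there are 87 cells; this is the homogeneity statistic reported for
#' annotation precision (e.g. "80/87 points within an SD of 8 mm").
#'
#' @param summary A long coordinate summary ([summarize_coordinates()] or
#'   [as_coordinate_summary()]).
#' @param threshold_mm Non-negative threshold in mm.
#' @return A list with `count`, `total`, `fraction` and `percent`
#'   (fraction rounded to a whole percent for display).
#' @examples
#' sd_threshold_count(as_coordinate_summary(lam_coordinate_reference()), 8)
#' @export
sd_threshold_count <- function(summary, threshold_mm) {
  if (threshold_mm < 0) abort("threshold must be >= 0")
  if (nrow(summary) == 0) abort("empty coordinate summary")
  count <- sum(summary$sd <= threshold_mm)
  total <- nrow(summary)
  list(count = count, total = total, fraction = count / total,
       percent = round(100 * count / total))
}

#' Cohort-level morphometry summary
#'
#' Aggregates per-subject morphometry into reference-table form: for each
#' (structure, side), the mean and sample SD of the muscle length and the
#' median and quartiles of each plane angle. Quartiles use linear
#' interpolation between order statistics (R's default `quantile`
#' type 7).
#'
#' @param results Per-subject morphometry tibble ([cohort_morphometry()]).
#' @return A tibble with length mean/SD and per-angle median, q1, q3.
#' @export
summarize_morphometry <- function(results) {
  if (nrow(results) == 0) abort("empty morphometry results")
  q <- function(v, p) quantile(v, p, na.rm = TRUE, names = FALSE, type = 7)
  results |>
    dplyr::group_by(.data$structure, .data$side) |>
    dplyr::summarise(
      n = sum(!is.na(.data$length_mm)),
      length_mean = mean(.data$length_mm, na.rm = TRUE),
      length_sd = sd(.data$length_mm, na.rm = TRUE),
      dplyr::across(
        dplyr::all_of(c("angle_sagittal_deg", "angle_transversal_deg",
                        "angle_coronal_deg")),
        list(median = function(v) q(v, 0.5),
             q1 = function(v) q(v, 0.25),
             q3 = function(v) q(v, 0.75))),
      .groups = "drop")
}
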
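#' Default PICS-space landmark geometry for simulation
#'
#' Plausible pelvic dimensions used when embedding synthetic subjects in
#' scanner space: inferior pubic point at the origin, sacrococcygeal
#' articulation 110 mm posterior, ischial spines 45 mm lateral on either
#' side and slightly posterior/caudal. The values are configurable
#' plumbing, not anatomy to be estimated.
#'
#' @return A landmark tibble tagged `"pics"`.
#' @export
default_landmark_geometry <- function() {
  landmark_set(ipp = c(0, 0, 0), scj = c(110, 0, 0),
               is_left = c(10, -5, -45), is_right = c(10, -5, 45),
               frame = "pics")
}

#' Simulation parameters for a synthetic annotation cohort
#'
#' Bundles everything the generator needs: the per-point Gaussian
#' coordinate distribution (defaults to the packaged reference table, so
#' simulated anatomy is centred on the reference cohort), rigid-embedding
#' ranges, two-rater annotation noise and the random seed.
#'
#' @param n_subjects Number of subjects (default 35, the reference cohort
#'   size).
#' @param distribution A point-distribution table: one row per
#'   (structure, role, side, subpoint) with `mean_*` / `sd_*` columns in mm.
#' @param inclination_deg Range (length 2, degrees) of pelvic inclination:
#'   rotation about the left-right (z) axis.
#' @param rotation_deg Range (degrees) for the remaining two rotation axes.
#' @param translation_mm Range (mm) for each translation component.
#' @param rater_sigma_mm Per-axis SD (mm) of rater annotation noise.
#' @param landmark_geometry PICS-space bony-landmark positions used for the
#'   scanner embedding; see [default_landmark_geometry()].
#' @param lr_correlation Correlation in \[0, 1\] between the coordinate
#'   deviations of mirrored left/right points (z-deviation mirrored in
#'   sign). 0 (the default) samples every point independently.
#' @param seed Integer seed; per-subject streams are derived from it so any
#'   subject subset is reproducible.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 35,
                       distribution = lam_coordinate_reference(),
                       inclination_deg = c(-30, 30),
                       rotation_deg = c(-10, 10),
                       translation_mm = c(-100, 100),
                       rater_sigma_mm = 2,
                       landmark_geometry = default_landmark_geometry(),
                       lr_correlation = 0,
                       seed = 1L) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  validate_point_table(distribution)
  if (rater_sigma_mm < 0) abort("rater_sigma_mm must be >= 0")
  if (lr_correlation < 0 || lr_correlation > 1) {
    abort("lr_correlation must be in [0, 1]")
  }
  geom <- landmark_geometry
  ipp <- landmark_coords(geom, "ipp")
  scj <- landmark_coords(geom, "scj")
  is_l <- landmark_coords(geom, "is_left")
  is_r <- landmark_coords(geom, "is_right")
  if (scj[1] <= ipp[1]) abort("landmark geometry: scj must lie posterior to ipp (larger x)")
  if (abs(is_l[3] + is_r[3]) > 1e-6 || any(abs(is_l[1:2] - is_r[1:2]) > 1e-6)) {
    abort("landmark geometry: ischial spines must be mirror-symmetric in z")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 distribution = distribution,
                 inclination_deg = inclination_deg,
                 rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 rater_sigma_mm = rater_sigma_mm,
                 landmark_geometry = landmark_geometry,
                 lr_correlation = lr_correlation,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Counter-based per-subject substream: subject i always sees the same seed
# for a given global seed, regardless of which other subjects are drawn.
subject_seed <- function(seed, i, salt = 0L) {
  (as.numeric(seed) * 48271 + i * 69621 + salt * 16807) %% 2147483647
}

subject_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Generate a synthetic annotation cohort in PICS space
#'
#' Draws every muscle-point coordinate independently from
#' `Normal(mean, sd)` using the per-point means and SDs of the
#' distribution table (marginals only: no inter-point covariance is
#' modelled beyond the optional left/right mirror correlation).
#'
#' @param params A [sim_params()] object.
#' @return A point tibble (all subjects, PICS frame) with columns
#'   `subject_id`, `structure`, `role`, `side`, `subpoint`, `x_mm`, `y_mm`,
#'   `z_mm`, `frame`.
#' @examples
#' cohort <- generate_cohort(sim_params(n_subjects = 2, seed = 7))
#' dplyr::count(cohort, subject_id)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  tab <- params$distribution
  n_pts <- nrow(tab)
  means <- as.matrix(tab[, c("mean_x", "mean_y", "mean_z")])
  sds <- as.matrix(tab[, c("sd_x", "sd_y", "sd_z")])
  rho <- params$lr_correlation

  # index of each right-side row's mirrored left partner (for lr_correlation)
  partner <- rep(NA_integer_, n_pts)
  if (rho > 0) {
    key_l <- paste(tab$structure, tab$role, "left", tab$subpoint)
    key_self <- paste(tab$structure, tab$role, tab$side, tab$subpoint)
    right_rows <- which(tab$side == "right")
    partner[right_rows] <- match(
      paste(tab$structure, tab$role, "left", tab$subpoint)[right_rows], key_self)
  }

  subjects <- lapply(seq_len(params$n_subjects), function(i) {
    withr::with_seed(subject_seed(params$seed, i), {
      e <- matrix(rnorm(n_pts * 3), n_pts, 3)
      if (rho > 0) {
        for (r in which(!is.na(partner))) {
          mirror <- c(1, 1, -1) # right z-deviation mirrors the left one
          e[r, ] <- rho * mirror * e[partner[r], ] + sqrt(1 - rho^2) * e[r, ]
        }
      }
      xyz <- means + e * sds
      tibble::tibble(
        subject_id = subject_ids(params$n_subjects)[i],
        structure = tab$structure, role = tab$role,
        side = tab$side, subpoint = tab$subpoint,
        x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
        frame = "pics")
    })
  })
  dplyr::bind_rows(subjects)
}

#' Rotation matrix from three axis angles
#'
#' Proper rotation `R = Rz(gamma) Ry(beta) Rx(alpha)` (intrinsic x-y-z
#' order, degrees).
#'
#' @param angles_deg Numeric length 3: rotations about x, y, z in degrees.
#' @return A 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(angles_deg) {
  stopifnot(length(angles_deg) == 3)
  a <- angles_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Embed a PICS-space subject in scanner space
#'
#' Applies one rigid motion `p -> R p + t` to all muscle points of a
#' subject and to the configured bony-landmark geometry, emulating an
#' arbitrary pelvic inclination and scanner position. The emitted
#' landmarks are exactly what [build_pics_frame()] needs to undo the
#' motion.
#'
#' @param subject A point tibble (one or more subjects, PICS frame).
#' @param rotation Either a length-3 vector of axis angles in degrees (see
#'   [rotation_matrix()]) or a 3 x 3 proper rotation matrix.
#' @param translation_mm Numeric length-3 translation (mm).
#' @param landmark_geometry PICS-space landmark positions to embed
#'   alongside the points.
#' @return A list with `points` (scanner frame) and `landmarks` (scanner
#'   frame, one set per subject with a `subject_id` column).
#' @export
embed_in_scanner <- function(subject, rotation = c(0, 0, 0),
                             translation_mm = c(0, 0, 0),
                             landmark_geometry = default_landmark_geometry()) {
  check_frame_tag(subject, "pics")
  rot <- if (is.matrix(rotation)) rotation else rotation_matrix(rotation)
  if (!all(dim(rot) == c(3, 3)) ||
      max(abs(t(rot) %*% rot - diag(3))) > 1e-9 || det(rot) < 0) {
    abort("rotation must be a proper rotation (orthonormal, det = +1)")
  }
  apply_motion <- function(tbl) {
    xyz <- as.matrix(tbl[, c("x_mm", "y_mm", "z_mm")])
    out <- sweep(xyz %*% t(rot), 2, -translation_mm)
    tbl$x_mm <- out[, 1]; tbl$y_mm <- out[, 2]; tbl$z_mm <- out[, 3]
    tbl$frame <- "scanner"
    tbl
  }
  points <- apply_motion(subject)
  lms <- landmark_geometry
  lms$frame <- "pics" # tag irrelevant pre-motion; overwritten below
  lms <- apply_motion(lms)
  landmarks <- dplyr::bind_rows(lapply(unique(subject$subject_id), function(sid) {
    dplyr::mutate(lms, subject_id = sid, .before = 1)
  }))
  list(points = points, landmarks = landmarks)
}

#' Embed a whole cohort with random rigid motions
#'
#' Draws one rigid motion per subject -- inclination about the left-right
#' axis from `inclination_deg`, the other two rotations from
#' `rotation_deg`, translations from `translation_mm`, all uniform -- and
#' applies it with [embed_in_scanner()]. Motions come from per-subject
#' substreams of the global seed.
#'
#' @param cohort A multi-subject point tibble in PICS frame.
#' @param params A [sim_params()] object.
#' @return A list with `points` and `landmarks`, both scanner frame.
#' @export
embed_cohort <- function(cohort, params) {
  stopifnot(inherits(params, "sim_params"))
  check_frame_tag(cohort, "pics")
  sids <- unique(cohort$subject_id)
  out <- lapply(seq_along(sids), function(i) {
    sub <- cohort[cohort$subject_id == sids[i], , drop = FALSE]
    withr::with_seed(subject_seed(params$seed, i, salt = 1L), {
      angles <- c(runif(1, params$rotation_deg[1], params$rotation_deg[2]),
                  runif(1, params$rotation_deg[1], params$rotation_deg[2]),
                  runif(1, params$inclination_deg[1], params$inclination_deg[2]))
      trans <- runif(3, params$translation_mm[1], params$translation_mm[2])
      embed_in_scanner(sub, angles, trans, params$landmark_geometry)
    })
  })
  list(points = dplyr::bind_rows(lapply(out, `[[`, "points")),
       landmarks = dplyr::bind_rows(lapply(out, `[[`, "landmarks")))
}

#' Recover PICS coordinates of an embedded cohort
#'
#' Builds each subject's PICS frame from its scanner-space landmarks and
#' maps that subject's points into PICS space.
#'
#' @param points Scanner-frame point tibble.
#' @param landmarks Scanner-frame landmark tibble with `subject_id`.
#' @return The points in PICS frame.
#' @export
normalize_cohort <- function(points, landmarks) {
  check_frame_tag(points, "scanner")
  sids <- unique(points$subject_id)
  dplyr::bind_rows(lapply(sids, function(sid) {
    lms <- landmarks[landmarks$subject_id == sid, , drop = FALSE]
    if (nrow(lms) == 0) abort(paste0("no landmarks for subject ", sid))
    frame <- build_pics_frame(lms[, setdiff(names(lms), "subject_id")])
    to_pics(points[points$subject_id == sid, , drop = FALSE], frame)
  }))
}

#' Simulate two raters annotating the same subjects
#'
#' Adds independent per-axis Gaussian noise (SD `rater_sigma_mm`) to every
#' muscle point, twice, emulating two independent human raters placing the
#' same anatomical points. Landmarks are left untouched by default (the
#' bony points are easy to identify and the study's reliability question
#' concerns the muscle points).
#'
#' @param points A point tibble (any frame).
#' @param rater_sigma_mm Noise SD in mm, `>= 0`.
#' @param seed Integer seed for the two noise draws.
#' @return A list with tibbles `rater1` and `rater2`.
#' @export
simulate_raters <- function(points, rater_sigma_mm = 2, seed = 1L) {
  if (rater_sigma_mm < 0) abort("rater_sigma_mm must be >= 0")
  perturb <- function(tbl, s) {
    withr::with_seed(s, {
      n <- nrow(tbl)
      tbl$x_mm <- tbl$x_mm + rnorm(n, 0, rater_sigma_mm)
      tbl$y_mm <- tbl$y_mm + rnorm(n, 0, rater_sigma_mm)
      tbl$z_mm <- tbl$z_mm + rnorm(n, 0, rater_sigma_mm)
    })
    tbl
  }
  list(rater1 = perturb(points, subject_seed(seed, 1L, salt = 2L)),
       rater2 = perturb(points, subject_seed(seed, 2L, salt = 2L)))
}
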
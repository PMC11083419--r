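# Shared fixtures, all built in code.

ref_table <- lam_coordinate_reference()

# One subject whose every point sits at the reference-cohort mean.
mean_subject <- function(id = "S1", frame = "pics") {
  tibble::tibble(
    subject_id = id,
    structure = ref_table$structure, role = ref_table$role,
    side = ref_table$side, subpoint = ref_table$subpoint,
    x_mm = ref_table$mean_x, y_mm = ref_table$mean_y, z_mm = ref_table$mean_z,
    frame = frame)
}

# Canonical PICS-aligned landmark set (identity frame).
aligned_landmarks <- function() {
  landmark_set(ipp = c(0, 0, 0), scj = c(100, 0, 0),
               is_left = c(10, -5, -45), is_right = c(10, -5, 45))
}

# A random but non-degenerate scanner-space landmark set.
random_landmarks <- function() {
  rot <- rotation_matrix(runif(3, -40, 40))
  trans <- runif(3, -80, 80)
  move <- function(p) as.vector(rot %*% p + trans)
  landmark_set(ipp = move(c(0, 0, 0)), scj = move(c(100 + runif(1, -20, 20), 0, 0)),
               is_left = move(c(10, -5, -45) + runif(3, -5, 5)),
               is_right = move(c(10, -5, 45) + runif(3, -5, 5)))
}

# Two-way ANOVA mean squares computed independently via stats::aov,
# used as the oracle for the ICC decomposition.
aov_icc2k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
}
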
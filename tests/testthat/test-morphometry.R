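# Hand-computed oracle values from the reference mean coordinates:
#   COC left origin (56.2, -49.5, -52.4) to insertions (87.2, -56.5, -8.9)
#   and (75.3, -45.7, -8.8): lengths sqrt(2902.25) and sqrt(2280.21).
#   PRM left course 1 direction (60.4, -14.2, 20.4): |d| = sqrt(4265.96),
#   transversal angle asin(-14.2 / |d|).
coc_len1 <- sqrt(31.0^2 + 7.0^2 + 43.5^2)    # 53.87253...
coc_len2 <- sqrt(19.1^2 + 3.8^2 + 43.6^2)    # 47.75154...
prm_trans1 <- asin(-14.2 / sqrt(60.4^2 + 14.2^2 + 20.4^2)) * 180 / pi # -12.557

test_that("muscle_length is the Euclidean origin-insertion distance", {
  expect_warning(z <- muscle_length(c(0, 0, 0), c(0, 0, 0)), "degenerate")
  expect_equal(z, 0)
  expect_equal(muscle_length(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(muscle_length(c(3, 4, 0), c(0, 0, 0)), 5) # symmetric
  expect_equal(muscle_length(c(56.2, -49.5, -52.4), c(87.2, -56.5, -8.9)),
               coc_len1, tolerance = 1e-12)
})

test_that("plane angles follow the arcsin-of-normal-component definition", {
  expect_equal(plane_angle(c(0, 1, 0), "transversal"), 90)
  expect_equal(plane_angle(c(1, 0, 0), "transversal"), 0)
  expect_equal(plane_angle(c(0, -1, 0), "transversal"), -90)
  expect_equal(plane_angle(c(0, 0, 1), "sagittal"), 90)
  expect_equal(plane_angle(c(1, 0, 0), "coronal"), 90)
  expect_equal(plane_angle(c(60.4, -14.2, 20.4), "transversal"),
               prm_trans1, tolerance = 1e-12)
  expect_error(plane_angle(c(0, 0, 0), "sagittal"), "zero direction")
})

test_that("plane_angle agrees with the 90-minus-vector-angle brute force", {
  set.seed(13)
  for (i in 1:200) {
    d <- rnorm(3)
    for (plane in c("sagittal", "transversal", "coronal")) {
      n <- switch(plane, sagittal = c(0, 0, 1), transversal = c(0, 1, 0),
                  coronal = c(1, 0, 0))
      theta_to_normal <- acos(sum(d * n) / sqrt(sum(d^2))) * 180 / pi
      oracle <- sign(sum(d * n)) * (90 - min(theta_to_normal, 180 - theta_to_normal))
      expect_equal(plane_angle(d, plane), oracle, tolerance = 1e-9)
    }
  }
})

test_that("angle identity sin^2 sag + sin^2 trans + sin^2 cor = 1 per course", {
  set.seed(14)
  for (i in 1:500) {
    d <- rnorm(3)
    s <- sin(c(plane_angle(d, "sagittal"), plane_angle(d, "transversal"),
               plane_angle(d, "coronal")) * pi / 180)
    expect_equal(sum(s^2), 1, tolerance = 1e-9)
  }
})

test_that("quarter points split the PVM origin line into four equal parts", {
  q <- pvm_quarter_points(c(0, 0, 0), c(4, 0, 0))
  expect_equal(unname(q), rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)))

  q2 <- pvm_quarter_points(c(15.2, -34.6, -32.4), c(-1.3, -10.5, -16.1))
  expect_equal(unname(q2["q2", ]), c(6.95, -22.55, -24.25), tolerance = 1e-12)
  # q1 and q3 mirror about q2; segments equal length
  expect_equal(q2["q1", ] + q2["q3", ], 2 * q2["q2", ], tolerance = 1e-12)
  expect_equal(sqrt(sum((q2["q1", ] - q2["q2", ])^2)),
               sqrt(sum((q2["q2", ] - q2["q3", ])^2)), tolerance = 1e-12)
  expect_error(pvm_quarter_points(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("the default roster yields the expected course groups", {
  courses <- build_courses(mean_subject())
  counts <- table(courses$structure, courses$side)
  expect_equal(unname(counts["COC", c("left", "right")]), c(2L, 2L))
  expect_equal(unname(counts["ICM", c("left", "right")]), c(2L, 2L))
  expect_equal(unname(counts["PRM", c("left", "right")]), c(2L, 2L))
  expect_equal(unname(counts["PAM", c("left", "right")]), c(1L, 1L))
  expect_equal(unname(counts["PPM", c("left", "right")]), c(1L, 1L))
  expect_equal(unname(counts["PVaM", c("left", "right")]), c(2L, 2L))
  expect_true(all(courses$flag == "ok"))
})

test_that("mean-coordinate morphometry matches the arithmetic oracles", {
  m <- subject_morphometry(mean_subject())
  g <- function(st, sd_) m[m$structure == st & m$side == sd_, ]
  expect_equal(g("COC", "left")$length_mm, (coc_len1 + coc_len2) / 2,
               tolerance = 1e-9) # ~50.81, reference table prints 50.8(7.2)
  # PPM left: q2 (6.95, -22.55, -24.25) to insertion (29.0, 3.5, -0.2)
  expect_equal(g("PPM", "left")$length_mm,
               sqrt(22.05^2 + 26.05^2 + 24.05^2), tolerance = 1e-9) # ~41.75
  # PRM left mean of the course pair
  prm_len2 <- sqrt(44.1^2 + 12^2 + 20.2^2)
  expect_equal(g("PRM", "left")$length_mm,
               (sqrt(4265.96) + prm_len2) / 2, tolerance = 1e-9) # ~57.6
})

test_that("mirror reflection flips sagittal angles, keeps lengths and transversal", {
  subj <- mean_subject()
  mirrored <- subj
  mirrored$z_mm <- -subj$z_mm
  mirrored$side <- c(left = "right", midline = "midline", right = "left")[subj$side]
  m0 <- subject_morphometry(subj)
  m1 <- subject_morphometry(mirrored)
  swap <- c(left = "right", midline = "midline", right = "left")
  for (i in seq_len(nrow(m0))) {
    j <- which(m1$structure == m0$structure[i] & m1$side == swap[[m0$side[i]]])
    expect_equal(m1$length_mm[j], m0$length_mm[i], tolerance = 1e-9)
    expect_equal(m1$angle_sagittal_deg[j], -m0$angle_sagittal_deg[i],
                 tolerance = 1e-9)
    expect_equal(m1$angle_transversal_deg[j], m0$angle_transversal_deg[i],
                 tolerance = 1e-9)
  }
})

test_that("missing points yield flagged records, not errors", {
  subj <- mean_subject()
  subj <- subj[!(subj$structure == "PAM" & subj$side == "left"), ]
  courses <- build_courses(subj)
  pam_left <- courses[courses$structure == "PAM" & courses$side == "left", ]
  expect_equal(pam_left$flag, "missing")
  m <- subject_morphometry(subj)
  expect_equal(m$flag[m$structure == "PAM" & m$side == "left"], "missing")
  expect_equal(m$flag[m$structure == "COC" & m$side == "left"], "ok")
})

test_that("cross pairing is configurable and differs from the default", {
  m_match <- subject_morphometry(mean_subject())
  m_cross <- subject_morphometry(mean_subject(),
                                 course_pairing(subpoints = "cross"))
  prm_match <- m_match$length_mm[m_match$structure == "PRM" & m_match$side == "left"]
  prm_cross <- m_cross$length_mm[m_cross$structure == "PRM" & m_cross$side == "left"]
  expect_gt(abs(prm_match - prm_cross), 1)
})
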
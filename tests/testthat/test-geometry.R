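test_that("midplane angles follow the anterior-posterior reference line", {
  # horizontal symmetric C3 body -> 0 degrees
  c3 <- rbind(C3_ant_sup = c(10, 1), C3_ant_inf = c(10, -1),
              C3_post_sup = c(0, 1), C3_post_inf = c(0, -1))
  expect_equal(midplane_angle(c3, "C3"), 0)
  # atlas arc centers on the unit slope -> 45 degrees
  expect_equal(midplane_angle(list(C1_ant_arc = c(5, 5),
                                   C1_post_arc = c(0, 0)), "C1"), 45)
  # rotating C7's superior corners by a known angle is recovered exactly
  c7 <- rbind(C7_sup_ant = c(8, 0), C7_sup_post = c(0, 0))
  for (a in c(-10, -37.25, 12.5, 89, 90)) {
    expect_equal(midplane_angle(rotate_points(c7, a), "C7"),
                 if (a == -90) 90 else a, tolerance = 1e-12)
  }
})

test_that("midplane angle errors name the problem", {
  expect_error(midplane_angle(list(C1_ant_arc = c(5, 5)), "C1"),
               class = "cervik_missing_landmark")
  expect_error(midplane_angle(list(C1_ant_arc = c(1, 1),
                                   C1_post_arc = c(1, 1)), "C1"),
               class = "cervik_degenerate_geometry")
  expect_error(midplane_angle(list(C1_ant_arc = c(NA, 1),
                                   C1_post_arc = c(0, 0)), "C1"),
               class = "cervik_invalid_argument")
})

test_that("joint rotation is the signed difference of midplane angles", {
  expect_equal(joint_rotation(5, 0), 5)
  expect_equal(joint_rotation(-3, 2), -5)
  expect_equal(joint_rotation(0, 0), 0)
  expect_error(joint_rotation(NaN, 0), class = "cervik_invalid_angle")
})

test_that("angles are invariant to translation, scaling and mirroring", {
  tmpl <- vertebra_template()
  base <- midplane_angles(rotate_points(tmpl, 7.3))
  shifted <- rotate_points(tmpl, 7.3)
  shifted[, 1] <- shifted[, 1] + 103.7
  shifted[, 2] <- shifted[, 2] - 55.1
  expect_equal(midplane_angles(shifted), base)
  expect_equal(midplane_angles(rotate_points(tmpl, 7.3) * 4.2), base)
  mirrored <- rotate_points(tmpl, 7.3)
  mirrored[, 1] <- -mirrored[, 1]
  expect_equal(midplane_angles(mirrored, facing = "-x"), base)
})

test_that("static landmark input yields identically zero joint positions", {
  ang <- matrix(0, 10, 7)
  seq0 <- landmarks_from_angles(ang, "extension")
  trs <- angle_trajectories(seq0, upright_reference = "first-frame")
  expect_length(trs, 7)
  for (tr in trs) expect_equal(tr$position, rep(0, 10))
})

test_that("rotating a single vertebra moves exactly its two joints", {
  # C4 rotates +10 degrees linearly; every joint angle is a difference of
  # vertebra orientations, so C3/C4 ends at -10 and C4/C5 at +10
  n <- 26
  ramp <- seq(0, 10, length.out = n)
  tmpl <- vertebra_template()
  coords <- array(NA_real_, dim = c(n, 26, 2),
                  dimnames = list(NULL, landmark_ids(), c("x", "y")))
  c4 <- landmark_ids("C4")
  ctr <- colMeans(tmpl[c4, ])
  for (f in seq_len(n)) {
    coords[f, , ] <- tmpl
    rel <- sweep(tmpl[c4, ], 2, ctr)
    coords[f, c4, ] <- sweep(rotate_points(rel, ramp[f]), 2, ctr, "+")
  }
  seq1 <- landmark_sequence("s1", "extension", (seq_len(n) - 1) / 25, coords)
  trs <- angle_trajectories(seq1, upright_reference = "first-frame")
  ends <- vapply(trs, function(tr) tr$position[n], numeric(1))
  expect_equal(unname(ends[c("C3/C4", "C4/C5")]), c(-10, 10),
               tolerance = 1e-9)
  expect_equal(max(abs(ends[setdiff(joint_levels(),
                                    c("C3/C4", "C4/C5"))])), 0,
               tolerance = 1e-9)
})

test_that("geometry round-trips angle sets through landmarks", {
  set.seed(42)
  for (rep in 1:20) {
    ang <- matrix(stats::runif(15 * 7, -12, 12), 15, 7)
    seqs <- landmarks_from_angles(ang, "flexion")
    trs <- angle_trajectories(seqs, upright_reference = "first-frame")
    for (j in seq_len(7)) {
      expect_equal(trs[[j]]$position, ang[, j] - ang[1, j],
                   tolerance = 1e-6)
    }
  }
})

test_that("initial-hold-mean reference zeroes a noisy static hold", {
  set.seed(3)
  n <- 201  # 8 s at 25 fps, first 2 s are the hold
  ang <- matrix(stats::rnorm(n * 7, 0, 0.2), n, 7)
  seqs <- landmarks_from_angles(ang, "extension")
  trs <- angle_trajectories(seqs, upright_reference = "initial-hold-mean",
                            hold_duration = 2)
  hold <- trs[[1]]$times <= 2
  for (j in c(1, 4, 7)) {
    expect_lt(abs(mean(trs[[j]]$position[hold])), 4 * 0.2 / sqrt(sum(hold)))
  }
})

test_that("landmark jitter perturbs recovered angles without bias", {
  set.seed(11)
  ang <- matrix(rep(seq(0, 8, length.out = 40), 7), 40, 7)
  errs <- replicate(30, {
    seqs <- landmarks_from_angles(ang, "extension", jitter_sd = 0.5)
    trs <- angle_trajectories(seqs, upright_reference = "first-frame")
    trs[["C3/C4"]]$position[40] - (ang[40, 4] - ang[1, 4])
  })
  expect_lt(abs(mean(errs)), 3 * stats::sd(errs) / sqrt(length(errs)))
  expect_gt(stats::sd(errs), 0.01)
})
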
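test_that("joint specs validate their type invariants", {
  expect_error(joint_spec("C0/C1", "flexion", "C", 5, surplus_pro = 1),
               class = "cervik_spec_validation")
  expect_error(joint_spec("C0/C1", "flexion", "S", 5, surplus_pro = 0),
               class = "cervik_spec_validation")
  expect_error(joint_spec("C0/C1", "flexion", "A", 2),
               class = "cervik_spec_validation")
  expect_error(joint_spec("C0/C1", "flexion", "C", -5),
               class = "cervik_spec_validation")
  expect_s3_class(joint_spec("C0/C1", "flexion", "S", 5, surplus_pro = 2),
                  "synthetic_joint_spec")
})

test_that("noise-free trajectories reproduce their spec exactly", {
  # Classic: monotone to end-range
  ms <- motion_summary(trim_holds(simulate_trajectory(
    joint_spec("C4/C5", "extension", "C", end_range = 10))))
  expect_equal(ms$end_range, 10)
  expect_equal(ms$surplus_pro, 0)
  expect_equal(classify_joint(ms), "C")
  expect_equal(ms$epoch_of_max, 10L)
  # Surplus: boundary maximum exceeds end-range by exactly the surplus
  ms <- motion_summary(trim_holds(simulate_trajectory(
    joint_spec("C1/C2", "flexion", "S", end_range = 5, surplus_pro = 2,
               overshoot_epoch = 6))))
  expect_equal(ms$max_pro, 7, tolerance = 1e-6)
  expect_equal(ms$surplus_pro, 2, tolerance = 1e-6)
  expect_equal(ms$epoch_of_max, 6L)
  expect_equal(classify_joint(ms), "S")
  # Anti-directional: terminates below upright
  ms <- motion_summary(trim_holds(simulate_trajectory(
    joint_spec("C0/C1", "flexion", "A", end_range = -1.5,
               surplus_pro = 2.5))))
  expect_equal(ms$end_range, -1.5)
  expect_equal(ms$max_pro, 1, tolerance = 1e-6)
  expect_equal(classify_joint(ms), "A")
  # anti-directional dip of a requested depth
  ms <- motion_summary(trim_holds(simulate_trajectory(
    joint_spec("C2/C3", "extension", "C", end_range = 8,
               surplus_anti = 1.2))))
  expect_equal(ms$surplus_anti, 1.2, tolerance = 1e-6)
  expect_equal(classify_joint(ms), "C")
  # never-pro type A: peak below upright
  ms <- motion_summary(trim_holds(simulate_trajectory(
    joint_spec("C0/C1", "extension", "A", end_range = -2))))
  expect_true(ms$never_pro)
})

test_that("the recording protocol shapes the sampled trajectory", {
  tr <- simulate_trajectory(joint_spec("C3/C4", "extension", "C", 10))
  expect_length(tr$times, 401)  # 16 s at 25 fps
  # holds: flat at upright for 2 s, at end-range for the last 2 s
  expect_equal(tr$position[tr$times < 2], rep(0, sum(tr$times < 2)))
  expect_equal(tr$position[tr$times > 14], rep(10, sum(tr$times > 14)))
  # flexion sign convention: recorded positions are negative
  trf <- simulate_trajectory(joint_spec("C3/C4", "flexion", "C", 10))
  expect_equal(trf$position[length(trf$position)], -10)
})

test_that("identical spec and seed give identical output", {
  sp <- joint_spec("C5/C6", "extension", "S", 6, surplus_pro = 1.5,
                   noise_sd = 0.2)
  expect_identical(simulate_trajectory(sp, seed = 9)$position,
                   simulate_trajectory(sp, seed = 9)$position)
  cs <- cohort_spec(n_subjects = 2)
  expect_identical(simulate_cohort(cs, seed = 5)$manifest,
                   simulate_cohort(cs, seed = 5)$manifest)
  # seeded simulation does not disturb the caller's RNG stream
  set.seed(1); a <- stats::rnorm(1)
  set.seed(1); invisible(simulate_trajectory(sp, seed = 9)); b <- stats::rnorm(1)
  expect_identical(a, b)
})

test_that("cohorts have the protocol size and respect the type mix", {
  co <- simulate_cohort(cohort_spec(n_subjects = 33, noise_sd = 0),
                        seed = 12)
  expect_equal(nrow(co$manifest), 33 * 7 * 2)
  expect_equal(sum(co$manifest$direction == "flexion"), 231)
  # empirical mix approaches the target with many joints
  big <- simulate_cohort(cohort_spec(n_subjects = 72, noise_sd = 0),
                         seed = 13)
  mixf <- prop.table(table(big$manifest$motion_type[
    big$manifest$direction == "flexion"]))
  target <- default_type_mix()$flexion
  expect_lt(max(abs(mixf[names(target)] - target)), 0.03)
  # truncation: no negative magnitudes anywhere
  expect_true(all(abs(co$manifest$end_range) > 0))
  expect_true(all(co$manifest$surplus_anti >= 0))
  expect_true(all(co$manifest$surplus_pro[co$manifest$motion_type == "S"] >
                    0))
})

test_that("surplus recovery error stays small under marking noise", {
  set.seed(14)
  errs <- vapply(1:120, function(i) {
    sp <- joint_spec("C2/C3", "extension", "S",
                     end_range = stats::runif(1, 1, 10),
                     surplus_pro = stats::runif(1, 0.5, 5),
                     overshoot_epoch = sample(3:9, 1), noise_sd = 0.1)
    tr <- simulate_trajectory(sp)
    ms <- motion_summary(trim_holds(tr))
    abs(ms$surplus_pro - attr(tr, "ground_truth")$surplus_pro)
  }, numeric(1))
  expect_lt(mean(errs), 0.15)
})

test_that("landmark synthesis inverts the landmark geometry", {
  # one joint ramping while the rest stay still
  ang <- matrix(0, 30, 7)
  ang[, 3] <- seq(0, 10, length.out = 30)
  seqs <- landmarks_from_angles(ang, "extension")
  trs <- angle_trajectories(seqs, upright_reference = "first-frame")
  expect_equal(trs[["C2/C3"]]$position, ang[, 3], tolerance = 1e-6)
  for (j in setdiff(joint_levels(), "C2/C3"))
    expect_equal(max(abs(trs[[j]]$position)), 0, tolerance = 1e-6)
  # jitter degrades recovery smoothly: RMSE grows with jitter
  set.seed(15)
  rmse_at <- function(jit) {
    e <- replicate(12, {
      s <- landmarks_from_angles(ang, "extension", jitter_sd = jit)
      tr <- angle_trajectories(s, upright_reference = "first-frame")
      tr[["C2/C3"]]$position[30] - 10
    })
    sqrt(mean(e^2))
  }
  expect_lt(rmse_at(0.1), rmse_at(2))
})

test_that("cohort landmark export round-trips through the full pipeline", {
  co <- simulate_cohort(cohort_spec(n_subjects = 1, noise_sd = 0),
                        seed = 16)
  seqs <- cohort_landmarks(co)
  expect_length(seqs, 2)  # one per direction
  trs <- angle_trajectories(seqs[[1]], upright_reference = "first-frame")
  orig <- co$trajectories[vapply(co$trajectories, function(t)
    t$direction == seqs[[1]]$direction, logical(1))]
  names(orig) <- vapply(orig, `[[`, character(1), "joint")
  for (j in joint_levels())
    expect_equal(trs[[j]]$position, orig[[j]]$position, tolerance = 1e-6)
})
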
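test_that("velocity and acceleration follow the segment-fit definitions", {
  prof <- compute_velocity_profile(
    tibble::tibble(strike_time = c(0, 0.5, 1), x_cm = c(0, 30, 60))
  )
  expect_equal(prof$velocity_mps, 0.6)
  expect_equal(prof$acceleration_mps2, 0)

  prof2 <- compute_velocity_profile(
    tibble::tibble(strike_time = c(0, 0.5, 1), x_cm = c(0, 25, 60))
  )
  expect_equal(prof2$acceleration_mps2, 0.4) # segment velocities 0.5 and 0.7
  expect_gt(abs(prof2$acceleration_mps2), 0.1)

  prof3 <- compute_velocity_profile(tibble::tibble(strike_time = 0.5, x_cm = 40))
  expect_true(is.na(prof3$velocity_mps))
})

test_that("walking validity applies the velocity and acceleration windows", {
  mk <- function(v, a = 0) {
    # three strikes generating exactly velocity v and acceleration a
    t <- c(0, 0.5, 1)
    v1 <- v - a / 2 * 0.5
    v2 <- v + a / 2 * 0.5
    x <- c(0, v1 * 0.5, v1 * 0.5 + v2 * 0.5) * 100
    tibble::tibble(strike_time = t, x_cm = x, y_cm = c(25, 25, 25), side = "L")
  }
  ok <- validate_walking_trial(mk(0.6))
  expect_true(ok$valid)
  expect_equal(ok$reasons, "")

  fast <- validate_walking_trial(mk(0.85))
  expect_false(fast$valid)
  expect_equal(fast$reasons, "velocity")

  acc <- validate_walking_trial(mk(0.75, a = 0.15))
  expect_false(acc$valid)
  expect_equal(acc$reasons, "acceleration")

  crooked <- mk(0.6)
  crooked$y_cm <- c(10, 25, 40)
  expect_match(validate_walking_trial(crooked)$reasons, "straightness")

  single <- validate_walking_trial(tibble::tibble(
    strike_time = 0.5, x_cm = 10, y_cm = 25, side = "L"
  ))
  expect_false(single$valid)
  expect_equal(single$reasons, "too_few_footfalls")
})

test_that("best-trial selection keeps the k closest to the target velocity", {
  vels <- c(0.58, 0.61, 0.63, 0.66, 0.70, 0.72, 0.75, 0.78, 0.79, 0.60)
  qc <- tibble::tibble(
    trial = 1:10, velocity_mps = vels, acceleration_mps2 = 0, valid = TRUE
  )
  sel <- select_best_trials(qc, k = 5, target = 0.6)
  expect_setequal(sel$velocity_mps, c(0.60, 0.61, 0.58, 0.63, 0.66))
  expect_false(attr(sel, "short"))

  # permutation invariance up to the documented tie-break
  perm <- qc[c(7, 2, 10, 4, 1, 9, 3, 5, 8, 6), ]
  sel2 <- select_best_trials(perm, k = 5, target = 0.6)
  expect_setequal(sel2$trial, sel$trial)

  # exactly k valid trials: identity
  sel3 <- select_best_trials(qc[1:5, ], k = 5, target = 0.6)
  expect_equal(sel3$trial, 1:5)

  # fewer than k: returned in full, with a warning
  expect_warning(
    sel4 <- select_best_trials(qc[1:3, ], k = 5, target = 0.6),
    class = "psw_short_session"
  )
  expect_equal(nrow(sel4), 3)
  expect_true(attr(sel4, "short"))
})

test_that("ties in velocity distance break on acceleration then trial order", {
  # 0.25 and 0.75 are exactly representable, so all three trials tie on
  # |v - 0.5| = 0.25 and the two smallest |acceleration| win
  qc <- tibble::tibble(
    trial = 1:3,
    velocity_mps = c(0.25, 0.75, 0.75),
    acceleration_mps2 = c(0.09, 0.01, 0.0),
    valid = TRUE
  )
  sel <- select_best_trials(qc, k = 2, target = 0.5)
  expect_setequal(sel$trial, c(2, 3))
  # equal acceleration too: trial order decides
  qc$acceleration_mps2 <- 0
  sel2 <- select_best_trials(qc, k = 2, target = 0.5)
  expect_equal(sel2$trial, c(1, 2))
})

test_that("landing validity demands forelimbs first, travelling forward", {
  ok <- tibble::tibble(
    position = c("fore", "fore", "hind", "hind"),
    strike_time = c(1, 1, 1.1, 1.1),
    x_cm = c(50, 50, 32, 32)
  )
  expect_true(validate_landing_trial(ok)$valid)

  hind_first <- ok
  hind_first$strike_time <- c(1.1, 1.1, 1, 1)
  v <- validate_landing_trial(hind_first)
  expect_false(v$valid)
  expect_match(v$reasons, "hindlimb_first")

  fore_only <- ok[1:2, ]
  v2 <- validate_landing_trial(fore_only)
  expect_true(v2$valid)
  expect_false(v2$has_hind)

  backward <- ok
  backward$x_cm <- c(32, 32, 50, 50)
  expect_match(validate_landing_trial(backward)$reasons, "not_forward")
})

test_that("the vectorized study QC agrees with the per-trial rules", {
  cfg <- sim_config()
  study <- simulate_study(cfg, seed = 55)
  sm <- summarize_study(study, target = cfg$target_walk_velocity_mps)
  qc <- sm$qc
  idx <- which(qc$trial_type == "landing")[1:20]
  for (i in idx) {
    ref <- validate_landing_trial(study$trials$footfalls[[qc$.trial_id[i]]])
    expect_equal(qc$valid[i], ref$valid)
  }
  widx <- which(qc$trial_type == "walking")[1:20]
  for (i in widx) {
    ref <- validate_walking_trial(study$trials$footfalls[[qc$.trial_id[i]]],
      target = cfg$target_walk_velocity_mps
    )
    expect_equal(qc$valid[i], ref$valid)
    expect_equal(qc$velocity_mps[i], ref$velocity_mps)
  }
})

test_that("QC validity of rendered trials matches the plan's validity away from the window edge", {
  cfg <- sim_config()
  for (s in 1:6) {
    sim <- simulate_walking_trial(cfg, (s %% 4) + 1, 0, seed = 80 + s)
    plan_qc <- validate_walking_trial(sim$ground_truth)
    ff <- extract_trial(sim$recording, "walking", cfg$body_weight_kg[(s %% 4) + 1])
    ext_qc <- validate_walking_trial(ff)
    margin <- min(abs(abs(plan_qc$velocity_mps - 0.6) - 0.2))
    if (margin > 0.01) {
      expect_equal(ext_qc$valid, plan_qc$valid)
    }
    expect_equal(ext_qc$velocity_mps, plan_qc$velocity_mps, tolerance = 0.02)
  }
})
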
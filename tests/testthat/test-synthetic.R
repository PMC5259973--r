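cfg <- sim_config()

test_that("identical seeds give identical recordings; disjoint seeds differ", {
  a <- simulate_walking_trial(cfg, 1, 0, seed = 21)
  b <- simulate_walking_trial(cfg, 1, 0, seed = 21)
  c <- simulate_walking_trial(cfg, 1, 0, seed = 22)
  expect_identical(
    as.data.frame(a$recording$frames),
    as.data.frame(b$recording$frames)
  )
  expect_false(identical(
    as.data.frame(a$recording$frames),
    as.data.frame(c$recording$frames)
  ))
  expect_equal(a$ground_truth, b$ground_truth)
})

test_that("ground-truth VI equals the frame-grid integral of the stored curve", {
  for (s in 1:3) {
    gt <- simulate_walking_trial(cfg, 2, 24, seed = s, render = FALSE,
      keep_curves = TRUE
    )$ground_truth
    integral <- purrr::map_dbl(gt$curve, ~ sum(.x$force) / cfg$frame_rate_hz)
    expect_equal(gt$vi_pct_bw_s, integral, tolerance = 1e-9)
    gt2 <- simulate_landing_trial(cfg, 3, 6, seed = s, render = FALSE,
      keep_curves = TRUE
    )$ground_truth
    integral2 <- purrr::map_dbl(gt2$curve, ~ sum(.x$force) / cfg$frame_rate_hz)
    expect_equal(gt2$vi_pct_bw_s, integral2, tolerance = 1e-9)
  }
})

test_that("baseline landing forelimb peaks sit in the calibrated 185-190 %BW band", {
  gt <- purrr::map_dfr(
    1:40,
    ~ simulate_landing_trial(cfg, (.x %% 4) + 1, 0, seed = 300 + .x, render = FALSE)$ground_truth
  )
  fore <- gt$pvf_pct_bw[gt$position == "fore"]
  expect_gt(mean(fore), 175)
  expect_lt(mean(fore), 200)
})

test_that("landing stagger honours its configuration", {
  cfg0 <- sim_config(stagger_prob_baseline = 0, stagger_gain = 0)
  sims <- purrr::map(1:10, ~ simulate_landing_trial(cfg0, 1, 0, seed = .x, render = FALSE))
  tf <- purrr::map_dbl(sims, ~ .x$meta$tf1f2)
  expect_true(all(tf == 0))
  expect_true(all(!purrr::map_lgl(sims, ~ .x$meta$measurable)))

  cfg1 <- sim_config(stagger_prob_baseline = 1, stagger_gain = 0)
  sims1 <- purrr::map(1:10, ~ simulate_landing_trial(cfg1, 1, 0, seed = .x, render = FALSE))
  tf1 <- purrr::map_dbl(sims1, ~ abs(.x$meta$tf1f2))
  expect_true(all(tf1 >= 1 / 60 - 1e-9))
  # staggers are one or two frames at 60 Hz; a one-frame stagger is 0.0167 s
  expect_true(all(round(tf1 * 60) %in% c(1, 2)))
  one_frame <- tf1[round(tf1 * 60) == 1]
  expect_true(length(one_frame) > 0)
  expect_equal(unique(one_frame), 1 / 60, tolerance = 1e-12)
})

test_that("without lameness the landing symmetry index is centred at zero", {
  gt <- purrr::map_dfr(1:25, function(s) {
    sim <- simulate_landing_trial(cfg, (s %% 4) + 1, 0, seed = 500 + s, render = FALSE)
    tk <- trial_kinetics(sim$ground_truth)
    tk
  })
  expect_lt(abs(mean(gt$si_pvf)), 5)
})

test_that("decreasing the lameness factor never increases mean operated PVF", {
  lams <- c(1, 0.8, 0.6, 0.4, 0.2)
  means <- purrr::map_dbl(lams, function(l) {
    cfg_l <- sim_config(lameness_factor = flat_lameness(l))
    gt <- purrr::map_dfr(
      1:15,
      ~ simulate_landing_trial(cfg_l, 1, 24,
        seed = 700 + .x, render = FALSE,
        treatment = "control", operated_foot = "L"
      )$ground_truth
    )
    mean(gt$pvf_pct_bw[gt$role == "operated"])
  })
  expect_true(all(diff(means) < 0))
})

test_that("pain scores follow the latent-decay model and its guarantees", {
  # zero effect, zero noise: every score equals the baseline level
  cfg0 <- sim_config(pain_amplitude = c(control = 0, er_bup = 0), pain_noise = 0)
  p0 <- simulate_pain_scores(cfg0, 1, 1, seed = 1)
  expect_true(all(p0$score == 0))
  # defaults never exceed 2 (the study's observed ceiling) and never rescue
  ps <- purrr::map_dfr(1:20, function(s) {
    dplyr::bind_rows(
      simulate_pain_scores(cfg, 1, 1, seed = s, treatment = "control"),
      simulate_pain_scores(cfg, 1, 1, seed = s + 1000, treatment = "er_bup")
    )
  })
  expect_lte(max(ps$score), 2L)
  expect_false(any(ps$rescue))
  expect_true(all(ps$score >= 0 & ps$score <= 5))
  # control AUC above baseline exceeds the treated arm's on average
  aucs <- purrr::map_dfr(1:100, function(s) {
    ctl <- simulate_pain_scores(cfg, 1, 1, seed = 2000 + s, treatment = "control")
    trt <- simulate_pain_scores(cfg, 1, 1, seed = 6000 + s, treatment = "er_bup")
    tibble::tibble(
      control = pain_auc_above_baseline(ctl),
      er_bup = pain_auc_above_baseline(trt)
    )
  })
  expect_gt(mean(aucs$control), mean(aucs$er_bup))
  # reproducibility
  expect_equal(
    simulate_pain_scores(cfg, 2, 1, seed = 5),
    simulate_pain_scores(cfg, 2, 1, seed = 5)
  )
})

test_that("a full simulated study has the crossover's shape", {
  study <- simulate_study(cfg, seed = 77)
  expect_equal(nrow(study$trials), 4 * 2 * 8 * 20)
  expect_equal(as.data.frame(study$design), as.data.frame(default_allocation()))
  counts <- dplyr::count(study$trials, cat, period, time_h, trial_type)
  expect_true(all(counts$n == 10))
  # kinetic schedule: 6 post-op plus 2 baseline sessions per period
  expect_equal(
    sort(unique(study$trials$time_h)),
    c(-48, -24, 6, 24, 30, 48, 54, 72)
  )
  # pain schedule: 10 post-op observations plus 2 baselines per cat-period
  pain_counts <- dplyr::count(study$pain, cat, period)
  expect_true(all(pain_counts$n == 12))
  expect_equal(
    sort(unique(study$pain$time_h[study$pain$time_h > 0])),
    c(3, 6, 12, 24, 30, 36, 48, 54, 60, 72)
  )
  # disjoint seeds give distinct datasets
  study2 <- simulate_study(cfg, seed = 78)
  expect_false(identical(study$trials$footfalls[[1]], study2$trials$footfalls[[1]]))
})

test_that("the simulator refuses a mat too short for two strides", {
  cfg_short <- sim_config(mat_size_m = c(0.6, 0.5))
  expect_error(
    simulate_walking_trial(cfg_short, 1, 0, seed = 1),
    class = "psw_input_error"
  )
})
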
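test_that("symmetry index reproduces its limiting values", {
  expect_equal(symmetry_index(0, 180), -200)
  expect_equal(symmetry_index(150, 150), 0)
  expect_equal(symmetry_index(100, 300), -100)
  expect_warning(out <- symmetry_index(0, 0), class = "psw_si_undefined")
  expect_true(is.na(out))
  expect_error(symmetry_index(-1, 10), class = "psw_input_error")
})

test_that("symmetry index is antisymmetric, scale-invariant and bounded", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 0, 300)
    b <- runif(1, 0, 300)
    if (a + b == 0) next
    si <- symmetry_index(a, b)
    expect_equal(si, -symmetry_index(b, a))
    k <- runif(1, 0.1, 10)
    expect_equal(symmetry_index(k * a, k * b), si, tolerance = 1e-12)
    expect_gte(si, -200)
    expect_lte(si, 200)
  }
  expect_equal(symmetry_index(5, 0), 200) # attained only at single-limb loading
})

test_that("landing timing metrics follow the strike-time definitions", {
  ff <- tibble::tibble(
    role = c("operated", "non_operated", "hind", "hind"),
    position = c("fore", "fore", "hind", "hind"),
    strike_time = c(1.017, 1.000, 1.117, 1.125)
  )
  tm <- landing_timing(ff, frame_rate_hz = 60)
  expect_equal(tm$tf1f2, 0.017, tolerance = 1e-9)
  expect_true(tm$measurable)
  expect_equal(tm$tf1h1, 0.117, tolerance = 1e-9)

  simult <- ff
  simult$strike_time[1] <- 1.000
  tm2 <- landing_timing(simult, 60)
  expect_equal(tm2$tf1f2, 0)
  expect_false(tm2$measurable)

  missing_fore <- ff[-1, ]
  tm3 <- landing_timing(missing_fore, 60)
  expect_true(is.na(tm3$tf1f2))
})

test_that("NTf1f2 counting matches the study's 19-in-78 arithmetic", {
  out <- count_ntf1f2(c(rep(TRUE, 19), rep(FALSE, 59)))
  expect_equal(out$n_measurable, 19)
  expect_equal(out$n_trials, 78)
  expect_equal(out$proportion, 19 / 78)
  expect_equal(round(100 * out$proportion), 24)
  expect_equal(count_ntf1f2(rep(FALSE, 10))$proportion, 0)
  expect_equal(count_ntf1f2(rep(TRUE, 7))$proportion, 1)
})

test_that("session summaries use per-trial SI averaged across trials", {
  sym <- tibble::tibble(
    role = rep(c("operated", "non_operated"), 1),
    position = "fore",
    strike_time = c(1, 1),
    pvf_pct_bw = c(150, 150),
    vi_pct_bw_s = c(12, 12)
  )
  trials <- tibble::tibble(footfalls = rep(list(sym), 5))
  sm <- session_summary(trials)
  expect_equal(sm$si_pvf_mean, 0)
  expect_equal(sm$si_pvf_sd, 0)
  expect_equal(sm$n_trials, 5)

  halved <- tibble::tibble(
    role = c("operated", "non_operated"),
    position = "fore",
    strike_time = c(1, 1),
    pvf_pct_bw = c(100, 200),
    vi_pct_bw_s = c(8, 16)
  )
  sm2 <- session_summary(tibble::tibble(footfalls = rep(list(halved), 4)))
  expect_equal(sm2$si_pvf_mean, -100 * 100 / 150, tolerance = 1e-9) # -66.67
  expect_equal(sm2$si_vi_mean, -100 * 8 / 12, tolerance = 1e-9)
})

test_that("a simulated session recovers its planted asymmetry", {
  cfg <- sim_config(lameness_factor = flat_lameness(0.5))
  gt <- purrr::map_dfr(1:30, function(s) {
    sim <- simulate_landing_trial(cfg, (s %% 4) + 1, 24,
      seed = 900 + s,
      render = FALSE, treatment = "control", operated_foot = "L"
    )
    trial_kinetics(sim$ground_truth)
  })
  planted_si <- 100 * (0.5 - 1) / ((0.5 + 1) / 2) # -66.67 at ratio 0.5
  expect_equal(mean(gt$si_pvf), planted_si, tolerance = 0.12)
})

test_that("baseline adjustment subtracts the per-period baseline average", {
  sm <- tibble::tibble(
    cat = 1, period = 1, treatment = "control", trial_type = "landing",
    time_h = c(-48, -24, 6),
    response = "si_pvf_mean",
    value = c(4.86, 4.86, -41.42)
  )
  out <- quiet_baseline_adjust(sm)
  expect_equal(out$delta, -46.28)
  expect_equal(out$baseline_n, 2)
  expect_false(out$baseline_incomplete)

  sm2 <- sm
  sm2$value[3] <- 4.86
  expect_equal(quiet_baseline_adjust(sm2)$delta, 0)

  # a missing baseline session: use the lone session and flag it
  sm3 <- sm[-1, ]
  expect_warning(out3 <- baseline_adjust(sm3), class = "psw_missing_baseline")
  expect_equal(out3$delta, -41.42 - 4.86)
  expect_true(out3$baseline_incomplete)
})

test_that("washout readiness uses an inclusive 95% t-interval of baselines", {
  base <- c(180, 185, 190, 175, 188, 182, 179, 186)
  ready <- washout_readiness(base, rep(mean(base), 5))
  expect_true(ready$ready)

  low <- washout_readiness(base, rep(mean(base) - 10 * sd(base), 5))
  expect_false(low$ready)

  # boundary case: current mean exactly at the interval edge is ready
  edge <- washout_readiness(base, rep(ready$ci_upper, 3))
  expect_true(edge$ready)
  just_out <- washout_readiness(base, rep(ready$ci_upper + 1e-6, 3))
  expect_false(just_out$ready)

  expect_error(washout_readiness(180, 185), class = "psw_input_error")
})

test_that("NTf1f2 proportion converges to the planted stagger probability", {
  cfg <- sim_config(stagger_prob_baseline = 0.3, stagger_gain = 0)
  meta <- purrr::map_dfr(
    1:200,
    ~ simulate_landing_trial(cfg, 1, 0, seed = 5000 + .x, render = FALSE)$meta
  )
  prop <- mean(meta$measurable)
  ci <- stats::binom.test(sum(meta$measurable), nrow(meta))$conf.int
  expect_true(0.3 >= ci[1] && 0.3 <= ci[2])
})
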
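cfg <- sim_config()

test_that("an all-zero recording yields zero events", {
  rec <- psw_recording(
    tibble::tibble(
      frame = integer(), row = integer(), col = integer(),
      force = double()
    ),
    n_frames = 10, n_rows = 20, n_cols = 20
  )
  expect_equal(nrow(detect_contacts(rec)), 0)
})

test_that("a single blob active over frames 10-12 is one event of 0.05 s", {
  rec <- blob_recording(10:12)
  ev <- detect_contacts(rec, force_threshold = 0.02)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_frames, 3L)
  expect_equal(ev$contact_time, 3 / 60)
  expect_equal(ev$strike_time, 10 / 60)
  expect_equal(ev$lift_time, 13 / 60)
})

test_that("two temporally overlapping blobs 10 cm apart stay distinct events", {
  a <- blob_recording(10:14, row0 = 20, col0 = 40)
  b <- blob_recording(12:16, row0 = 20, col0 = 60) # 20 sensels = 10 cm away
  rec <- psw_recording(rbind(a$frames, b$frames),
    n_frames = 21, n_rows = 100, n_cols = 480
  )
  ev <- detect_contacts(rec, force_threshold = 0.02)
  expect_equal(nrow(ev), 2)
})

test_that("invalid detection parameters are rejected", {
  rec <- blob_recording(10:12)
  expect_error(detect_contacts(rec, force_threshold = 0), class = "psw_input_error")
  expect_error(detect_contacts(rec, min_frames = 1), class = "psw_input_error")
})

test_that("landing classification: earliest two strikes are the forelimbs", {
  # strikes at 1.000, 1.017, 1.117, 1.117 s on alternating lateral sides
  ev <- tibble::tibble(
    event = 1:4,
    strike_time = c(1.000, 1.017, 1.117, 1.117),
    x_cm = c(50, 50, 32, 32),
    y_cm = c(29, 21, 29.5, 20.5)
  )
  out <- classify_limbs(ev, "landing")
  expect_equal(sum(out$position == "fore"), 2)
  expect_equal(sum(out$position == "hind"), 2)
  expect_equal(out$position[order(out$strike_time)][1:2], c("fore", "fore"))
  expect_setequal(out$limb, c("LF", "RF", "LH", "RH"))
  # the higher-y paw is the cat's left
  expect_equal(out$limb[out$y_cm == 29], "LF")
})

test_that("a single event is classified as a forelimb", {
  ev <- tibble::tibble(event = 1L, strike_time = 1, x_cm = 50, y_cm = 25)
  out <- classify_limbs(ev, "landing")
  expect_equal(out$position, "fore")
})

test_that("walking limb labels match the generator for >= 95% of footfalls", {
  total <- 0
  hits <- 0
  for (s in 1:6) {
    sim <- simulate_walking_trial(cfg, (s %% 4) + 1, 0, seed = 40 + s)
    ff <- extract_trial(sim$recording, "walking", cfg$body_weight_kg[(s %% 4) + 1])
    gt <- sim$ground_truth
    for (j in seq_len(nrow(gt))) {
      d <- abs(ff$strike_time - gt$strike_time[j]) +
        abs(ff$x_cm - gt$x_cm[j]) / 10 + abs(ff$y_cm - gt$y_cm[j]) / 10
      k <- which.min(d)
      total <- total + 1
      hits <- hits + (ff$limb[k] == gt$limb[j])
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("kinetic normalization follows the %BW definitions", {
  w_kg <- 100 / 9.80665 # body-weight force of exactly 100 N
  rect <- tibble::tibble(curve = list(tibble::tibble(
    frame = 0:11, time_s = (0:11) / 60, force = rep(50, 12)
  )))
  out <- extract_kinetics(rect, w_kg, frame_rate_hz = 60)
  expect_equal(out$pvf_pct_bw, 50)
  expect_equal(out$vi_pct_bw_s, 10.0)
  tri_force <- c(30, 90, 150, 150, 90, 30) # midpoint-sampled triangle, peak 180
  tri <- tibble::tibble(curve = list(tibble::tibble(
    frame = 0:5, time_s = (0:5) / 60, force = tri_force
  )))
  out_tri <- extract_kinetics(tri, w_kg, frame_rate_hz = 60)
  expect_equal(out_tri$vi_pct_bw_s, 9.0)
  zero <- tibble::tibble(curve = list(tibble::tibble(
    frame = 0:3, time_s = (0:3) / 60, force = rep(0, 4)
  )))
  out0 <- extract_kinetics(zero, w_kg, frame_rate_hz = 60)
  expect_equal(out0$pvf_pct_bw, 0)
  expect_equal(out0$vi_pct_bw_s, 0)
  expect_error(extract_kinetics(rect, -1), class = "psw_input_error")
})

test_that("mat force during single-limb stance equals the limb's curve", {
  # a noise-free recording with a vanishing threshold: every rendered sensel
  # belongs to some event's footprint, so conservation is exact
  cfg0 <- sim_config(noise_sd = 0)
  sim <- simulate_landing_trial(cfg0, 1, 0, seed = 9)
  ev <- detect_contacts(sim$recording, force_threshold = 1e-6)
  # pick a frame where exactly one event is active
  spans <- purrr::map(ev$curve, ~ range(.x$frame))
  solo <- NULL
  for (i in seq_len(nrow(ev))) {
    frames_i <- ev$curve[[i]]$frame
    others <- unlist(purrr::map(ev$curve[-i], ~ .x$frame))
    cand <- setdiff(frames_i, others)
    if (length(cand) > 0) {
      solo <- c(i, cand[ceiling(length(cand) / 2)])
      break
    }
  }
  expect_false(is.null(solo))
  i <- solo[1]
  f <- solo[2]
  mat_total <- sum(sim$recording$frames$force[sim$recording$frames$frame == f])
  curve_val <- ev$curve[[i]]$force[ev$curve[[i]]$frame == f]
  expect_equal(curve_val, mat_total, tolerance = 1e-9)
})

test_that("extracted contact times are integer multiples of the frame period", {
  sim <- simulate_landing_trial(cfg, 1, 6, seed = 31)
  ff <- extract_trial(sim$recording, "landing", cfg$body_weight_kg[1])
  mult <- ff$contact_time * 60
  expect_equal(mult, round(mult), tolerance = 1e-9)
})
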
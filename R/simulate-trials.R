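# Trial planners draw every stochastic quantity of a session's passes over the
# mat and return per-footfall ground truth ("plans"); the renderer turns one
# trial's plan into a sparse pressure recording. Planners are vectorized over
# the trials of a session; the single-trial simulators are their n = 1 case,
# so the rendered path and the footfall-level fast path share one stochastic
# model.

# --- walking -----------------------------------------------------------------

plan_walking_session <- function(cfg, cat, time_h, treatment, operated_foot,
                                 n = 1, keep_curves = TRUE) {
  fr <- cfg$frame_rate_hz
  bw <- cfg$body_weight_kg[cat]
  lam <- lameness_at(cfg, treatment, time_h)
  target <- cfg$target_walk_velocity_mps
  stride <- cfg$stride_length_m
  mat_len <- cfg$mat_size_m[1]
  margin <- 0.12
  n_strides <- floor((mat_len - 2 * margin) / stride)
  if (n_strides < 2) {
    abort("mat too short for >= 2 strides at this stride length",
      class = "psw_input_error"
    )
  }
  # per-trial draws
  v <- exp(rnorm(n, log(target), cfg$velocity_sd / target))
  stride_t <- stride / v
  contact <- cfg$walk_contact_duty * stride_t
  x0 <- margin + runif(n, 0, stride * 0.5)
  y_mid <- cfg$mat_size_m[2] / 2 * 100 + rnorm(n, 0, 1.5)
  track_half <- 4 # cm lateral offset of each side from the midline
  t0 <- 0.3

  # limb phases of a lateral-sequence walk; hind paws land on the ipsilateral
  # fore print (track-up), so LH_k reuses LF_k's position and RH_k reuses
  # RF_(k-1)'s.
  ks <- 0:(n_strides - 1)
  limb1 <- rep(c("LF", "RF", "LH", "RH"), each = n_strides)
  phase1 <- rep(c(0, 0.5, 0.75, 0.25), each = n_strides)
  korder <- rep(ks, 4)
  xoff1 <- c(ks, ks + 0.5, ks, ks - 0.5) * stride
  m <- length(limb1) # footfalls per trial before edge filtering
  trial <- rep(seq_len(n), each = m)
  limb <- rep(limb1, n)
  side <- substr(limb, 1, 1)
  plan <- fast_tb(
    trial = trial,
    limb = limb,
    side = side,
    position = ifelse(substr(limb, 2, 2) == "F", "fore", "hind"),
    t_s = t0 + (rep(korder, n) + rep(phase1, n)) * stride_t[trial],
    x_m = x0[trial] + rep(xoff1, n) + rnorm(n * m, 0, 0.005),
    y_cm = y_mid[trial] + ifelse(side == "L", track_half, -track_half) +
      rnorm(n * m, 0, 0.3)
  )
  plan <- plan[plan$x_m > 0.05 & plan$x_m < mat_len - 0.05, ]
  if (any(tapply(plan$limb == "LF", plan$trial, sum) < 2)) {
    abort("mat too short for >= 2 strides", class = "psw_input_error")
  }

  base_peak <- ifelse(plan$position == "fore", cfg$walk_fore_pvf, cfg$walk_hind_pvf)
  op_limb <- paste0(operated_foot, "F")
  scale <- ifelse(plan$limb == op_limb, lam, 1)
  peak <- pmax(base_peak * scale * (1 + rnorm(nrow(plan), 0, cfg$peak_cv)), 1)

  finish_plan(plan, peak, contact[plan$trial], fr,
    cat = cat, bw = bw, time_h = time_h, treatment = treatment,
    operated_foot = operated_foot, trial_type = "walking",
    velocity_mps = v, n_trials = n, keep_curves = keep_curves
  )
}

# --- landing -----------------------------------------------------------------

plan_landing_session <- function(cfg, cat, time_h, treatment, operated_foot,
                                 n = 1, keep_curves = TRUE) {
  fr <- cfg$frame_rate_hz
  bw <- cfg$body_weight_kg[cat]
  if (cfg$jump_height_m <= 0) {
    abort("jump_height_m must be > 0", class = "psw_input_error")
  }
  lam <- lameness_at(cfg, treatment, time_h)
  op_limb <- paste0(operated_foot, "F")
  track_half <- 4

  # per-trial draws (length n)
  y_mid <- cfg$mat_size_m[2] / 2 * 100 + rnorm(n, 0, 1.5)
  x_land <- 0.5 + rnorm(n, 0, 0.05)
  t0_frame <- round((0.5 + runif(n, 0, 0.1)) * fr)
  p_stagger <- min(1, cfg$stagger_prob_baseline + cfg$stagger_gain * (1 - lam))
  staggered <- runif(n) < p_stagger
  stagger_frames <- ifelse(staggered, 1L + (runif(n) < 0.3), 0L)
  # the operated limb loads later when lame; at baseline the sign is random
  op_later <- if (lam < 1) rep(TRUE, n) else runif(n) < 0.5
  tf1h1 <- cfg$tf1h1_baseline_s + cfg$tf1h1_gain_s * (1 - lam) +
    rnorm(n, 0, 0.015)
  hind_frame <- pmax(round(tf1h1 * fr), 1L) + stagger_frames
  hind_extra <- (runif(n) < 0.5) * 1L
  h_scale <- sqrt(cfg$jump_height_m / 0.7)
  contact_no <- cfg$land_fore_contact_s * (1 + rnorm(n, 0, 0.05))
  contact_op <- cfg$land_fore_contact_s * (1 + 0.35 * (1 - lam)) *
    (1 + rnorm(n, 0, 0.05))
  peak_fore <- cfg$land_fore_pvf * h_scale *
    matrix(1 + rnorm(2 * n, 0, cfg$peak_cv), n, 2) # cols: LF, RF
  peak_hind <- cfg$land_hind_pvf *
    matrix(1 + rnorm(2 * n, 0, cfg$peak_cv), n, 2) # cols: LH, RH
  x_jit <- matrix(rnorm(4 * n, 0, 0.01), n, 4)
  y_jit <- matrix(rnorm(4 * n, 0, 0.3), n, 4)

  op_off <- ifelse(op_later, stagger_frames, 0L)
  no_off <- ifelse(op_later, 0L, stagger_frames)
  lf_off <- if (op_limb == "LF") op_off else no_off
  rf_off <- if (op_limb == "RF") op_off else no_off

  # footfall-level vectors, trial-major order LF, RF, LH, RH
  limbs <- c("LF", "RF", "LH", "RH")
  plan <- fast_tb(
    trial = rep(seq_len(n), each = 4),
    limb = rep(limbs, n),
    position = rep(c("fore", "fore", "hind", "hind"), n),
    side = rep(c("L", "R", "L", "R"), n),
    frame0 = as.integer(t(cbind(
      t0_frame + lf_off, t0_frame + rf_off,
      t0_frame + hind_frame, t0_frame + hind_frame + hind_extra
    ))),
    x_m = as.vector(t(cbind(
      x_land + x_jit[, 1], x_land + x_jit[, 2],
      x_land - 0.18 + x_jit[, 3], x_land - 0.18 + x_jit[, 4]
    ))),
    y_cm = as.vector(t(cbind(
      y_mid + track_half + y_jit[, 1], y_mid - track_half + y_jit[, 2],
      y_mid + track_half + y_jit[, 3], y_mid - track_half + y_jit[, 4]
    )))
  )
  peak <- as.vector(t(cbind(peak_fore, peak_hind)))
  op_scale <- if (op_limb == "LF") c(lam, 1, 1, 1) else c(1, lam, 1, 1)
  peak <- peak * rep(op_scale, n)
  contact_lf <- if (op_limb == "LF") contact_op else contact_no
  contact_rf <- if (op_limb == "RF") contact_op else contact_no
  contact <- as.vector(t(cbind(
    contact_lf, contact_rf,
    rep(cfg$land_hind_contact_s, n), rep(cfg$land_hind_contact_s, n)
  )))

  out <- finish_plan(plan, pmax(peak, 1), contact, fr,
    cat = cat, bw = bw, time_h = time_h, treatment = treatment,
    operated_foot = operated_foot, trial_type = "landing",
    velocity_mps = rep(NA_real_, n), n_trials = n, keep_curves = keep_curves
  )
  truth <- fast_tb(
    trial = seq_len(n),
    tf1f2 = (op_off - no_off) / fr,
    measurable = stagger_frames > 0,
    stagger_planted = staggered,
    tf1h1 = (hind_frame - pmin(lf_off, rf_off)) / fr
  )
  attr(out, "meta") <- dplyr::left_join(attr(out, "meta"), truth, by = "trial")
  out
}

# Shared tail of both planners: frame-align strikes, sample force curves and
# record ground-truth kinetics (%BW units). With keep_curves = FALSE the
# sampled PVF/VI of the half-sine are computed in closed form
# (max_k sin(pi (k + 1/2) / n) and sum_k sin(pi (k + 1/2) / n) =
# 1 / sin(pi / 2n)) instead of materializing per-frame curves.
finish_plan <- function(plan, peak_pct, contact_s, fr, cat, bw, time_h,
                        treatment, operated_foot, trial_type, velocity_mps,
                        n_trials = 1, keep_curves = TRUE) {
  n_frames_contact <- pmax(2L, round(contact_s * fr))
  strike_frame <- if ("frame0" %in% names(plan)) {
    plan$frame0
  } else {
    round(plan$t_s * fr)
  }
  if (keep_curves) {
    curves <- purrr::map2(
      peak_pct, n_frames_contact,
      ~ generate_force_curve(.x, .y / fr, fr, "half_sine")
    )
    pvf <- purrr::map_dbl(curves, ~ attr(.x, "pvf"))
    vi <- purrr::map_dbl(curves, ~ attr(.x, "vi"))
  } else {
    nn <- n_frames_contact
    pvf <- peak_pct * ifelse(nn %% 2 == 1, 1, cos(pi / (2 * nn)))
    vi <- peak_pct / (fr * sin(pi / (2 * nn)))
  }
  role <- ifelse(plan$limb == paste0(operated_foot, "F"), "operated",
    ifelse(plan$position == "fore", "non_operated", "hind")
  )
  ff <- fast_tb(
    trial = plan$trial,
    limb = plan$limb, side = plan$side, position = plan$position, role = role,
    strike_time = strike_frame / fr,
    contact_time = n_frames_contact / fr,
    lift_time = (strike_frame + n_frames_contact) / fr,
    strike_frame = as.integer(strike_frame),
    n_frames = n_frames_contact,
    pvf_pct_bw = pvf,
    vi_pct_bw_s = vi,
    x_cm = plan$x_m * 100,
    y_cm = plan$y_cm
  )
  if (keep_curves) ff$curve <- curves
  meta <- fast_tb(
    trial = seq_len(n_trials),
    cat = cat, time_h = time_h, treatment = treatment,
    operated_foot = operated_foot, trial_type = trial_type,
    body_weight_kg = bw, velocity_mps = velocity_mps
  )
  structure(list(), footfalls = ff, meta = meta, class = "psw_trial_plan")
}

plan_footfalls <- function(plan) attr(plan, "footfalls")
plan_meta <- function(plan) attr(plan, "meta")

# --- rendering ---------------------------------------------------------------

# Render one trial's footfall plan onto the sensel grid as one
# truncated-Gaussian pressure blob per paw (~3 x 3 cm footprint), with the
# blob weights renormalized so every frame's summed force equals the planned
# curve value.
render_footfalls <- function(ff, body_weight_kg, cfg) {
  fr <- cfg$frame_rate_hz
  pitch_cm <- 1 / sqrt(cfg$sensel_per_cm2)
  n_rows <- round(cfg$mat_size_m[2] * 100 / pitch_cm)
  n_cols <- round(cfg$mat_size_m[1] * 100 / pitch_cm)
  bw_n <- body_weight_kg * .G

  half <- 4L # blob window half-width in sensels
  off <- expand.grid(dr = -half:half, dc = -half:half)
  sigma_px <- 0.75 / pitch_cm # sigma 0.75 cm -> ~3 cm footprint
  w <- exp(-(off$dr^2 + off$dc^2) / (2 * sigma_px^2))
  w <- w / sum(w)

  rows <- purrr::pmap_dfr(
    list(ff$curve, ff$x_cm, ff$y_cm, ff$strike_frame),
    function(curve, x_cm, y_cm, f0) {
      r0 <- pmin(pmax(round(y_cm / pitch_cm + 0.5), half + 1L), n_rows - half)
      c0 <- pmin(pmax(round(x_cm / pitch_cm + 0.5), half + 1L), n_cols - half)
      npx <- nrow(off)
      nfr <- nrow(curve)
      fast_tb(
        frame = rep(f0 + curve$frame, each = npx),
        row = rep.int(as.integer(r0 + off$dr), nfr),
        col = rep.int(as.integer(c0 + off$dc), nfr),
        force = rep(curve$force / 100 * bw_n, each = npx) * rep.int(w, nfr)
      )
    }
  )
  if (cfg$noise_sd > 0) {
    # load-proportional sensel noise: mean-one log-normal, so summed blob
    # forces stay unbiased and no sensel ever reads negative
    rows$force <- rows$force *
      exp(rnorm(nrow(rows), -cfg$noise_sd^2 / 2, cfg$noise_sd))
  }
  rows <- rows |>
    dplyr::group_by(.data$frame, .data$row, .data$col) |>
    dplyr::summarise(force = sum(.data$force), .groups = "drop") |>
    dplyr::filter(.data$force > 0)
  n_frames <- max(rows$frame) + 1L + round(0.2 * fr)
  psw_recording(rows,
    n_frames = n_frames, n_rows = n_rows, n_cols = n_cols,
    frame_rate_hz = fr, sensel_pitch_cm = pitch_cm,
    calibration_range_psi = cfg$calibration_range_psi
  )
}

gt_from_plan <- function(plan) {
  ff <- plan_footfalls(plan)
  keep <- intersect(
    c(
      "trial", "limb", "side", "position", "role", "strike_time",
      "contact_time", "pvf_pct_bw", "vi_pct_bw_s", "x_cm", "y_cm", "curve",
      "strike_frame"
    ),
    names(ff)
  )
  ff[, keep]
}

#' Simulate one walking pass over the walkway
#'
#' Draws a trial velocity (log-normal around the target, so some trials fall
#' outside the QC window), lays out a lateral-sequence walking gait with
#' hind paws landing on the ipsilateral fore prints, scales the operated
#' forelimb's force by the configured lameness factor, and renders each
#' footfall as a Gaussian pressure blob on the sensel grid.
#'
#' @param config A [sim_config()].
#' @param cat Cat index (1-based).
#' @param timepoint Session time in hours (<= 0 means baseline, no lameness).
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param period Study period (1 or 2), used to look up treatment and
#'   operated foot in the allocation; ignored when `treatment` and
#'   `operated_foot` are given explicitly.
#' @param treatment,operated_foot Optional explicit overrides.
#' @param render If `FALSE`, skip rendering and return only the ground truth.
#' @param keep_curves Attach per-frame force curves to the ground truth
#'   (forced on when rendering); with `FALSE` the sampled PVF/VI are computed
#'   in closed form, which is what [simulate_study()] uses for speed.
#' @return A list with elements `recording` (a [psw_recording()], or `NULL`
#'   when `render = FALSE`), `ground_truth` (per-footfall tibble: limb, role,
#'   strike/contact times, intended PVF and VI in %BW units), and `meta`
#'   (one-row tibble with body weight and the drawn velocity).
#' @export
simulate_walking_trial <- function(config, cat, timepoint, seed = NULL,
                                   period = 1, treatment = NULL,
                                   operated_foot = NULL, render = TRUE,
                                   keep_curves = TRUE) {
  arm <- resolve_arm(config, cat, period, treatment, operated_foot)
  with_seed(seed, {
    plan <- plan_walking_session(config, cat, timepoint, arm$treatment,
      arm$operated_foot,
      n = 1, keep_curves = keep_curves || render
    )
    ff <- plan_footfalls(plan)
    rec <- if (render) {
      render_footfalls(ff, config$body_weight_kg[cat], config)
    } else {
      NULL
    }
    list(recording = rec, ground_truth = gt_from_plan(plan), meta = plan_meta(plan))
  })
}

#' Simulate one jump-landing trial
#'
#' The cat lands forelimbs-first from the configured perch height. The
#' inter-forelimb stagger is measurable (>= 1 frame) with a probability that
#' grows with lameness, the operated limb loading later when lame; the
#' fore-to-hind delay likewise lengthens with lameness. Forelimb peaks are
#' scaled so baseline landing PVF is of the order of 185-190 %BW.
#'
#' @inheritParams simulate_walking_trial
#' @return As [simulate_walking_trial()], with `meta` additionally carrying
#'   the planted stagger truth (`tf1f2`, `measurable`, `stagger_planted`,
#'   `tf1h1`).
#' @export
simulate_landing_trial <- function(config, cat, timepoint, seed = NULL,
                                   period = 1, treatment = NULL,
                                   operated_foot = NULL, render = TRUE,
                                   keep_curves = TRUE) {
  if (config$jump_height_m <= 0) {
    abort("jump_height_m must be > 0", class = "psw_input_error")
  }
  arm <- resolve_arm(config, cat, period, treatment, operated_foot)
  with_seed(seed, {
    plan <- plan_landing_session(config, cat, timepoint, arm$treatment,
      arm$operated_foot,
      n = 1, keep_curves = keep_curves || render
    )
    ff <- plan_footfalls(plan)
    rec <- if (render) {
      render_footfalls(ff, config$body_weight_kg[cat], config)
    } else {
      NULL
    }
    list(recording = rec, ground_truth = gt_from_plan(plan), meta = plan_meta(plan))
  })
}

resolve_arm <- function(config, cat, period, treatment, operated_foot) {
  if (is.null(treatment) || is.null(operated_foot)) {
    row <- dplyr::filter(config$allocation, .data$cat == !!cat, .data$period == !!period)
    if (nrow(row) != 1) {
      abort("cat/period not found in allocation", class = "psw_input_error")
    }
    treatment <- treatment %||% row$treatment
    operated_foot <- operated_foot %||% row$operated_foot
  }
  list(treatment = treatment, operated_foot = operated_foot)
}
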
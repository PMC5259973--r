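#' Crossover allocation table for a two-period unilateral onychectomy study
#'
#' The default allocation used by the simulator: four cats in two sequence
#' groups, each cat receiving control (saline) in one period and the
#' extended-release buprenorphine arm (`er_bup`) in the other, with the
#' operated forelimb alternating between periods.
#'
#' @param n_cats Number of cats. The canonical design uses 4; other even
#'   numbers extend the same alternating pattern.
#' @return A tibble with columns `cat`, `period` (1 or 2), `treatment`
#'   (`"control"` or `"er_bup"`), and `operated_foot` (`"L"` or `"R"`).
#' @examples
#' default_allocation()
#' @export
default_allocation <- function(n_cats = 4) {
  stopifnot(n_cats >= 2, n_cats %% 2 == 0)
  # sequence group 1: control first; group 2: er_bup first
  # feet alternate L,R within a sequence group and switch between periods
  purrr::map_dfr(seq_len(n_cats), function(i) {
    group <- if (i <= n_cats / 2) 1L else 2L
    first_trt <- if (group == 1L) "control" else "er_bup"
    second_trt <- if (group == 1L) "er_bup" else "control"
    # cats 1,3: L first; cats 2,4: R first (matching the canonical schedule)
    feet <- if (i %% 2 == 1) c("L", "R") else c("R", "L")
    if (group == 2L) feet <- rev(feet)
    tibble(
      cat = i,
      period = c(1L, 2L),
      treatment = c(first_trt, second_trt),
      operated_foot = feet
    )
  })
}

#' Simulation configuration
#'
#' Bundles every tunable parameter of the synthetic pressure-sensitive-walkway
#' (PSW) study generator. Defaults reproduce the structure of a four-cat,
#' two-period crossover: a 2.4 m x 0.5 m mat with 4 sensels/cm^2 sampled at
#' 60 Hz over a 50 psi calibrated range, walking trials targeted at 0.6 m/s,
#' landings from a 0.7 m perch, six post-operative kinetic sessions
#' (6, 24, 30, 48, 54, 72 h), two baseline sessions (-48, -24 h), and ordinal
#' 0-5 pain scores observed at 3, 6, 12, 24, 30, 36, 48, 54, 60, 72 h.
#'
#' @param n_cats Number of cats (default 4).
#' @param body_weight_kg Per-cat body mass in kg; recycled or length `n_cats`.
#' @param allocation Crossover allocation tibble (see [default_allocation()]).
#' @param lameness_factor Named list with elements `control` and `er_bup`,
#'   each a named numeric vector over post-op times (hours) of multipliers in
#'   \[0, 1\] applied to the operated forelimb's force (1 = no lameness).
#' @param target_walk_velocity_mps Target walking velocity (m/s).
#' @param velocity_sd Standard deviation (m/s scale) of the log-normal
#'   trial-to-trial velocity draw; the default deliberately produces some
#'   trials outside the accepted velocity window so QC has work to do.
#' @param jump_height_m Perch height for landing trials (m); must be > 0.
#' @param frame_rate_hz Acquisition rate (Hz).
#' @param sensel_per_cm2 Sensor density; pitch is `1/sqrt(sensel_per_cm2)` cm.
#' @param mat_size_m Length-2 numeric, mat length x width in metres.
#' @param calibration_range_psi Calibrated sensor range (psi), metadata only.
#' @param noise_sd Per-sensel multiplicative (log-normal, mean-one) force
#'   noise SD on the log scale: 0.05 means roughly 5% noise on each loaded
#'   sensel. Proportional noise reflects how piezoresistive sensels behave
#'   and keeps summed blob forces unbiased; unloaded sensels read zero.
#' @param walk_fore_pvf,walk_hind_pvf Walking peak vertical force (%BW) for
#'   fore/hind limbs before lameness scaling.
#' @param land_fore_pvf,land_hind_pvf Landing peak vertical force (%BW);
#'   the forelimb default gives baseline landing PVF near 185-190 %BW.
#' @param walk_contact_duty Fraction of the stride the paw is on the ground.
#' @param land_fore_contact_s,land_hind_contact_s Landing contact times (s).
#' @param peak_cv Trial-to-trial coefficient of variation of peak forces.
#' @param stride_length_m Walking stride length (m).
#' @param stagger_prob_baseline Probability that a baseline landing has a
#'   measurable (>= 1 frame) inter-forelimb stagger.
#' @param stagger_gain Added stagger probability per unit (1 - lameness).
#' @param tf1h1_baseline_s Baseline fore-to-hind landing delay (s).
#' @param tf1h1_gain_s Added fore-to-hind delay per unit (1 - lameness).
#' @param pain_amplitude Named vector, latent post-surgical pain amplitude per
#'   arm (ordinal-score units at time 0+).
#' @param pain_tau_h Named vector, exponential decay time constant (h) per arm.
#' @param pain_noise Half-width of the bounded uniform observation noise on
#'   the latent pain intensity; with the default amplitudes the rounded score
#'   can never exceed 2, matching the study's observed ceiling.
#' @param n_walking_trials,n_landing_trials Trials collected per session.
#' @param kinetic_times_h Post-op kinetic session times (h).
#' @param pain_times_h Post-op pain observation times (h).
#' @param baseline_times_h Baseline session times (negative hours).
#' @param rng_seed Default seed used when a `seed` argument is not supplied.
#' @return A validated list of class `psw_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$frame_rate_hz
#' @export
sim_config <- function(n_cats = 4,
                       body_weight_kg = c(2.4, 2.8, 3.2, 2.2),
                       allocation = default_allocation(n_cats),
                       lameness_factor = default_lameness(),
                       target_walk_velocity_mps = 0.6,
                       velocity_sd = 0.15,
                       jump_height_m = 0.7,
                       frame_rate_hz = 60,
                       sensel_per_cm2 = 4,
                       mat_size_m = c(2.4, 0.5),
                       calibration_range_psi = 50,
                       noise_sd = 0.05,
                       walk_fore_pvf = 55,
                       walk_hind_pvf = 45,
                       land_fore_pvf = 187,
                       land_hind_pvf = 90,
                       walk_contact_duty = 0.55,
                       land_fore_contact_s = 0.125,
                       land_hind_contact_s = 0.12,
                       peak_cv = 0.08,
                       stride_length_m = 0.40,
                       stagger_prob_baseline = 0.24,
                       stagger_gain = 0.5,
                       tf1h1_baseline_s = 0.11,
                       tf1h1_gain_s = 0.06,
                       pain_amplitude = c(control = 2.0, er_bup = 0.9),
                       pain_tau_h = c(control = 40, er_bup = 18),
                       pain_noise = 0.4,
                       n_walking_trials = 10,
                       n_landing_trials = 10,
                       kinetic_times_h = c(6, 24, 30, 48, 54, 72),
                       pain_times_h = c(3, 6, 12, 24, 30, 36, 48, 54, 60, 72),
                       baseline_times_h = c(-48, -24),
                       rng_seed = 1L) {
  cfg <- list(
    n_cats = as.integer(n_cats),
    body_weight_kg = rep_len(body_weight_kg, n_cats),
    allocation = as_tibble(allocation),
    lameness_factor = lameness_factor,
    target_walk_velocity_mps = target_walk_velocity_mps,
    velocity_sd = velocity_sd,
    jump_height_m = jump_height_m,
    frame_rate_hz = frame_rate_hz,
    sensel_per_cm2 = sensel_per_cm2,
    mat_size_m = mat_size_m,
    calibration_range_psi = calibration_range_psi,
    noise_sd = noise_sd,
    walk_fore_pvf = walk_fore_pvf,
    walk_hind_pvf = walk_hind_pvf,
    land_fore_pvf = land_fore_pvf,
    land_hind_pvf = land_hind_pvf,
    walk_contact_duty = walk_contact_duty,
    land_fore_contact_s = land_fore_contact_s,
    land_hind_contact_s = land_hind_contact_s,
    peak_cv = peak_cv,
    stride_length_m = stride_length_m,
    stagger_prob_baseline = stagger_prob_baseline,
    stagger_gain = stagger_gain,
    tf1h1_baseline_s = tf1h1_baseline_s,
    tf1h1_gain_s = tf1h1_gain_s,
    pain_amplitude = pain_amplitude,
    pain_tau_h = pain_tau_h,
    pain_noise = pain_noise,
    n_walking_trials = as.integer(n_walking_trials),
    n_landing_trials = as.integer(n_landing_trials),
    kinetic_times_h = kinetic_times_h,
    pain_times_h = pain_times_h,
    baseline_times_h = baseline_times_h,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "psw_config"
  validate_config(cfg)
}

#' Default operated-limb lameness profile
#'
#' Multipliers in \[0, 1\] applied to the operated forelimb's vertical force at
#' each post-operative kinetic time. The control profile plants a substantial
#' asymmetry (operated limb near half loading) with partial recovery; the
#' treated arm is uniformly less lame.
#'
#' @param times_h Post-op kinetic times (hours).
#' @return Named list with numeric vectors `control` and `er_bup`.
#' @export
default_lameness <- function(times_h = c(6, 24, 30, 48, 54, 72)) {
  list(
    control = setNames(c(0.55, 0.50, 0.57, 0.55, 0.45, 0.52), times_h),
    er_bup  = setNames(c(0.75, 0.66, 0.70, 0.64, 0.67, 0.66), times_h)
  )
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "psw_config"))
  if (cfg$n_cats < 1) abort("n_cats must be >= 1", class = "psw_config_error")
  if (any(cfg$body_weight_kg <= 0)) {
    abort("body_weight_kg must be positive", class = "psw_config_error")
  }
  if (cfg$frame_rate_hz <= 0) abort("frame_rate_hz must be > 0", class = "psw_config_error")
  if (cfg$sensel_per_cm2 <= 0) abort("sensel_per_cm2 must be > 0", class = "psw_config_error")
  if (cfg$jump_height_m <= 0) abort("jump_height_m must be > 0", class = "psw_config_error")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0", class = "psw_config_error")
  lam <- unlist(cfg$lameness_factor)
  if (any(lam < 0 | lam > 1)) {
    abort("lameness_factor values must lie in [0, 1]", class = "psw_config_error")
  }
  al <- cfg$allocation
  need <- c("cat", "period", "treatment", "operated_foot")
  if (!all(need %in% names(al))) {
    abort("allocation must have columns cat, period, treatment, operated_foot",
      class = "psw_config_error"
    )
  }
  cover <- dplyr::count(al, .data$cat, .data$period)
  if (nrow(cover) != cfg$n_cats * 2 || any(cover$n != 1)) {
    abort("allocation must cover every cat x period exactly once",
      class = "psw_config_error"
    )
  }
  if (!all(al$treatment %in% c("control", "er_bup"))) {
    abort("allocation treatments must be 'control' or 'er_bup'", class = "psw_config_error")
  }
  if (!all(al$operated_foot %in% c("L", "R"))) {
    abort("allocation operated_foot must be 'L' or 'R'", class = "psw_config_error")
  }
  both <- dplyr::summarise(dplyr::group_by(al, .data$cat),
    ok = dplyr::n_distinct(.data$treatment) == 2 &&
      dplyr::n_distinct(.data$operated_foot) == 2
  )
  if (!all(both$ok)) {
    abort("each cat must receive both treatments and have both feet operated",
      class = "psw_config_error"
    )
  }
  cfg
}

# lameness multiplier for one arm at one post-op time; baselines are 1
lameness_at <- function(cfg, treatment, time_h) {
  if (time_h <= 0) {
    return(1)
  }
  prof <- cfg$lameness_factor[[treatment]]
  idx <- match(as.character(time_h), names(prof))
  if (is.na(idx)) {
    # interpolate for off-schedule queries
    tt <- as.numeric(names(prof))
    return(approx(tt, prof, xout = time_h, rule = 2)$y)
  }
  unname(prof[idx])
}

#' Read and write pipeline/simulation configuration as YAML
#'
#' Round-trips the scalar and vector fields of a [sim_config()] object through
#' a YAML file. The allocation table is stored as a list of records.
#'
#' @param cfg A `psw_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `psw_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "psw_config"))
  x <- unclass(cfg)
  x$allocation <- purrr::pmap(cfg$allocation, list)
  # named vectors must become YAML maps, not sequences
  x$lameness_factor <- purrr::map(x$lameness_factor, as.list)
  x$pain_amplitude <- as.list(x$pain_amplitude)
  x$pain_tau_h <- as.list(x$pain_tau_h)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  alloc <- purrr::map_dfr(x$allocation, ~ tibble(
    cat = as.integer(.x$cat),
    period = as.integer(.x$period),
    treatment = as.character(.x$treatment),
    operated_foot = as.character(.x$operated_foot)
  ))
  x$allocation <- NULL
  lam <- x$lameness_factor
  x$lameness_factor <- NULL
  args <- x
  args$allocation <- alloc
  if (!is.null(lam)) {
    args$lameness_factor <- purrr::map(lam, ~ unlist(.x))
  }
  for (nm in c("pain_amplitude", "pain_tau_h")) {
    if (is.list(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(sim_config, args)
}

#' @export
print.psw_config <- function(x, ...) {
  cat("<psw_config>\n")
  cat(sprintf(
    "  %d cats, %.1f x %.1f m mat, %g sensels/cm^2, %g Hz\n",
    x$n_cats, x$mat_size_m[1], x$mat_size_m[2], x$sensel_per_cm2, x$frame_rate_hz
  ))
  cat(sprintf(
    "  walk target %g m/s; jump height %g m; %d+%d trials/session\n",
    x$target_walk_velocity_mps, x$jump_height_m,
    x$n_walking_trials, x$n_landing_trials
  ))
  invisible(x)
}
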
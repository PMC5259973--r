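# shared fixtures: configurations and small constructors used across tests

quiet_baseline_adjust <- function(...) {
  withCallingHandlers(
    baseline_adjust(...),
    psw_missing_baseline = function(w) invokeRestart("muffleWarning")
  )
}

quiet_fit_mixed <- function(...) {
  withCallingHandlers(
    fit_kinetic_mixed_model(...),
    psw_covariance_fallback = function(w) invokeRestart("muffleWarning")
  )
}

# a config whose two arms are equally lame: the null crossover
null_config <- function(...) {
  lam <- default_lameness()
  lam$er_bup <- lam$control
  sim_config(lameness_factor = lam, ...)
}

# constant lameness factor in both arms at all post-op times
flat_lameness <- function(value) {
  times <- c(6, 24, 30, 48, 54, 72)
  list(
    control = setNames(rep(value, 6), times),
    er_bup = setNames(rep(value, 6), times)
  )
}

# minimal sparse recording with one Gaussian-ish blob active over given frames
blob_recording <- function(frames_active, row0 = 20, col0 = 40, force = 5,
                           n_rows = 100, n_cols = 480, frame_rate = 60) {
  off <- expand.grid(dr = -2:2, dc = -2:2)
  w <- exp(-(off$dr^2 + off$dc^2) / 2)
  w <- w / sum(w)
  rows <- do.call(rbind, lapply(frames_active, function(f) {
    data.frame(
      frame = f, row = row0 + off$dr, col = col0 + off$dc,
      force = force * w
    )
  }))
  psw_recording(rows,
    n_frames = max(frames_active) + 5L, n_rows = n_rows, n_cols = n_cols,
    frame_rate_hz = frame_rate, sensel_pitch_cm = 0.5
  )
}

# brute-force one-sided exact signed-rank p, written independently of the
# package implementation (bitmask enumeration instead of expand.grid)
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(1)
  }
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  total <- 2^n
  ws <- numeric(total)
  for (mask in 0:(total - 1)) {
    w <- 0
    for (j in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0) w <- w + r[j]
    }
    ws[mask + 1] <- w
  }
  if (w_obs >= n * (n + 1) / 4) mean(ws >= w_obs - 1e-9) else mean(ws <= w_obs + 1e-9)
}
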
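#' Simulate an ordinal pain-score series for one cat and period
#'
#' Scores arise from a latent post-surgical intensity that decays
#' exponentially from the moment of surgery, plus bounded uniform observation
#' noise, rounded and clamped to the ordinal 0-5 scale. Baseline sessions
#' (negative hours) have zero latent intensity. The treated arm has a lower
#' amplitude and a shorter decay constant, so it stochastically lowers scores
#' and shortens the time back to baseline. Under the default amplitudes
#' (control 2.0, treated 0.9) and noise half-width 0.4 the rounded score can
#' never exceed 2.
#'
#' @param config A [sim_config()].
#' @param cat Cat index.
#' @param period Study period (1 or 2); the treatment arm is looked up in the
#'   allocation.
#' @param seed Integer seed.
#' @param treatment Optional explicit arm, bypassing the allocation.
#' @return Tibble with one row per observation: `cat`, `period`, `treatment`,
#'   `time_h` (two baseline sessions then 3-72 h), `score` (integer 0-5),
#'   `is_baseline`, and `rescue` (TRUE when the score reaches 4, the rescue
#'   analgesia trigger).
#' @export
simulate_pain_scores <- function(config, cat, period, seed = NULL,
                                 treatment = NULL) {
  if (is.null(treatment)) {
    treatment <- resolve_arm(config, cat, period, NULL, "L")$treatment
  }
  amp <- unname(config$pain_amplitude[treatment])
  tau <- unname(config$pain_tau_h[treatment])
  times <- c(config$baseline_times_h, config$pain_times_h)
  with_seed(seed, {
    latent <- ifelse(times <= 0, 0, amp * exp(-times / tau))
    eps <- runif(length(times), -config$pain_noise, config$pain_noise)
    score <- pmin(pmax(round(latent + eps), 0), 5)
    tibble(
      cat = cat, period = period, treatment = treatment,
      time_h = times, score = as.integer(score),
      is_baseline = times <= 0,
      rescue = score >= 4
    )
  })
}
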
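cfg <- sim_config()

test_that("the ordinal repeated-measures fit returns coherent probabilities", {
  study <- simulate_study(cfg, seed = 60, trial_types = "landing")
  fit <- fit_ordinal_repeated(study$pain)
  expect_s3_class(fit, "psw_ordinal_fit")
  expect_setequal(
    fit$effects$term,
    c("treatment", "period", "time_d", "treatment:time_d", "period:time_d")
  )
  expect_true(all(fit$prob_baseline$prob >= 0 & fit$prob_baseline$prob <= 1))
  probs <- as.matrix(fit$category_probs[, as.character(fit$levels)])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-8)
  expect_equal(nrow(tidy(fit)), 5)
  expect_equal(glance(fit)$method, "marginal")
})

test_that("both estimation routes see a planted treatment effect", {
  study <- simulate_study(cfg, seed = 61, trial_types = "landing")
  m <- fit_ordinal_repeated(study$pain, method = "marginal")
  expect_lt(m$effects$p_value[m$effects$term == "treatment"], 0.05)
  g <- fit_ordinal_repeated(study$pain, method = "random_intercept")
  expect_lt(g$effects$p_value[g$effects$term == "treatment"], 0.05)
  # treated arm reaches a 0.5 probability of baseline earlier than control
  cr <- crossing_times(m)
  for (p in unique(cr$period)) {
    tc <- cr$crossing_h[cr$period == p & cr$treatment == "control"]
    te <- cr$crossing_h[cr$period == p & cr$treatment == "er_bup"]
    expect_true(is.na(tc) || is.na(te) || te < tc)
  }
})

test_that("degenerate pain data raises an explicit diagnostic", {
  study <- simulate_study(
    sim_config(pain_amplitude = c(control = 0, er_bup = 0), pain_noise = 0),
    seed = 62, trial_types = "landing"
  )
  expect_error(fit_ordinal_repeated(study$pain), class = "psw_fit_error")
  expect_error(
    fit_ordinal_repeated(study$pain[study$pain$cat == 1, ]),
    class = "psw_input_error"
  )
})

test_that("crossing times interpolate linearly and censor at the grid edges", {
  expect_equal(
    crossing_time(tibble::tibble(time_h = c(0, 24), prob = c(0.2, 0.8)))$crossing_h,
    12.0
  )
  high <- crossing_time(tibble::tibble(time_h = c(3, 24), prob = c(0.9, 0.95)))
  expect_true(is.na(high$crossing_h))
  expect_equal(high$label, "< 3")
  flat <- crossing_time(tibble::tibble(time_h = c(3, 72), prob = c(0.4, 0.4)))
  expect_equal(flat$label, "> 72")
  expect_error(
    crossing_time(tibble::tibble(time_h = 1, prob = 1.2)),
    class = "psw_input_error"
  )
})

test_that("equal-arm responses give a zero treatment contrast", {
  times <- c(6, 24, 30, 48, 54, 72)
  base <- tidyr::expand_grid(cat = 1:4, time_h = times)
  set.seed(3)
  base$value <- -40 + 5 * sin(base$time_h / 20) + rnorm(nrow(base), 0, 6)
  deltas <- dplyr::bind_rows(
    dplyr::mutate(base, treatment = "control", period = 1),
    dplyr::mutate(base, treatment = "er_bup", period = 2)
  )
  deltas$delta <- deltas$value
  deltas$response <- "si_pvf_mean"
  fit <- quiet_fit_mixed(deltas, covariance = "cs")
  expect_true(all(abs(fit$contrasts$estimate) < 1e-8))
  expect_gt(fit$treatment_p, 0.9)
})

test_that("mixed-model per-timepoint adjustment never shrinks a p-value", {
  study <- simulate_study(cfg, seed = 63, trial_types = "landing")
  sm <- summarize_study(study)
  deltas <- quiet_baseline_adjust(summaries_to_long(sm$summaries))
  fit <- quiet_fit_mixed(deltas[deltas$response == "si_pvf_mean", ], covariance = "cs")
  raw <- 2 * pt(-abs(fit$contrasts$estimate / fit$contrasts$se), fit$contrasts$df)
  expect_true(all(fit$contrasts$p_adj >= raw - 1e-12))
  expect_true(all(fit$contrasts$time_h %in% c(6, 24, 30, 48, 54, 72)))
})

test_that("a planted effect at two timepoints is localized there", {
  times <- c(6, 24, 30, 48, 54, 72)
  hits <- integer(length(times))
  names(hits) <- times
  set.seed(11)
  for (r in 1:15) {
    d <- tidyr::expand_grid(cat = 1:4, period = 1:2, time_h = times)
    d$treatment <- ifelse((d$cat <= 2) == (d$period == 1), "control", "er_bup")
    d$delta <- rnorm(nrow(d), -40, 4) +
      ifelse(d$treatment == "er_bup" & d$time_h %in% c(6, 54), 25, 0)
    d$response <- "si_pvf_mean"
    fit <- quiet_fit_mixed(d, covariance = "cs")
    sig <- fit$contrasts$time_h[fit$contrasts$p_adj < 0.05]
    hits[as.character(sig)] <- hits[as.character(sig)] + 1L
  }
  expect_true(all(hits[c("6", "54")] >= max(hits[c("24", "30", "48", "72")])))
  expect_gte(hits[["6"]], 10)
  expect_gte(hits[["54"]], 10)
})

test_that("Dunnett comparisons flag a large planted drop at every time", {
  times <- c(6, 24, 30, 48, 54, 72)
  set.seed(21)
  d <- tidyr::expand_grid(cat = 1:4, time_h = c(-48, -24, times))
  d$value <- 100 + rnorm(nrow(d), 0, 3) + ifelse(d$time_h > 0, -50, 0)
  dn <- dunnett_vs_baseline(d)
  expect_true(all(dn$significant))
  expect_setequal(dn$time_h, times)

  # and stays quiet when nothing changed
  d0 <- d
  d0$value <- 100 + rnorm(nrow(d0), 0, 3)
  dn0 <- dunnett_vs_baseline(d0)
  expect_false(any(dn0$significant))
})

test_that("chi-square contingency analysis uses the cross-product odds ratio", {
  out <- chisq_2x2(rbind(c(10, 10), c(20, 5)))
  expect_equal(out$odds_ratio, 0.25)
  expect_false(out$haldane)

  flat <- chisq_2x2(rbind(c(12, 8), c(12, 8)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$odds_ratio, 1)

  # study-scale stagger counts: post-op odds vs baseline odds ~ 3.0
  study_counts <- chisq_2x2(rbind(c(59, 61), c(19, 59)))
  expect_equal(study_counts$odds_ratio, 3481 / 1159, tolerance = 1e-12)
  expect_lt(study_counts$p_value, 0.05)

  zero <- chisq_2x2(rbind(c(0, 10), c(5, 5)))
  expect_true(zero$haldane)
  expect_gt(zero$odds_ratio, 0)

  expect_error(chisq_2x2(rbind(c(-1, 2), c(3, 4))), class = "psw_input_error")
  expect_error(chisq_2x2(matrix(1, 3, 2)), class = "psw_input_error")
})

test_that("null ordinal and mixed fits are not grossly miscalibrated", {
  # a light calibration probe; the acceptance suite runs the full 200-replicate
  # binomial check for the mixed model
  rej <- 0
  for (r in 1:30) {
    study <- simulate_study(null_config(), seed = 30000 + r, trial_types = "landing")
    sm <- summarize_study(study)
    deltas <- quiet_baseline_adjust(summaries_to_long(sm$summaries))
    fit <- quiet_fit_mixed(deltas[deltas$response == "si_pvf_mean", ],
      covariance = "cs"
    )
    rej <- rej + (fit$treatment_p < 0.05)
  }
  expect_lte(rej, 6) # P(X > 6 | Bin(30, 0.05)) < 0.001
})
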
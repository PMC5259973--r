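#' Forelimb symmetry index
#'
#' `SI = 100 * (x_op - x_no) / ((x_op + x_no) / 2)` for a gait variable
#' measured on the operated (`x_op`) and non-operated (`x_no`) forelimb.
#' SI is 0 under perfect symmetry and -200 when the operated limb bears no
#' load; negative values mean less weight on the operated limb. Vectorized.
#'
#' @param x_op,x_no Nonnegative gait-variable values (e.g. PVF in %BW).
#' @return Numeric SI on the percent scale, in \[-200, 200\]; `NA` (with a
#'   warning) where both inputs are zero.
#' @examples
#' symmetry_index(0, 180) # -200, non-weight bearing
#' symmetry_index(150, 150) # 0, perfect symmetry
#' @export
symmetry_index <- function(x_op, x_no) {
  if (any(x_op < 0, na.rm = TRUE) || any(x_no < 0, na.rm = TRUE)) {
    abort("gait variables must be nonnegative", class = "psw_input_error")
  }
  both_zero <- x_op + x_no == 0
  if (any(both_zero, na.rm = TRUE)) {
    warn("SI undefined where both limbs carry zero load; returning NA",
      class = "psw_si_undefined"
    )
  }
  out <- 100 * (x_op - x_no) / ((x_op + x_no) / 2)
  out[both_zero] <- NA_real_
  out
}

#' Landing timing metrics for one trial
#'
#' `tf1f2` is the strike time of the operated forelimb minus that of the
#' non-operated forelimb (positive = delayed loading of the operated limb);
#' it is "measurable" when at least one frame long. `tf1h1` is the first
#' hindlimb strike minus the first forelimb strike (`NA` without hindlimbs).
#'
#' @param footfalls Labeled footfall tibble with `role`, `position`,
#'   `strike_time`.
#' @param frame_rate_hz Acquisition rate defining the measurability
#'   granularity.
#' @return One-row tibble: `tf1f2`, `measurable`, `tf1h1`. Both forelimbs
#'   must be identified, otherwise `tf1f2` is `NA` and the trial should be
#'   excluded upstream.
#' @export
landing_timing <- function(footfalls, frame_rate_hz = 60) {
  op <- footfalls$strike_time[footfalls$role == "operated"]
  no <- footfalls$strike_time[footfalls$role == "non_operated"]
  hind <- footfalls$strike_time[footfalls$position == "hind"]
  fore <- footfalls$strike_time[footfalls$position == "fore"]
  tf1f2 <- if (length(op) == 1 && length(no) == 1) op - no else NA_real_
  tibble(
    tf1f2 = tf1f2,
    measurable = !is.na(tf1f2) & abs(tf1f2) >= 1 / frame_rate_hz - 1e-9,
    tf1h1 = if (length(hind) > 0 && length(fore) > 0) {
      min(hind) - min(fore)
    } else {
      NA_real_
    }
  )
}

#' Count trials with a measurable inter-forelimb strike difference
#'
#' @param measurable Logical vector (one element per trial), or a tibble with
#'   a `measurable` column.
#' @return One-row tibble with `n_measurable`, `n_trials`, `proportion`.
#' @examples
#' count_ntf1f2(c(rep(TRUE, 19), rep(FALSE, 59)))
#' @export
count_ntf1f2 <- function(measurable) {
  if (is.data.frame(measurable)) measurable <- measurable$measurable
  measurable <- measurable[!is.na(measurable)]
  tibble(
    n_measurable = sum(measurable),
    n_trials = length(measurable),
    proportion = if (length(measurable)) mean(measurable) else NA_real_
  )
}

# vectorized per-trial reduction over a long footfall table carrying a
# .trial_id column: op/no means, per-trial SI, landing timing
trial_kinetics_long <- function(ff_long, frame_rate_hz = 60) {
  stopifnot(all(c(".trial_id", "role", "pvf_pct_bw", "vi_pct_bw_s") %in% names(ff_long)))
  safe_mean <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  one <- function(x) if (length(x) == 1) x else NA_real_
  safe_min <- function(x) if (length(x) == 0) NA_real_ else min(x)
  out <- ff_long |>
    dplyr::group_by(.data$.trial_id) |>
    dplyr::summarise(
      op_pvf = safe_mean(.data$pvf_pct_bw[.data$role == "operated"]),
      no_pvf = safe_mean(.data$pvf_pct_bw[.data$role == "non_operated"]),
      op_vi = safe_mean(.data$vi_pct_bw_s[.data$role == "operated"]),
      no_vi = safe_mean(.data$vi_pct_bw_s[.data$role == "non_operated"]),
      tf1f2 = one(.data$strike_time[.data$role == "operated"]) -
        one(.data$strike_time[.data$role == "non_operated"]),
      tf1h1 = safe_min(.data$strike_time[.data$position == "hind"]) -
        safe_min(.data$strike_time[.data$position == "fore"]),
      .groups = "drop"
    )
  both <- !is.na(out$op_pvf) & !is.na(out$no_pvf)
  out$si_pvf <- ifelse(both, 100 * (out$op_pvf - out$no_pvf) /
    ((out$op_pvf + out$no_pvf) / 2), NA_real_)
  both_vi <- !is.na(out$op_vi) & !is.na(out$no_vi)
  out$si_vi <- ifelse(both_vi, 100 * (out$op_vi - out$no_vi) /
    ((out$op_vi + out$no_vi) / 2), NA_real_)
  out$measurable <- !is.na(out$tf1f2) & abs(out$tf1f2) >= 1 / frame_rate_hz - 1e-9
  out
}

# per-trial reduction: one row per trial with op/no means, per-trial SI and
# landing timing. Walking trials average PVF/VI per limb across strides.
trial_kinetics <- function(footfalls, frame_rate_hz = 60) {
  ff <- dplyr::mutate(footfalls, .trial_id = 1L)
  dplyr::select(trial_kinetics_long(ff, frame_rate_hz), -".trial_id")
}

#' Summarize the selected trials of one session
#'
#' Computes per-limb-role means, the session mean and SD of the per-trial
#' symmetry indices (SI is computed within each trial, then averaged - the
#' mean-of-ratios convention), aggregated landing timing metrics, and the
#' count of trials with measurable inter-forelimb stagger.
#'
#' @param trials A tibble of per-trial footfall tables: either a list-column
#'   `footfalls`, or an already-reduced tibble as returned by
#'   [trial_kinetics()] rows bound together.
#' @param frame_rate_hz Acquisition rate (for timing granularity).
#' @return One-row tibble (`KineticSummary`): means and SDs of op/no PVF and
#'   VI, `si_pvf_mean`/`sd`, `si_vi_mean`/`sd`, `tf1f2_mean`, `tf1h1_mean`,
#'   `ntf1f2`, `n_trials`.
#' @export
session_summary <- function(trials, frame_rate_hz = 60) {
  per_trial <- if ("footfalls" %in% names(trials)) {
    ff_long <- dplyr::bind_rows(trials$footfalls, .id = ".trial_id")
    if (nrow(ff_long) == 0) {
      tibble()
    } else {
      trial_kinetics_long(ff_long, frame_rate_hz)
    }
  } else {
    trials
  }
  if (nrow(per_trial) == 0) {
    per_trial <- tibble(
      op_pvf = NA_real_, no_pvf = NA_real_, op_vi = NA_real_, no_vi = NA_real_,
      si_pvf = NA_real_, si_vi = NA_real_, tf1f2 = NA_real_, measurable = NA,
      tf1h1 = NA_real_
    )[0, ]
  }
  m <- function(x) if (length(x) == 0 || all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  s <- function(x) if (sum(!is.na(x)) < 2) NA_real_ else sd(x, na.rm = TRUE)
  tibble(
    op_pvf_mean = m(per_trial$op_pvf), op_pvf_sd = s(per_trial$op_pvf),
    no_pvf_mean = m(per_trial$no_pvf), no_pvf_sd = s(per_trial$no_pvf),
    op_vi_mean = m(per_trial$op_vi), op_vi_sd = s(per_trial$op_vi),
    no_vi_mean = m(per_trial$no_vi), no_vi_sd = s(per_trial$no_vi),
    si_pvf_mean = m(per_trial$si_pvf), si_pvf_sd = s(per_trial$si_pvf),
    si_vi_mean = m(per_trial$si_vi), si_vi_sd = s(per_trial$si_vi),
    tf1f2_mean = m(per_trial$tf1f2), tf1f2_sd = s(per_trial$tf1f2),
    tf1h1_mean = m(per_trial$tf1h1), tf1h1_sd = s(per_trial$tf1h1),
    ntf1f2 = sum(per_trial$measurable, na.rm = TRUE),
    n_trials = nrow(per_trial)
  )
}

#' Subtract each cat-period's averaged baseline from its post-operative values
#'
#' Baselines from the two pre-operative sessions are averaged separately per
#' cat and period (each period has its own baseline pair), and the average is
#' subtracted from every post-operative value of the same response. When one
#' baseline session is missing the single available session is used and the
#' row is flagged.
#'
#' @param summaries Long tibble with columns `cat`, `period`, `treatment`,
#'   `trial_type`, `time_h`, `response`, `value`; baseline rows have
#'   `time_h <= 0`.
#' @return Tibble of post-operative rows with `baseline`, `delta`
#'   (`value - baseline`), `baseline_n`, and `baseline_incomplete` added.
#' @export
baseline_adjust <- function(summaries) {
  need <- c("cat", "period", "trial_type", "time_h", "response", "value")
  if (!all(need %in% names(summaries))) {
    abort(paste(
      "summaries must have columns",
      paste(need, collapse = ", ")
    ), class = "psw_input_error")
  }
  base <- summaries |>
    dplyr::filter(.data$time_h <= 0, !is.na(.data$value)) |>
    dplyr::group_by(.data$cat, .data$period, .data$trial_type, .data$response) |>
    dplyr::summarise(
      baseline = mean(.data$value), baseline_n = dplyr::n(),
      .groups = "drop"
    )
  if (any(base$baseline_n < 2)) {
    warn("one or more cat-periods have a single baseline session",
      class = "psw_missing_baseline"
    )
  }
  summaries |>
    dplyr::filter(.data$time_h > 0) |>
    dplyr::left_join(base, by = c("cat", "period", "trial_type", "response")) |>
    dplyr::mutate(
      delta = .data$value - .data$baseline,
      baseline_incomplete = is.na(.data$baseline_n) | .data$baseline_n < 2
    )
}

#' Washout readiness check
#'
#' A cat is ready for its second surgery when the current mean PVF lies
#' within the two-sided 95% t confidence interval of the pooled baseline
#' trial-level PVF measurements (inclusive at the interval boundary). Walking
#' and landing are assessed separately by calling this once per trial type.
#'
#' @param baseline_pvf Trial-level PVF values pooled over the two baseline
#'   sessions (>= 2 values).
#' @param current_pvf Trial-level PVF values of the current session.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `ready`, `current_mean`, `ci_lower`, `ci_upper`.
#' @export
washout_readiness <- function(baseline_pvf, current_pvf, conf = 0.95) {
  baseline_pvf <- baseline_pvf[!is.na(baseline_pvf)]
  current_pvf <- current_pvf[!is.na(current_pvf)]
  if (length(baseline_pvf) < 2 || length(current_pvf) < 1) {
    abort("need >= 2 baseline and >= 1 current PVF values", class = "psw_input_error")
  }
  n <- length(baseline_pvf)
  m <- mean(baseline_pvf)
  half <- qt(1 - (1 - conf) / 2, n - 1) * sd(baseline_pvf) / sqrt(n)
  cur <- mean(current_pvf)
  tibble(
    ready = cur >= m - half & cur <= m + half,
    current_mean = cur, ci_lower = m - half, ci_upper = m + half
  )
}
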
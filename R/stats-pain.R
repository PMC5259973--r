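#' Area under the pain-score curve above baseline
#'
#' Trapezoidal area of `(score - baseline)` against time, anchored at
#' `t = 0` with a delta of zero (the baseline is the time-0 reference).
#' Negative increments are kept by default; `floor_negative = TRUE` clips the
#' integrand at zero.
#'
#' @param data Tibble with time and score columns (post-treatment
#'   observations, time in hours > 0), or a numeric vector of scores when
#'   `times` is given.
#' @param baseline Baseline score level subtracted from every observation.
#'   If `NULL`, the mean score of rows with `time_h <= 0` in `data` is used.
#' @param times Optional numeric times when `data` is a plain vector.
#' @param floor_negative Clip negative deltas at zero before integrating.
#' @return AUC in score-hours (a single number).
#' @examples
#' pain_auc_above_baseline(
#'   tibble::tibble(time_h = c(3, 6, 12), score = c(1, 2, 0)),
#'   baseline = 0
#' ) # 12
#' @export
pain_auc_above_baseline <- function(data, baseline = NULL, times = NULL,
                                    floor_negative = FALSE) {
  if (is.data.frame(data)) {
    times_all <- data$time_h
    scores_all <- data$score
  } else {
    times_all <- times
    scores_all <- data
  }
  if (is.null(baseline)) {
    pre <- times_all <= 0
    if (!any(pre)) {
      abort("no baseline rows (time_h <= 0) and no explicit baseline given",
        class = "psw_input_error"
      )
    }
    baseline <- mean(scores_all[pre])
  }
  keep <- times_all > 0
  t <- times_all[keep]
  s <- scores_all[keep]
  if (length(t) < 2) abort("need >= 2 post-treatment timepoints", class = "psw_input_error")
  if (is.unsorted(t, strictly = TRUE)) {
    abort("times must be strictly increasing", class = "psw_input_error")
  }
  delta <- s - baseline
  if (floor_negative) delta <- pmax(delta, 0)
  tt <- c(0, t)
  dd <- c(0, delta)
  sum(diff(tt) * (head(dd, -1) + dd[-1]) / 2)
}

#' Exact Wilcoxon signed-rank p-value by complete enumeration
#'
#' Enumerates all `2^n` sign assignments of the ranked absolute differences
#' (ties share mid-ranks, zeros are dropped) and returns the one-sided exact
#' p-value in the direction of the observed rank sum: `P(W+ >= w)` when the
#' positive rank sum is at or above its null mean, `P(W+ <= w)` otherwise.
#' With four concordant pairs this floor is `1/16 = 0.0625`.
#'
#' @param diffs Paired differences.
#' @param max_n Enumeration guard (default 16).
#' @return One-sided exact p-value; 1 when all differences are zero.
#' @examples
#' exact_signed_rank_p(c(2, 1, 4, 3)) # 1/16
#' @export
exact_signed_rank_p <- function(diffs, max_n = 16) {
  d <- diffs[!is.na(diffs) & diffs != 0]
  n <- length(d)
  if (n == 0) {
    return(1)
  }
  if (n > max_n) {
    abort(sprintf("enumeration limited to n <= %d nonzero differences", max_n),
      class = "psw_input_error"
    )
  }
  r <- rank(abs(d)) # mid-ranks for ties
  w_obs <- sum(r[d > 0])
  # all 2^n subsets: distribution of W+ under the exact null
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  if (w_obs >= mu) {
    mean(w_all >= w_obs - 1e-9)
  } else {
    mean(w_all <= w_obs + 1e-9)
  }
}

#' Format a p-value the way study reports print them
#'
#' Rounds half away from zero at the given number of decimals, so the exact
#' four-subject signed-rank floor 1/16 = 0.0625 prints as `"0.063"` (base
#' `sprintf` would banker's-round it to 0.062).
#'
#' @param p Numeric p-value(s).
#' @param digits Decimal places (default 3).
#' @return Character vector.
#' @examples
#' format_p_value(1 / 16) # "0.063"
#' @export
format_p_value <- function(p, digits = 3) {
  scaled <- trunc(abs(p) * 10^digits + 0.5) / 10^digits
  sprintf(paste0("%.", digits, "f"), sign(p) * scaled)
}

#' Compare per-cat pain AUCs between crossover arms
#'
#' Runs the paired t-test and the exact one-sided Wilcoxon signed-rank test
#' on per-subject AUC differences (control minus treated).
#'
#' @param data Tibble with one row per cat and columns `auc_control`,
#'   `auc_treatment`; or two numeric vectors via `auc_control`/
#'   `auc_treatment`.
#' @param auc_control,auc_treatment Numeric vectors (alternative interface).
#' @return One-row tibble: `mean_diff`, `t_statistic`, `df`, `p_t` (two-sided
#'   paired t), `p_signed_rank` (one-sided exact), `direction`.
#' @export
paired_auc_comparison <- function(data = NULL, auc_control = NULL,
                                  auc_treatment = NULL) {
  if (!is.null(data)) {
    auc_control <- data$auc_control
    auc_treatment <- data$auc_treatment
  }
  stopifnot(length(auc_control) == length(auc_treatment))
  d <- auc_control - auc_treatment
  n <- length(d)
  if (all(d == 0)) {
    return(tibble(
      mean_diff = 0, t_statistic = 0, df = n - 1, p_t = 1,
      p_signed_rank = 1, direction = "none"
    ))
  }
  tt <- t.test(auc_control, auc_treatment, paired = TRUE)
  tibble(
    mean_diff = mean(d),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_t = tt$p.value,
    p_signed_rank = exact_signed_rank_p(d),
    direction = if (mean(d) > 0) "control > treatment" else "treatment > control"
  )
}
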
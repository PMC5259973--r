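#' Velocity and acceleration of a walking pass
#'
#' The body's progress along the travel axis is tracked through the footfall
#' strike positions. Velocity is the least-squares slope of position versus
#' strike time; acceleration is the slope of the consecutive segment
#' velocities against the segment midpoints (0 when only one segment exists).
#'
#' @param footfalls Tibble with `strike_time` (s) and `x_cm` columns; at least
#'   3 footfalls spanning the mat are required.
#' @return One-row tibble with `velocity_mps`, `acceleration_mps2`, and
#'   `n_points`. Fewer than 3 usable points yield `NA` values.
#' @examples
#' compute_velocity_profile(
#'   tibble::tibble(strike_time = c(0, 0.5, 1), x_cm = c(0, 30, 60))
#' )
#' @export
compute_velocity_profile <- function(footfalls) {
  ok <- !is.na(footfalls$strike_time) & !is.na(footfalls$x_cm)
  t_all <- footfalls$strike_time[ok]
  x_all <- footfalls$x_cm[ok] / 100
  ord <- order(t_all)
  t_all <- t_all[ord]
  x_all <- x_all[ord]
  # collapse near-simultaneous strikes (left/right pairs) to one body position
  tkey <- round(t_all, 6)
  tu <- unique(tkey)
  xu <- vapply(tu, function(k) mean(x_all[tkey == k]), numeric(1))
  if (length(tu) < 3) {
    return(tibble(
      velocity_mps = NA_real_, acceleration_mps2 = NA_real_,
      n_points = length(tu)
    ))
  }
  ls_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  v <- ls_slope(tu, xu)
  seg_v <- diff(xu) / diff(tu)
  mid_t <- (head(tu, -1) + tu[-1]) / 2
  a <- if (length(seg_v) >= 2) ls_slope(mid_t, seg_v) else 0
  tibble(velocity_mps = v, acceleration_mps2 = a, n_points = length(tu))
}

# lateral straightness: largest deviation of footfall centroids from their
# side's mean lateral position (cm); sides are taken from the labels when
# available, otherwise split about the mean path
straightness_cm <- function(footfalls) {
  if (nrow(footfalls) == 0) {
    return(NA_real_)
  }
  side <- footfalls$side %||% NULL
  if (is.null(side) || all(is.na(side))) {
    side <- ifelse(footfalls$y_cm >= mean(footfalls$y_cm), "L", "R")
  }
  dev <- footfalls$y_cm - stats::ave(footfalls$y_cm, side)
  max(abs(dev))
}

#' Validate one walking trial against the study's acceptance window
#'
#' A walking pass is valid when its velocity lies within `vel_tol` of the
#' target, its acceleration magnitude is at most `acc_tol`, and the lateral
#' path deviates less than `straightness_max` from straight.
#'
#' @param footfalls Footfall tibble for the trial (`strike_time`, `x_cm`,
#'   `y_cm`, optionally `side`).
#' @param target Target velocity (m/s). Default 0.6.
#' @param vel_tol Velocity tolerance (m/s). Default 0.2.
#' @param acc_tol Acceleration tolerance (m/s^2). Default 0.1.
#' @param straightness_max Maximum lateral deviation (cm).
#' @return One-row tibble: `velocity_mps`, `acceleration_mps2`,
#'   `straightness_cm`, `valid`, and `reasons` (comma-separated failure
#'   reasons, `""` when valid).
#' @export
validate_walking_trial <- function(footfalls, target = 0.6, vel_tol = 0.2,
                                   acc_tol = 0.1, straightness_max = 10) {
  prof <- compute_velocity_profile(footfalls)
  st <- straightness_cm(footfalls)
  reasons <- character()
  if (is.na(prof$velocity_mps)) {
    reasons <- c(reasons, "too_few_footfalls")
  } else {
    if (abs(prof$velocity_mps - target) > vel_tol) reasons <- c(reasons, "velocity")
    if (abs(prof$acceleration_mps2) > acc_tol) reasons <- c(reasons, "acceleration")
  }
  if (!is.na(st) && st > straightness_max) reasons <- c(reasons, "straightness")
  tibble(
    velocity_mps = prof$velocity_mps,
    acceleration_mps2 = prof$acceleration_mps2,
    straightness_cm = st,
    valid = length(reasons) == 0,
    reasons = paste(reasons, collapse = ",")
  )
}

#' Validate one landing trial
#'
#' Valid when the earliest strike(s) are forelimbs and the pass is forward:
#' any hindlimb strikes lie behind (at or upstream of) the forelimb strikes
#' along the travel axis. A trial with only forelimb strikes on the mat is
#' valid for forelimb metrics (the fore-hind delay is then undefined).
#'
#' @param footfalls Labeled footfall tibble (`position`, `strike_time`,
#'   `x_cm`).
#' @return One-row tibble with `valid`, `reasons`, and `has_hind`.
#' @export
validate_landing_trial <- function(footfalls) {
  reasons <- character()
  fore <- footfalls[footfalls$position == "fore", ]
  hind <- footfalls[footfalls$position == "hind", ]
  if (nrow(fore) == 0) {
    reasons <- c(reasons, "no_forelimb")
  } else if (nrow(hind) > 0) {
    if (min(hind$strike_time) < min(fore$strike_time)) {
      reasons <- c(reasons, "hindlimb_first")
    }
    if (mean(hind$x_cm) > mean(fore$x_cm) + 1) {
      reasons <- c(reasons, "not_forward")
    }
  }
  tibble(
    valid = length(reasons) == 0,
    reasons = paste(reasons, collapse = ","),
    has_hind = nrow(hind) > 0
  )
}

#' Select the trials closest to the target velocity
#'
#' From the valid trials of a session, keeps the `k` whose velocities are
#' closest to the target; ties are broken by smaller acceleration magnitude,
#' then by trial order. When fewer than `k` valid trials exist, all are
#' returned with a warning (condition class `psw_short_session`).
#'
#' @param qc Tibble of per-trial QC rows (must contain `velocity_mps`,
#'   `acceleration_mps2`, `valid`, and a `trial` identifier).
#' @param k Number of trials to keep (default 5).
#' @param target Target velocity (m/s).
#' @return The selected subset of `qc`, ordered as in the input, with an
#'   attribute `"short"` = TRUE when fewer than `k` were available.
#' @export
select_best_trials <- function(qc, k = 5, target = 0.6) {
  stopifnot(all(c("velocity_mps", "acceleration_mps2", "valid") %in% names(qc)))
  if (!"trial" %in% names(qc)) qc$trial <- seq_len(nrow(qc))
  valid <- qc[qc$valid & !is.na(qc$velocity_mps), , drop = FALSE]
  if (nrow(valid) < k) {
    warn(
      sprintf(
        "only %d valid trials available (requested %d); returning all",
        nrow(valid), k
      ),
      class = "psw_short_session"
    )
    attr(valid, "short") <- TRUE
    return(valid)
  }
  ord <- order(
    abs(valid$velocity_mps - target),
    abs(valid$acceleration_mps2),
    valid$trial
  )
  sel <- valid[sort(ord[seq_len(k)]), , drop = FALSE]
  attr(sel, "short") <- FALSE
  sel
}
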
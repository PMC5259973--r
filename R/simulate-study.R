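#' Simulate a complete two-period crossover study
#'
#' Generates, per cat and period, two baseline sessions and six post-operative
#' kinetic sessions, each with the configured number of walking and landing
#' trials, plus the ordinal pain-score series. Trials are generated at the
#' footfall level (the ground truth the renderer would realize); set
#' `render_frames = TRUE` to also attach a rendered [psw_recording()] per
#' trial, which is substantially heavier and normally reserved for
#' extraction-oriented work on subsets.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$rng_seed`. Disjoint seeds
#'   give distinct datasets.
#' @param trial_types Which trial types to generate (default both).
#' @param render_frames Attach rendered recordings (list-column `recording`).
#' @return An object of class `psw_study`: a list with
#'   \describe{
#'     \item{design}{the allocation tibble,}
#'     \item{trials}{one row per trial (`cat`, `period`, `treatment`,
#'       `operated_foot`, `time_h`, `is_baseline`, `trial_type`, `trial`,
#'       `body_weight_kg`, `velocity_mps`, landing truth columns, and a
#'       `footfalls` list-column of per-footfall kinetics),}
#'     \item{pain}{the pain-score observations,}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(), seed = 1)
#' nrow(study$trials) # 4 cats x 2 periods x 8 sessions x 20 trials = 1280
#' }
#' @export
simulate_study <- function(config, seed = NULL,
                           trial_types = c("walking", "landing"),
                           render_frames = FALSE) {
  validate_config(config)
  seed <- seed %||% config$rng_seed
  trial_types <- match.arg(trial_types, several.ok = TRUE)
  al <- config$allocation
  session_times <- c(config$baseline_times_h, config$kinetic_times_h)
  grid <- tidyr::expand_grid(
    idx = seq_len(nrow(al)),
    time_h = session_times,
    trial_type = trial_types
  )
  n_trials_of <- function(tt) {
    if (tt == "walking") config$n_walking_trials else config$n_landing_trials
  }

  trials <- purrr::pmap_dfr(grid, function(idx, time_h, trial_type) {
    row <- al[idx, ]
    nt <- n_trials_of(trial_type)
    s <- child_seed(seed, idx * 1000 + match(time_h, session_times) * 50 +
      (trial_type == "landing") * 25)
    with_seed(s, {
      planner <- if (trial_type == "walking") {
        plan_walking_session
      } else {
        plan_landing_session
      }
      plan <- planner(config, row$cat, time_h, row$treatment,
        row$operated_foot,
        n = nt, keep_curves = render_frames
      )
      ff <- plan_footfalls(plan)
      meta <- plan_meta(plan)
      ff_split <- split(ff, factor(ff$trial, levels = seq_len(nt)))
      out <- dplyr::bind_cols(
        fast_tb(
          cat = row$cat, period = row$period, treatment = row$treatment,
          operated_foot = row$operated_foot, time_h = time_h,
          is_baseline = time_h <= 0, trial_type = trial_type,
          trial = seq_len(nt)
        ),
        meta[setdiff(names(meta), c(
          "trial", "cat", "time_h", "treatment", "operated_foot", "trial_type"
        ))]
      )
      out$footfalls <- ff_split
      if (render_frames) {
        out$recording <- purrr::map(ff_split, function(f1) {
          render_footfalls(f1, config$body_weight_kg[row$cat], config)
        })
      }
      out
    })
  })

  pain <- purrr::map_dfr(seq_len(nrow(al)), function(idx) {
    row <- al[idx, ]
    simulate_pain_scores(config, row$cat, row$period,
      seed = child_seed(seed, 9000000 + idx),
      treatment = row$treatment
    )
  })

  structure(
    list(design = al, trials = trials, pain = pain, config = config),
    class = "psw_study"
  )
}

#' @export
print.psw_study <- function(x, ...) {
  cat(sprintf(
    "<psw_study> %d cats, %d trials (%s), %d pain observations\n",
    x$config$n_cats, nrow(x$trials),
    paste(unique(x$trials$trial_type), collapse = "+"),
    nrow(x$pain)
  ))
  invisible(x)
}

#' Per-trial QC and session summaries for a simulated or extracted study
#'
#' Applies walking/landing QC to every trial, selects the best `k` walking
#' trials per session (closest to the target velocity), and reduces each
#' session to a [session_summary()] row.
#'
#' @param study A `psw_study`, or a trials tibble shaped like
#'   `psw_study$trials`.
#' @param k Walking trials retained per session (default 5).
#' @param velocity_mode `"fixed"` uses `target` for every cat;
#'   `"comfortable"` replaces it with the cat's own median walking velocity
#'   (the study's fallback when cats walk faster than the a-priori target).
#' @param target Target walking velocity (m/s).
#' @param frame_rate_hz Frame rate for timing granularity.
#' @return A list with `qc` (per-trial QC rows) and `summaries` (one row per
#'   cat x period x session x trial type, with identifiers and the
#'   `KineticSummary` columns).
#' @export
summarize_study <- function(study, k = 5, velocity_mode = c("fixed", "comfortable"),
                            target = 0.6, frame_rate_hz = NULL) {
  velocity_mode <- match.arg(velocity_mode)
  trials <- if (inherits(study, "psw_study")) study$trials else study
  if (inherits(study, "psw_study")) {
    frame_rate_hz <- frame_rate_hz %||% study$config$frame_rate_hz
  }
  frame_rate_hz <- frame_rate_hz %||% 60

  trials <- trials |>
    dplyr::select(-dplyr::any_of(c("recording"))) |>
    dplyr::mutate(.trial_id = dplyr::row_number())
  ff_long <- trials |>
    dplyr::select(".trial_id", "footfalls") |>
    tidyr::unnest("footfalls")
  per_trial <- trial_kinetics_long(ff_long, frame_rate_hz)

  # per-trial QC: least-squares velocity profile for walking passes,
  # forelimbs-first / forward rules for landings (vectorized equivalent of
  # validate_landing_trial, which tests assert against)
  walk_ids <- trials$.trial_id[trials$trial_type == "walking"]
  qc_walk <- if (length(walk_ids)) {
    dplyr::bind_cols(
      tibble(.trial_id = walk_ids),
      purrr::map_dfr(
        trials$footfalls[match(walk_ids, trials$.trial_id)],
        validate_walking_trial,
        target = target
      )
    )
  } else {
    tibble()
  }
  land_ids <- trials$.trial_id[trials$trial_type == "landing"]
  qc_land <- if (length(land_ids)) {
    ff_long |>
      dplyr::filter(.data$.trial_id %in% land_ids) |>
      dplyr::group_by(.data$.trial_id) |>
      dplyr::summarise(
        has_fore = any(.data$position == "fore"),
        has_hind = any(.data$position == "hind"),
        fore_first = !.data$has_hind |
          min(.data$strike_time[.data$position == "hind"], Inf) >=
            min(.data$strike_time[.data$position == "fore"], Inf),
        forward = !.data$has_hind |
          mean(.data$x_cm[.data$position == "hind"]) <=
            mean(.data$x_cm[.data$position == "fore"]) + 1,
        .groups = "drop"
      ) |>
      dplyr::mutate(
        valid = .data$has_fore & .data$fore_first & .data$forward,
        reasons = paste0(
          ifelse(.data$has_fore, "", "no_forelimb,"),
          ifelse(.data$fore_first, "", "hindlimb_first,"),
          ifelse(.data$forward, "", "not_forward,")
        ),
        reasons = sub(",$", "", .data$reasons),
        velocity_mps = NA_real_, acceleration_mps2 = NA_real_,
        straightness_cm = NA_real_
      ) |>
      dplyr::select(
        ".trial_id", "velocity_mps", "acceleration_mps2",
        "straightness_cm", "valid", "reasons", "has_hind"
      )
  } else {
    tibble()
  }
  qc <- trials |>
    dplyr::select(-"footfalls", -dplyr::any_of("velocity_mps")) |>
    dplyr::left_join(dplyr::bind_rows(qc_walk, qc_land), by = ".trial_id")

  if (velocity_mode == "comfortable") {
    qc <- qc |>
      dplyr::group_by(.data$cat) |>
      dplyr::mutate(cat_target = median(.data$velocity_mps, na.rm = TRUE)) |>
      dplyr::ungroup() |>
      dplyr::mutate(valid = ifelse(
        .data$trial_type == "walking",
        !is.na(.data$velocity_mps) &
          abs(.data$velocity_mps - .data$cat_target) <= 0.2 &
          abs(.data$acceleration_mps2) <= 0.1 &
          .data$straightness_cm <= 10,
        .data$valid
      ))
  } else {
    qc$cat_target <- target
  }

  # trial selection: landings keep every valid trial; walking keeps the k
  # valid trials closest to the target velocity (select_best_trials rule)
  qc <- qc |>
    dplyr::group_by(
      .data$cat, .data$period, .data$treatment, .data$operated_foot,
      .data$time_h, .data$is_baseline, .data$trial_type
    ) |>
    dplyr::mutate(selected = if (.data$trial_type[1] == "landing") {
      .data$valid
    } else {
      ok <- .data$valid & !is.na(.data$velocity_mps)
      r <- rep(Inf, dplyr::n())
      r[ok] <- order(order(
        abs(.data$velocity_mps[ok] - .data$cat_target[ok]),
        abs(.data$acceleration_mps2[ok]),
        .data$trial[ok]
      ))
      ok & r <= k
    }) |>
    dplyr::ungroup()

  sel_trials <- per_trial |>
    dplyr::inner_join(
      qc[qc$selected, c(
        ".trial_id", "cat", "period", "treatment", "operated_foot",
        "time_h", "is_baseline", "trial_type"
      )],
      by = ".trial_id"
    )
  m <- function(x) if (length(x) == 0 || all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  s <- function(x) if (sum(!is.na(x)) < 2) NA_real_ else sd(x, na.rm = TRUE)
  summaries <- sel_trials |>
    dplyr::group_by(
      .data$cat, .data$period, .data$treatment, .data$operated_foot,
      .data$time_h, .data$is_baseline, .data$trial_type
    ) |>
    dplyr::summarise(
      op_pvf_mean = m(.data$op_pvf), op_pvf_sd = s(.data$op_pvf),
      no_pvf_mean = m(.data$no_pvf), no_pvf_sd = s(.data$no_pvf),
      op_vi_mean = m(.data$op_vi), op_vi_sd = s(.data$op_vi),
      no_vi_mean = m(.data$no_vi), no_vi_sd = s(.data$no_vi),
      si_pvf_mean = m(.data$si_pvf), si_pvf_sd = s(.data$si_pvf),
      si_vi_mean = m(.data$si_vi), si_vi_sd = s(.data$si_vi),
      tf1f2_mean = m(.data$tf1f2), tf1f2_sd = s(.data$tf1f2),
      tf1h1_mean = m(.data$tf1h1), tf1h1_sd = s(.data$tf1h1),
      ntf1f2 = sum(.data$measurable, na.rm = TRUE),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  # sessions with no selected trials (e.g. a cat refusing to walk) keep a row
  grid_keys <- dplyr::distinct(qc, .data$cat, .data$period, .data$treatment,
    .data$operated_foot, .data$time_h, .data$is_baseline, .data$trial_type
  )
  summaries <- dplyr::left_join(grid_keys, summaries, by = names(grid_keys)) |>
    dplyr::mutate(
      ntf1f2 = ifelse(is.na(.data$ntf1f2), 0L, .data$ntf1f2),
      n_trials = ifelse(is.na(.data$n_trials), 0L, .data$n_trials)
    )

  list(qc = qc, summaries = summaries)
}

#' Reshape session summaries to the long response format used by the models
#'
#' @param summaries The `summaries` tibble from [summarize_study()].
#' @param responses Response columns to keep (defaults to the mean kinetics).
#' @return Long tibble with `response`/`value` columns, one row per session
#'   and response.
#' @export
summaries_to_long <- function(summaries,
                              responses = c(
                                "op_pvf_mean", "no_pvf_mean", "op_vi_mean",
                                "no_vi_mean", "si_pvf_mean", "si_vi_mean",
                                "tf1f2_mean", "tf1h1_mean"
                              )) {
  summaries |>
    tidyr::pivot_longer(
      dplyr::any_of(responses),
      names_to = "response", values_to = "value"
    ) |>
    dplyr::select(
      "cat", "period", "treatment", "operated_foot", "time_h",
      "is_baseline", "trial_type", "response", "value"
    )
}
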
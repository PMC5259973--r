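#' Run the full study pipeline on simulated data
#'
#' Simulate (footfall-level by default) -> QC and best-trial selection ->
#' session kinetics -> baseline adjustment -> study statistics -> report.
#' The report collects the session summary tables (one per arm and trial
#' type, shaped like the study's printed kinetic tables), the pain AUC
#' comparison, the ordinal pain model with its 0.5-probability crossing
#' times, the kinetic crossover models, the stagger contingency analysis,
#' and a rescue-analgesia audit. The run is deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @param responses Kinetic responses to model (columns of the session
#'   summaries).
#' @param trial_types Trial types to simulate and analyze.
#' @param render_frames Render pressure frames and re-extract footfalls
#'   instead of using the generator's footfall tables (slow; intended for
#'   reduced configurations).
#' @param output_dir Optional directory: writes `report.json` plus CSV
#'   tables.
#' @param velocity_mode Passed to [summarize_study()].
#' @return An object of class `psw_report` (a named list); the JSON
#'   serialization is attached as attribute `"json"`.
#' @export
run_pipeline <- function(config, seed = NULL,
                         responses = c("si_pvf_mean", "si_vi_mean"),
                         trial_types = c("walking", "landing"),
                         render_frames = FALSE,
                         output_dir = NULL,
                         velocity_mode = "fixed") {
  seed <- seed %||% config$rng_seed
  stages <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "psw_pipeline_error"
      )
    })
  }

  study <- run_stage("simulate", simulate_study(config, seed,
    trial_types = trial_types, render_frames = render_frames
  ))

  if (render_frames) {
    study$trials <- run_stage("extract", dplyr::mutate(
      study$trials,
      footfalls = purrr::pmap(
        list(.data$recording, .data$trial_type, .data$cat, .data$operated_foot),
        function(rec, tt, cat, foot) {
          extract_trial(rec, tt, config$body_weight_kg[cat], operated_foot = foot)
        }
      )
    ))
  }

  summarized <- run_stage("qc", summarize_study(study,
    velocity_mode = velocity_mode,
    target = config$target_walk_velocity_mps
  ))
  long <- run_stage("kinetics", summaries_to_long(summarized$summaries))
  deltas <- run_stage("baseline_adjust", withCallingHandlers(
    baseline_adjust(long),
    psw_missing_baseline = function(w) invokeRestart("muffleWarning")
  ))

  # pain statistics -----------------------------------------------------------
  pain <- study$pain
  aucs <- run_stage("pain_auc", pain |>
    dplyr::group_by(.data$cat, .data$treatment) |>
    dplyr::group_map(~ dplyr::bind_cols(.y,
      tibble(auc = pain_auc_above_baseline(.x))
    )) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "auc",
      names_prefix = "auc_") |>
    dplyr::rename(auc_treatment = "auc_er_bup"))
  auc_cmp <- run_stage("pain_auc", paired_auc_comparison(aucs))
  ordinal <- run_stage("ordinal_model", tryCatch(
    fit_ordinal_repeated(pain),
    psw_fit_error = function(e) NULL
  ))
  crossings <- if (!is.null(ordinal)) crossing_times(ordinal) else NULL

  # kinetic crossover models ---------------------------------------------------
  fits <- run_stage("mixed_models", purrr::map(
    rlang::set_names(trial_types), function(tt) {
      purrr::map(rlang::set_names(responses), function(resp) {
        dd <- deltas[deltas$trial_type == tt & deltas$response == resp, ]
        if (sum(!is.na(dd$delta)) < 8) {
          return(NULL)
        }
        withCallingHandlers(
          fit_kinetic_mixed_model(dd, covariance = "unstructured"),
          psw_covariance_fallback = function(w) invokeRestart("muffleWarning")
        )
      })
    }
  ))

  # stagger contingency: baseline vs post-op in the control arm ---------------
  ntf <- run_stage("ntf1f2", {
    land <- summarized$summaries[
      summarized$summaries$trial_type == "landing" &
        summarized$summaries$treatment == "control",
    ]
    agg <- land |>
      dplyr::group_by(post = !.data$is_baseline) |>
      dplyr::summarise(
        measurable = sum(.data$ntf1f2), trials = sum(.data$n_trials),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$post)
    tab <- rbind(
      c(agg$measurable[agg$post], agg$trials[agg$post] - agg$measurable[agg$post]),
      c(agg$measurable[!agg$post], agg$trials[!agg$post] - agg$measurable[!agg$post])
    )
    list(
      table = tab,
      baseline = count_ntf1f2(rep(
        c(TRUE, FALSE),
        c(agg$measurable[!agg$post], agg$trials[!agg$post] - agg$measurable[!agg$post])
      )),
      post = count_ntf1f2(rep(
        c(TRUE, FALSE),
        c(agg$measurable[agg$post], agg$trials[agg$post] - agg$measurable[agg$post])
      )),
      test = chisq_2x2(tab)
    )
  })

  report <- structure(
    list(
      seed = seed,
      design = study$design,
      n_trials = nrow(study$trials),
      qc = dplyr::count(summarized$qc, .data$trial_type, .data$valid),
      session_tables = summarized$summaries,
      pain_auc = aucs,
      pain_auc_comparison = auc_cmp,
      ordinal_effects = if (!is.null(ordinal)) ordinal$effects else NULL,
      crossing_times = crossings,
      kinetic_effects = purrr::imap_dfr(fits, function(by_resp, tt) {
        purrr::imap_dfr(by_resp, function(f, resp) {
          if (is.null(f)) {
            return(tibble())
          }
          dplyr::bind_cols(
            tibble(trial_type = tt, response = resp),
            glance(f)[, c("covariance", "treatment_p", "direction_label")]
          )
        })
      }),
      kinetic_contrasts = purrr::imap_dfr(fits, function(by_resp, tt) {
        purrr::imap_dfr(by_resp, function(f, resp) {
          if (is.null(f)) {
            return(tibble())
          }
          dplyr::bind_cols(tibble(trial_type = tt, response = resp), tidy(f))
        })
      }),
      ntf1f2 = list(
        baseline = ntf$baseline, post = ntf$post,
        test = ntf$test
      ),
      rescue_audit = dplyr::summarise(pain,
        any_rescue = any(.data$rescue),
        max_score = max(.data$score)
      )
    ),
    class = "psw_report"
  )
  json <- report_json(report)
  attr(report, "json") <- json
  attr(report, "fits") <- fits
  attr(report, "ordinal_fit") <- ordinal
  attr(report, "deltas") <- deltas

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(json, file.path(output_dir, "report.json"))
    readr::write_csv(summarized$summaries, file.path(output_dir, "session_summaries.csv"))
    readr::write_csv(deltas, file.path(output_dir, "deltas.csv"))
    readr::write_csv(study$pain, file.path(output_dir, "pain_scores.csv"))
    readr::write_csv(report$kinetic_effects, file.path(output_dir, "kinetic_effects.csv"))
  }
  report
}

# canonical JSON serialization of the report (determinism is asserted on it)
report_json <- function(report) {
  clean <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::toJSON(clean, dataframe = "rows", auto_unbox = TRUE, digits = NA,
    na = "null", null = "null", pretty = TRUE)
}

#' @export
print.psw_report <- function(x, ...) {
  cat("<psw_report>\n")
  cat(sprintf("  trials: %d; seed %d\n", x$n_trials, x$seed))
  cat(sprintf(
    "  pain AUC paired t p = %.4g, exact signed-rank p = %.4g\n",
    x$pain_auc_comparison$p_t, x$pain_auc_comparison$p_signed_rank
  ))
  if (nrow(x$kinetic_effects)) {
    cat("  kinetic treatment effects:\n")
    print(as.data.frame(x$kinetic_effects), row.names = FALSE)
  }
  invisible(x)
}

#' Time-course plot of a session summary response
#'
#' Mean and SD of one response over session times, one line per treatment
#' arm - the shape of the study's kinetic figures.
#'
#' @param summaries `summaries` tibble from [summarize_study()].
#' @param response Column to plot (e.g. `"si_pvf_mean"`).
#' @param trial_type Which trial type to show.
#' @return A ggplot object.
#' @export
plot_si_timecourse <- function(summaries, response = "si_pvf_mean",
                               trial_type = "landing") {
  d <- summaries[summaries$trial_type == trial_type, ]
  d$t0 <- pmax(d$time_h, 0) # baselines collapse to 0 as in the study figures
  sdcol <- sub("_mean$", "_sd", response)
  agg <- d |>
    dplyr::group_by(.data$treatment, .data$t0) |>
    dplyr::summarise(
      m = mean(.data[[response]], na.rm = TRUE),
      s = mean(.data[[sdcol]], na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(agg, ggplot2::aes(
    x = .data$t0, y = .data$m,
    colour = .data$treatment, group = .data$treatment
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$m - .data$s,
      ymax = .data$m + .data$s
    )) +
    ggplot2::labs(
      x = "time (h; 0 = baseline)", y = response,
      title = sprintf("%s, %s trials", response, trial_type)
    ) +
    ggplot2::theme_minimal()
}
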
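#' Linear mixed model for baseline-adjusted kinetic responses
#'
#' Fits the crossover treatment model to baseline-subtracted session values:
#' fixed effects treatment, time (factor over the six post-operative
#' sessions) and their interaction; random intercepts for cat and for the
#' cat x period series (each period's six repeated measures share a series).
#' With `covariance = "unstructured"` the six-time residual covariance is
#' additionally modeled as a general correlation with per-time variances
#' (`corSymm` + `varIdent`); with only a handful of subjects this routinely
#' fails to converge, in which case the fit falls back to the
#' compound-symmetry structure implied by the random intercepts and a
#' warning of class `psw_covariance_fallback` is raised. Per-timepoint
#' treatment contrasts are multiplicity-adjusted with the multivariate-t
#' (Tukey-type) method.
#'
#' @param deltas Long tibble from [baseline_adjust()] (or shaped like it)
#'   with columns `cat`, `period`, `treatment`, `time_h`, `response`,
#'   `delta`.
#' @param response Which response to model (matched against the `response`
#'   column); ignored when `deltas` holds a single response already.
#' @param covariance `"unstructured"` (with fallback) or `"cs"`.
#' @param alpha Significance level for direction labels.
#' @return An object of class `psw_crossover_fit`: list with `effects`
#'   (term, numDF, denDF, F, p_value), `contrasts` (per-time estimate,
#'   SE, adjusted p, direction), `treatment_p`, `direction_label` (e.g.
#'   `"er_bup > control at 6, 54 h"`), `covariance` actually used, the
#'   `nlme` fit, and the modeling data.
#' @export
fit_kinetic_mixed_model <- function(deltas, response = NULL,
                                    covariance = c("unstructured", "cs"),
                                    alpha = 0.05) {
  covariance <- match.arg(covariance)
  d <- deltas
  if (!is.null(response) && "response" %in% names(d)) {
    d <- d[d$response == response, ]
  }
  if (!"delta" %in% names(d)) {
    abort("deltas must carry a 'delta' column (see baseline_adjust())",
      class = "psw_input_error"
    )
  }
  d <- d[!is.na(d$delta), ]
  if (nrow(d) < 8) abort("too few observations to fit", class = "psw_input_error")
  d <- dplyr::mutate(d,
    treatment = factor(.data$treatment),
    time_f = factor(.data$time_h),
    cat = factor(.data$cat),
    tpos = as.integer(factor(.data$time_h))
  )
  ctr <- list(treatment = "contr.sum", time_f = "contr.sum")
  fit <- NULL
  used <- covariance
  if (covariance == "unstructured") {
    fit <- tryCatch(
      nlme::lme(delta ~ treatment * time_f,
        random = ~ 1 | cat / period, data = d,
        correlation = nlme::corSymm(form = ~ tpos | cat / period),
        weights = nlme::varIdent(form = ~ 1 | time_f),
        contrasts = ctr,
        control = nlme::lmeControl(maxIter = 100, msMaxIter = 100, opt = "optim",
          returnObject = FALSE)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) {
      warn(paste(
        "unstructured residual covariance did not converge;",
        "falling back to compound symmetry"
      ), class = "psw_covariance_fallback")
      used <- "cs"
    }
  }
  if (is.null(fit)) {
    fit <- nlme::lme(delta ~ treatment * time_f,
      random = ~ 1 | cat / period, data = d, contrasts = ctr,
      control = nlme::lmeControl(maxIter = 100, msMaxIter = 100)
    )
  }
  av <- anova(fit, type = "marginal")
  effects <- tibble(
    term = rownames(av), numDF = av$numDF, denDF = av$denDF,
    f_value = av$`F-value`, p_value = av$`p-value`
  )
  effects <- effects[effects$term != "(Intercept)", ]

  emm <- emmeans::emmeans(fit, ~ treatment | time_f, data = d, mode = "containment")
  prs <- emmeans::contrast(emm, method = "revpairwise", by = "time_f")
  # the multivariate-t adjustment is quasi-Monte-Carlo; pin its RNG so
  # identical inputs give identical adjusted p-values
  adj <- with_seed(1L, summary(rbind(prs), adjust = "mvt"))
  contrasts <- tibble(
    time_h = as.numeric(as.character(adj$time_f)),
    contrast = as.character(adj$contrast),
    estimate = adj$estimate, se = adj$SE, df = adj$df,
    p_adj = adj$p.value
  )
  lv <- levels(d$treatment)
  contrasts <- dplyr::mutate(contrasts,
    direction = dplyr::case_when(
      .data$p_adj >= alpha ~ "ns",
      .data$estimate > 0 ~ sprintf("%s > %s", lv[2], lv[1]),
      TRUE ~ sprintf("%s > %s", lv[1], lv[2])
    )
  )
  sig <- contrasts[contrasts$direction != "ns", ]
  label <- if (nrow(sig) == 0) {
    "no per-timepoint differences"
  } else {
    dirs <- unique(sig$direction)
    paste(purrr::map_chr(dirs, function(dd) {
      sprintf("%s at %s h", dd, paste(sort(sig$time_h[sig$direction == dd]),
        collapse = ", "
      ))
    }), collapse = "; ")
  }
  structure(
    list(
      effects = effects, contrasts = contrasts,
      treatment_p = effects$p_value[effects$term == "treatment"],
      direction_label = label, covariance = used, response = response,
      fit = fit, data = d, alpha = alpha
    ),
    class = "psw_crossover_fit"
  )
}

#' @export
print.psw_crossover_fit <- function(x, ...) {
  cat(sprintf(
    "<psw_crossover_fit> response %s (covariance: %s)\n",
    x$response %||% "<single>", x$covariance
  ))
  print(as.data.frame(x$effects), row.names = FALSE)
  cat(" per-timepoint:", x$direction_label, "\n")
  invisible(x)
}

#' @rdname fit_kinetic_mixed_model
#' @param x A `psw_crossover_fit`.
#' @param ... Unused.
#' @export
tidy.psw_crossover_fit <- function(x, ...) x$contrasts

#' @rdname fit_kinetic_mixed_model
#' @export
glance.psw_crossover_fit <- function(x, ...) {
  tibble(
    response = x$response %||% NA_character_,
    covariance = x$covariance,
    treatment_p = x$treatment_p,
    n = nrow(x$data),
    direction_label = x$direction_label
  )
}

#' Plot per-timepoint treatment contrasts of a crossover fit
#'
#' @param object A `psw_crossover_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psw_crossover_fit <- function(object, ...) {
  d <- object$contrasts
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - 2 * .data$se,
      ymax = .data$estimate + 2 * .data$se,
      colour = .data$p_adj < object$alpha
    )) +
    ggplot2::labs(
      x = "time after surgery (h)",
      y = sprintf("treatment contrast (%s)", unique(d$contrast)[1]),
      colour = sprintf("p < %g", object$alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Dunnett-style comparisons of each post-operative time to baseline
#'
#' For one arm's session values (baselines included), the two baseline
#' sessions are averaged per cat into a time-0 reference, a random-intercept
#' model `value ~ time` is fitted, and each post-operative time is compared
#' to time 0 with Dunnett multiplicity adjustment.
#'
#' @param summaries Long tibble with `cat`, `time_h`, `is_baseline`, `value`
#'   for one response and arm (e.g. the control group's landing `op_pvf`).
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with one row per post-op time: `time_h`, `estimate`
#'   (difference from baseline), `se`, `df`, `p_adj`, `significant`.
#' @export
dunnett_vs_baseline <- function(summaries, alpha = 0.05) {
  need <- c("cat", "time_h", "value")
  if (!all(need %in% names(summaries))) {
    abort("summaries must have columns cat, time_h, value", class = "psw_input_error")
  }
  d <- summaries |>
    dplyr::mutate(time0 = ifelse(.data$time_h <= 0, 0, .data$time_h)) |>
    dplyr::group_by(.data$cat, .data$time0) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(
      time_f = factor(.data$time0),
      cat = factor(.data$cat)
    )
  if (!"0" %in% levels(d$time_f)) {
    abort("no baseline (time_h <= 0) rows present", class = "psw_input_error")
  }
  fit <- nlme::lme(value ~ time_f, random = ~ 1 | cat, data = d, na.action = na.omit)
  emm <- emmeans::emmeans(fit, ~time_f, data = d, mode = "containment")
  cmp <- summary(
    emmeans::contrast(emm,
      method = "trt.vs.ctrl",
      ref = which(levels(d$time_f) == "0")
    ),
    adjust = "dunnettx"
  )
  tibble(
    time_h = as.numeric(sub("^time_f", "", sub(" - .*$", "", as.character(cmp$contrast)))),
    estimate = cmp$estimate, se = cmp$SE, df = cmp$df, p_adj = cmp$p.value,
    significant = cmp$p.value < alpha
  )
}

#' Pearson chi-square and odds ratio for a 2 x 2 table
#'
#' Pearson's chi-square test of independence (no continuity correction by
#' default) with the cross-product odds ratio `(a d)/(b c)`; the Haldane
#' correction (+0.5 to every cell) is applied to the odds ratio when any cell
#' is zero.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts
#'   (`rbind(c(a, b), c(c, d))`).
#' @param correct Apply Yates' continuity correction to the test.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `odds_ratio`,
#'   `haldane` (whether the OR was corrected).
#' @examples
#' chisq_2x2(rbind(c(10, 10), c(20, 5))) # OR 0.25
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    abort("table must be 2 x 2", class = "psw_input_error")
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be nonnegative integers", class = "psw_input_error")
  }
  haldane <- any(table == 0)
  tt <- if (haldane) table + 0.5 else table
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  if (all(table == 0) || any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble(
      statistic = NA_real_, df = 1, p_value = NA_real_,
      odds_ratio = or, haldane = haldane
    ))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble(
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value, odds_ratio = or, haldane = haldane
  )
}
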
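#' Ordinal repeated-measures model for pain scores
#'
#' Fits a proportional-odds (cumulative logit) model to the post-treatment
#' ordinal pain scores with fixed effects treatment, period, time, and the
#' time x treatment and time x period interactions (time in days, numeric).
#' Two estimation routes are exposed for the small-n crossover setting:
#' \describe{
#'   \item{`"marginal"` (default)}{maximum-likelihood proportional odds
#'     (`MASS::polr`) with cat-clustered robust (sandwich) standard errors;
#'     the stable choice with very few subjects.}
#'   \item{`"random_intercept"`}{a cumulative-logit likelihood with a normal
#'     per-cat random intercept integrated by Gauss-Hermite quadrature.}
#' }
#' Both return per-term Wald chi-square tests and, per period x treatment,
#' the fitted probability that the score sits at the baseline level as a
#' function of time (the curves whose 0.5 crossings behave like an LD50).
#'
#' @param pain Tibble with `cat`, `period`, `treatment`, `time_h`, `score`;
#'   rows with `time_h <= 0` define the baseline score level and are not
#'   modeled.
#' @param method `"marginal"` or `"random_intercept"`.
#' @param time_grid Times (h) at which to evaluate the probability curves.
#' @param gh_points Quadrature nodes for the random-intercept route.
#' @return An object of class `psw_ordinal_fit`: list with `effects` (term,
#'   chisq, df, p_value), `prob_baseline` (period, treatment, time_h, prob),
#'   `category_probs` (normalized per-level probabilities on the grid),
#'   `baseline_level`, `method`, and the underlying `model`.
#' @export
fit_ordinal_repeated <- function(pain, method = c("marginal", "random_intercept"),
                                 time_grid = NULL, gh_points = 15) {
  method <- match.arg(method)
  need <- c("cat", "period", "treatment", "time_h", "score")
  if (!all(need %in% names(pain))) {
    abort(paste("pain data must have columns", paste(need, collapse = ", ")),
      class = "psw_input_error"
    )
  }
  if (dplyr::n_distinct(pain$cat) < 2 || dplyr::n_distinct(pain$period) < 2) {
    abort("need >= 2 cats and both periods", class = "psw_input_error")
  }
  base_scores <- pain$score[pain$time_h <= 0]
  baseline_level <- if (length(base_scores)) {
    as.integer(names(sort(table(base_scores), decreasing = TRUE))[1])
  } else {
    0L
  }
  d <- pain[pain$time_h > 0, ]
  lev <- sort(unique(d$score))
  if (length(lev) < 2) {
    abort("pain scores are constant; ordinal model is degenerate",
      class = "psw_fit_error"
    )
  }
  d <- dplyr::mutate(d,
    y = factor(.data$score, levels = lev, ordered = TRUE),
    time_d = .data$time_h / 24,
    treatment = factor(.data$treatment),
    period = factor(.data$period)
  )
  form <- y ~ treatment + period + time_d + time_d:treatment + time_d:period
  time_grid <- time_grid %||% sort(unique(c(seq(0, 72, by = 1), d$time_h)))
  grid <- tidyr::expand_grid(
    period = levels(d$period), treatment = levels(d$treatment),
    time_h = time_grid
  ) |>
    dplyr::mutate(
      time_d = .data$time_h / 24,
      period = factor(.data$period, levels = levels(d$period)),
      treatment = factor(.data$treatment, levels = levels(d$treatment))
    )

  if (method == "marginal") {
    model <- tryCatch(
      MASS::polr(form, data = d, Hess = TRUE),
      error = function(e) {
        abort(paste0(
          "proportional-odds fit failed (possible complete separation ",
          "or non-convergence): ", conditionMessage(e)
        ), class = "psw_fit_error")
      }
    )
    vc <- tryCatch(
      sandwich::vcovCL(model, cluster = d$cat),
      error = function(e) vcov(model)[seq_along(coef(model)), seq_along(coef(model))]
    )
    b <- coef(model)
    vc <- vc[names(b), names(b), drop = FALSE]
    mm <- stats::model.matrix(form, data = d)
    asg <- attr(mm, "assign")[-1] # drop intercept
    labs <- attr(stats::terms(form), "term.labels")
    effects <- purrr::map_dfr(seq_along(labs), function(k) {
      j <- which(asg == k)
      bj <- b[j]
      wj <- tryCatch(
        drop(t(bj) %*% solve(vc[j, j, drop = FALSE]) %*% bj),
        error = function(e) NA_real_
      )
      tibble(
        term = labs[k], chisq = wj, df = length(j),
        p_value = pchisq(wj, length(j), lower.tail = FALSE)
      )
    })
    probs <- predict(model, newdata = grid, type = "probs")
    if (is.null(dim(probs))) probs <- matrix(probs, ncol = length(lev))
    colnames(probs) <- as.character(lev)
  } else {
    gh <- gauss_hermite(gh_points)
    fit0 <- tryCatch(MASS::polr(form, data = d, Hess = TRUE),
      error = function(e) NULL
    )
    mm <- stats::model.matrix(form, data = d)[, -1, drop = FALSE]
    yind <- as.integer(d$y)
    K <- length(lev)
    cat_id <- as.integer(factor(d$cat))
    start <- if (!is.null(fit0)) {
      c(fit0$zeta[1], log(pmax(diff(fit0$zeta), 1e-3)), coef(fit0), log(0.5))
    } else {
      c(0, rep(0, K - 2), rep(0, ncol(mm)), log(0.5))
    }
    nll <- function(par) {
      zeta <- cumsum(c(par[1], exp(par[2:(K - 1)])))
      if (K == 2) zeta <- par[1]
      beta <- par[K:(K - 1 + ncol(mm))]
      sigma <- exp(par[length(par)])
      eta <- drop(mm %*% beta)
      ll <- 0
      for (i in unique(cat_id)) {
        rows <- which(cat_id == i)
        li <- 0
        for (q in seq_along(gh$nodes)) {
          b <- sqrt(2) * sigma * gh$nodes[q]
          upper <- ifelse(yind[rows] == K, 1,
            plogis(zeta[pmin(yind[rows], K - 1)] - eta[rows] - b)
          )
          lower <- ifelse(yind[rows] == 1, 0,
            plogis(zeta[pmax(yind[rows] - 1, 1)] - eta[rows] - b)
          )
          li <- li + gh$weights[q] / sqrt(pi) * prod(pmax(upper - lower, 1e-12))
        }
        ll <- ll + log(li)
      }
      -ll
    }
    opt <- tryCatch(
      stats::optim(start, nll, method = "BFGS", hessian = TRUE,
        control = list(maxit = 500)),
      error = function(e) {
        abort(paste0("random-intercept ordinal fit failed: ", conditionMessage(e)),
          class = "psw_fit_error"
        )
      }
    )
    if (opt$convergence != 0) {
      warn("random-intercept ordinal fit did not fully converge",
        class = "psw_fit_warning"
      )
    }
    par <- opt$par
    zeta <- cumsum(c(par[1], exp(par[2:(K - 1)])))
    if (K == 2) zeta <- par[1]
    beta <- par[K:(K - 1 + ncol(mm))]
    names(beta) <- colnames(mm)
    vc_all <- tryCatch(solve(opt$hessian), error = function(e) {
      matrix(NA_real_, length(par), length(par))
    })
    bidx <- K:(K - 1 + ncol(mm))
    vc <- vc_all[bidx, bidx, drop = FALSE]
    asg <- attr(stats::model.matrix(form, data = d), "assign")[-1]
    labs <- attr(stats::terms(form), "term.labels")
    effects <- purrr::map_dfr(seq_along(labs), function(k) {
      j <- which(asg == k)
      bj <- beta[j]
      wj <- tryCatch(drop(t(bj) %*% solve(vc[j, j, drop = FALSE]) %*% bj),
        error = function(e) NA_real_
      )
      tibble(
        term = labs[k], chisq = wj, df = length(j),
        p_value = pchisq(wj, length(j), lower.tail = FALSE)
      )
    })
    mm_g <- stats::model.matrix(
      stats::delete.response(stats::terms(form)),
      data = grid
    )[, -1, drop = FALSE]
    eta_g <- drop(mm_g %*% beta)
    # population-averaged category probabilities (integrate the random term)
    gh2 <- gauss_hermite(gh_points)
    sigma <- exp(par[length(par)])
    cum <- purrr::map(seq_len(K - 1), function(kk) {
      p <- 0
      for (q in seq_along(gh2$nodes)) {
        b <- sqrt(2) * sigma * gh2$nodes[q]
        p <- p + gh2$weights[q] / sqrt(pi) * plogis(zeta[kk] - eta_g - b)
      }
      p
    })
    cum <- do.call(cbind, c(cum, list(rep(1, length(eta_g)))))
    probs <- cbind(cum[, 1], t(apply(cum, 1, diff)))
    if (K == 2) probs <- cbind(cum[, 1], 1 - cum[, 1])
    colnames(probs) <- as.character(lev)
    model <- list(par = par, zeta = zeta, beta = beta, sigma = sigma, opt = opt)
  }

  base_col <- as.character(baseline_level)
  prob_base <- if (base_col %in% colnames(probs)) {
    probs[, base_col]
  } else if (baseline_level <= min(lev)) {
    # baseline level below every observed score: P(at baseline) ~ P(lowest)
    probs[, 1]
  } else {
    rep(NA_real_, nrow(probs))
  }
  prob_baseline <- dplyr::bind_cols(
    dplyr::select(grid, "period", "treatment", "time_h"),
    tibble(prob = as.numeric(prob_base))
  )
  category_probs <- dplyr::bind_cols(
    dplyr::select(grid, "period", "treatment", "time_h"),
    as_tibble(as.data.frame(probs), .name_repair = "minimal")
  )
  structure(
    list(
      effects = effects, prob_baseline = prob_baseline,
      category_probs = category_probs, baseline_level = baseline_level,
      levels = lev, method = method, model = model, n = nrow(d)
    ),
    class = "psw_ordinal_fit"
  )
}

# Golub-Welsch Gauss-Hermite nodes/weights (physicists' convention)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Time at which a probability curve first reaches a level
#'
#' Linear interpolation between evaluation points; if the curve already sits
#' at or above the level at the first timepoint the crossing is reported as
#' `"< t_min"`, and as `"> t_max"` if it never reaches the level.
#'
#' @param prob_curve Tibble with `time_h` and `prob` columns.
#' @param level Reference probability (default 0.5).
#' @return One-row tibble with `crossing_h` (numeric, `NA` when censored) and
#'   `label` (the formatted crossing, e.g. `"12"`, `"< 3"`, `"> 72"`).
#' @examples
#' crossing_time(tibble::tibble(time_h = c(0, 24), prob = c(0.2, 0.8)))
#' @export
crossing_time <- function(prob_curve, level = 0.5) {
  d <- prob_curve[order(prob_curve$time_h), ]
  if (any(d$prob < 0 | d$prob > 1, na.rm = TRUE)) {
    abort("probabilities must lie in [0, 1]", class = "psw_input_error")
  }
  if (d$prob[1] >= level) {
    return(tibble(crossing_h = NA_real_, label = sprintf("< %g", d$time_h[1])))
  }
  above <- which(d$prob >= level)
  if (length(above) == 0) {
    return(tibble(
      crossing_h = NA_real_,
      label = sprintf("> %g", d$time_h[nrow(d)])
    ))
  }
  i <- above[1]
  t0 <- d$time_h[i - 1]
  t1 <- d$time_h[i]
  p0 <- d$prob[i - 1]
  p1 <- d$prob[i]
  tc <- t0 + (level - p0) / (p1 - p0) * (t1 - t0)
  tibble(crossing_h = tc, label = sprintf("%g", tc))
}

#' Crossing times of all fitted baseline-probability curves
#'
#' @param fit A `psw_ordinal_fit`.
#' @param level Reference probability.
#' @return Tibble with one row per period x treatment.
#' @export
crossing_times <- function(fit, level = 0.5) {
  stopifnot(inherits(fit, "psw_ordinal_fit"))
  fit$prob_baseline |>
    dplyr::group_by(.data$period, .data$treatment) |>
    dplyr::group_map(~ dplyr::bind_cols(.y, crossing_time(.x, level))) |>
    dplyr::bind_rows()
}

#' @export
print.psw_ordinal_fit <- function(x, ...) {
  cat(sprintf(
    "<psw_ordinal_fit> %s proportional-odds fit, %d observations, levels %s\n",
    x$method, x$n, paste(x$levels, collapse = "/")
  ))
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_ordinal_repeated
#' @param x A `psw_ordinal_fit`.
#' @param ... Unused.
#' @export
tidy.psw_ordinal_fit <- function(x, ...) x$effects

#' @rdname fit_ordinal_repeated
#' @export
glance.psw_ordinal_fit <- function(x, ...) {
  tibble(
    method = x$method, n = x$n, n_levels = length(x$levels),
    baseline_level = x$baseline_level
  )
}

#' Plot the fitted probability-of-baseline curves
#'
#' One panel per period, one curve per treatment, with the 0.5 reference line
#' whose crossings behave like an LD50.
#'
#' @param object A `psw_ordinal_fit`.
#' @param level Reference probability line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psw_ordinal_fit <- function(object, level = 0.5, ...) {
  ggplot2::ggplot(object$prob_baseline, ggplot2::aes(
    x = .data$time_h, y = .data$prob, colour = .data$treatment
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = level, linetype = 2) +
    ggplot2::facet_wrap(~ .data$period, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time after treatment (h)",
      y = sprintf("P(score = baseline level %d)", object$baseline_level)
    ) +
    ggplot2::theme_minimal()
}
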
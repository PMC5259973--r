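#' Detect limb-contact events in a pressure recording
#'
#' Finds spatiotemporally connected suprathreshold regions: sensels above
#' `force_threshold` are linked by 8-neighbourhood adjacency within a frame
#' and by same-or-neighbouring-sensel overlap across consecutive frames.
#' Events whose footprints lie closer than `merge_dist_cm` while overlapping
#' in time are merged (multiple pads of one paw). Each event's force-time
#' curve sums the raw frame forces over the union footprint of the event, and
#' the event span is extended to adjacent frames whose summed footprint force
#' still exceeds `2 * force_threshold`, so low-force loading/unloading frames
#' are not clipped. Events spanning fewer than `min_frames` frames are
#' discarded.
#'
#' @param recording A [psw_recording()].
#' @param force_threshold Per-sensel detection threshold (N). The default
#'   0.02 N is twice the noise a sensel carrying ~0.4 N shows under the
#'   simulator's default 5% proportional noise, and sits far below the
#'   centre-sensel load of any paw contact.
#' @param min_frames Minimum event duration in frames (>= 2).
#' @param merge_dist_cm Centroid distance below which temporally overlapping
#'   events are merged.
#' @param min_peak_force Components none of whose single sensels ever exceeds
#'   this force (N) are discarded as sensor noise (chains of
#'   just-over-threshold noise sensels can otherwise persist for several
#'   frames); the default, five times the per-sensel threshold, is far below
#'   the centre-sensel force of any real paw contact.
#' @return A tibble with one row per event: `event`, `strike_time`,
#'   `lift_time`, `contact_time` (= `n_frames / frame_rate`), `n_frames`,
#'   `x_cm`, `y_cm` (force-weighted centroid), `n_sensels`, and list-columns
#'   `curve` (per-frame `frame`, `time_s`, `force`) and `centroid_path`.
#'   Empty recordings yield zero rows.
#' @export
detect_contacts <- function(recording, force_threshold = 0.02, min_frames = 2,
                            merge_dist_cm = 2,
                            min_peak_force = 5 * force_threshold) {
  stopifnot(inherits(recording, "psw_recording"))
  if (force_threshold <= 0) {
    abort("force_threshold must be > 0", class = "psw_input_error")
  }
  if (min_frames < 2) abort("min_frames must be >= 2", class = "psw_input_error")
  fr <- recording$frame_rate_hz
  pitch <- recording$sensel_pitch_cm
  d <- recording$frames
  act <- d[d$force > force_threshold, , drop = FALSE]
  if (nrow(act) == 0) {
    return(empty_events())
  }

  nr <- recording$n_rows
  nc <- recording$n_cols
  key <- (act$frame * nr + (act$row - 1)) * nc + (act$col - 1)
  off <- expand.grid(dt = 0:1, dr = -1:1, dc = -1:1)
  off <- off[!(off$dt == 0 & off$dr <= 0 & !(off$dr == 0 & off$dc > 0)), ]
  edges <- purrr::pmap(off, function(dt, dr, dc) {
    k2 <- ((act$frame + dt) * nr + (act$row - 1 + dr)) * nc + (act$col - 1 + dc)
    j <- match(k2, key)
    ok <- !is.na(j)
    cbind(which(ok), j[ok])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = nrow(act), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  act$event <- igraph::components(g)$membership

  # merge temporally overlapping events with nearby centroids (paw pads)
  info <- act |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      f_lo = min(.data$frame), f_hi = max(.data$frame),
      x = sum(.data$col * .data$force) / sum(.data$force),
      y = sum(.data$row * .data$force) / sum(.data$force),
      .groups = "drop"
    )
  if (nrow(info) > 1) {
    remap <- seq_len(max(info$event))
    for (i in seq_len(nrow(info) - 1)) {
      for (j in (i + 1):nrow(info)) {
        overlap <- info$f_lo[i] <= info$f_hi[j] && info$f_lo[j] <= info$f_hi[i]
        dist_cm <- sqrt((info$x[i] - info$x[j])^2 + (info$y[i] - info$y[j])^2) * pitch
        if (overlap && dist_cm < merge_dist_cm) {
          remap[remap == info$event[j]] <- info$event[i]
        }
      }
    }
    act$event <- remap[act$event]
  }

  full <- d # raw frames including sub-threshold entries
  events <- act |>
    dplyr::group_by(.data$event) |>
    dplyr::group_map(function(px, grp) {
      if (max(px$force) < min_peak_force) {
        return(NULL)
      }
      fp <- dplyr::distinct(px, .data$row, .data$col)
      # dilate the footprint by one sensel so sub-threshold edge loading is
      # integrated rather than clipped
      ring <- expand.grid(dr = -1:1, dc = -1:1)
      fp <- dplyr::distinct(
        fast_tb(
          row = rep(fp$row, each = nrow(ring)) + rep.int(ring$dr, nrow(fp)),
          col = rep(fp$col, each = nrow(ring)) + rep.int(ring$dc, nrow(fp))
        )
      )
      f_lo <- min(px$frame)
      f_hi <- max(px$frame)
      raw <- dplyr::semi_join(full, fp, by = c("row", "col"))
      sums <- raw |>
        dplyr::group_by(.data$frame) |>
        dplyr::summarise(force = sum(.data$force), .groups = "drop")
      # extend the span while the footprint still carries appreciable force
      sum_at <- function(f) {
        v <- sums$force[sums$frame == f]
        if (length(v)) v else 0
      }
      while (f_lo > 0 && sum_at(f_lo - 1) > 2 * force_threshold) f_lo <- f_lo - 1
      while (f_hi < recording$n_frames - 1 && sum_at(f_hi + 1) > 2 * force_threshold) {
        f_hi <- f_hi + 1
      }
      span <- f_lo:f_hi
      curve <- tibble(
        frame = as.integer(span), time_s = span / fr,
        force = purrr::map_dbl(span, sum_at)
      )
      path <- raw |>
        dplyr::filter(.data$frame %in% span) |>
        dplyr::group_by(.data$frame) |>
        dplyr::summarise(
          x_cm = sum((.data$col - 0.5) * .data$force) / sum(.data$force) * pitch,
          y_cm = sum((.data$row - 0.5) * .data$force) / sum(.data$force) * pitch,
          .groups = "drop"
        )
      tibble(
        strike_time = f_lo / fr,
        lift_time = (f_hi + 1) / fr,
        n_frames = length(span),
        contact_time = length(span) / fr,
        x_cm = sum(raw$force * (raw$col - 0.5)) / sum(raw$force) * pitch,
        y_cm = sum(raw$force * (raw$row - 0.5)) / sum(raw$force) * pitch,
        n_sensels = nrow(fp),
        curve = list(curve),
        centroid_path = list(path)
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(events) > 0) {
    events <- events[events$n_frames >= min_frames, , drop = FALSE]
  }
  if (nrow(events) == 0) {
    return(empty_events())
  }
  events <- events[order(events$strike_time, events$x_cm), , drop = FALSE]
  events$event <- seq_len(nrow(events))
  dplyr::relocate(events, "event")
}

empty_events <- function() {
  tibble(
    event = integer(), strike_time = double(), lift_time = double(),
    n_frames = integer(), contact_time = double(), x_cm = double(),
    y_cm = double(), n_sensels = integer(), curve = list(),
    centroid_path = list()
  )
}

#' Label detected contact events with limb identities
#'
#' Landing trials: the earliest one or two strikes are forelimbs and later
#' strikes hindlimbs; left/right follow from lateral offset (with travel along
#' +x, the cat's left is the larger-y side). Walking trials: side is assigned
#' from lateral position relative to the trial's mean path; fore versus hind
#' uses the track-up property of a walking quadruped - a hind paw lands on the
#' ipsilateral fore print - so co-located strike pairs are (fore first, hind
#' second), and unpaired strikes are filled in by temporal alternation within
#' the side. Events whose lateral separation from the path axis is below one
#' sensel pitch are flagged `unclassified`.
#'
#' @param events Event tibble from [detect_contacts()].
#' @param trial_type `"walking"` or `"landing"`.
#' @param sensel_pitch_cm Sensel pitch, used for the ambiguity flag.
#' @param pair_dist_cm Maximum strike-position separation for a fore/hind
#'   track-up pair (walking).
#' @return The events tibble with `side` (`"L"`/`"R"`), `position`
#'   (`"fore"`/`"hind"`), `limb` (`"LF"`, `"RF"`, `"LH"`, `"RH"`), and
#'   `unclassified` columns added.
#' @export
classify_limbs <- function(events, trial_type = c("walking", "landing"),
                           sensel_pitch_cm = 0.5, pair_dist_cm = 5) {
  trial_type <- match.arg(trial_type)
  if (nrow(events) == 0) {
    abort("no events to classify", class = "psw_input_error")
  }
  ev <- events
  y0 <- mean(ev$y_cm)
  ev$side <- ifelse(ev$y_cm >= y0, "L", "R")
  ev$unclassified <- abs(ev$y_cm - y0) < sensel_pitch_cm
  if (nrow(ev) == 1) {
    ev$position <- "fore"
    ev$limb <- paste0(ev$side, "F")
    return(ev)
  }
  if (trial_type == "landing") {
    ord <- order(ev$strike_time, ev$x_cm)
    pos <- rep("hind", nrow(ev))
    n_fore <- min(2L, nrow(ev))
    pos[ord[seq_len(n_fore)]] <- "fore"
    ev$position <- pos
    # two simultaneous fore strikes are told apart by lateral offset alone
    fore <- which(ev$position == "fore")
    if (length(fore) == 2 && abs(diff(ev$y_cm[fore])) < sensel_pitch_cm) {
      ev$unclassified[fore] <- TRUE
    }
  } else {
    ev$position <- NA_character_
    for (s in unique(ev$side)) {
      idx <- which(ev$side == s)
      sub <- ev[idx, ]
      ordt <- order(sub$strike_time)
      lab <- rep(NA_character_, length(idx))
      # pair strikes sharing a print location: earlier = fore, later = hind
      used <- rep(FALSE, length(idx))
      for (a in seq_along(idx)) {
        if (used[a]) next
        near <- which(!used & seq_along(idx) != a &
          abs(sub$x_cm - sub$x_cm[a]) < pair_dist_cm)
        if (length(near) > 0) {
          b <- near[which.min(abs(sub$strike_time[near] - sub$strike_time[a]))]
          first <- if (sub$strike_time[a] <= sub$strike_time[b]) a else b
          second <- if (first == a) b else a
          lab[first] <- "fore"
          lab[second] <- "hind"
          used[c(a, b)] <- TRUE
        }
      }
      # alternation fill for unpaired strikes (mat-edge singletons)
      seq_lab <- lab[ordt]
      anchor <- which(!is.na(seq_lab))
      if (length(anchor) == 0) {
        seq_lab <- rep(c("fore", "hind"), length.out = length(seq_lab))
      } else {
        a0 <- anchor[1]
        for (i in seq_along(seq_lab)) {
          if (is.na(seq_lab[i])) {
            same_parity <- (i - a0) %% 2 == 0
            seq_lab[i] <- if (same_parity) {
              seq_lab[a0]
            } else {
              setdiff(c("fore", "hind"), seq_lab[a0])
            }
          }
        }
      }
      lab[ordt] <- seq_lab
      ev$position[idx] <- lab
    }
  }
  ev$limb <- paste0(ev$side, ifelse(ev$position == "fore", "F", "H"))
  ev
}

#' Fill in body-weight-normalized kinetics for footfalls
#'
#' Computes peak vertical force (PVF) and vertical impulse (VI) from each
#' footfall's force-time curve: `pvf = 100 * max(curve) / W` and
#' `vi = 100 * integral(curve) / W`, where `W` is the body-weight force.
#' The integral is the trapezoid over the frame grid padded with the zero
#' frames bounding the contact, which equals the frame-midpoint (rectangle)
#' sum `sum(force) / frame_rate`.
#'
#' @param footfalls Tibble with a `curve` list-column (as produced by
#'   [detect_contacts()]); curves carry `force` in newtons and `frame`.
#' @param body_weight_kg Body mass in kg (> 0).
#' @param frame_rate_hz Acquisition rate; defaults to the rate implied by each
#'   curve's `time_s` spacing when present.
#' @return `footfalls` with `pvf_pct_bw`, `vi_pct_bw_s`, and `contact_time`
#'   columns filled in (%BW and %BW s).
#' @export
extract_kinetics <- function(footfalls, body_weight_kg, frame_rate_hz = NULL) {
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0) {
    abort("body_weight_kg must be positive", class = "psw_input_error")
  }
  if (!"curve" %in% names(footfalls)) {
    abort("footfalls must carry a 'curve' list-column", class = "psw_input_error")
  }
  w_n <- body_weight_kg * .G
  rate_of <- function(curve) {
    if (!is.null(frame_rate_hz)) {
      return(frame_rate_hz)
    }
    if (nrow(curve) >= 2) 1 / mean(diff(curve$time_s)) else 60
  }
  footfalls |>
    dplyr::mutate(
      pvf_pct_bw = purrr::map_dbl(.data$curve, function(cv) {
        if (nrow(cv) == 0) {
          return(0)
        }
        100 * max(cv$force) / w_n
      }),
      vi_pct_bw_s = purrr::map_dbl(.data$curve, function(cv) {
        if (nrow(cv) == 0) {
          return(0)
        }
        100 * sum(cv$force) / rate_of(cv) / w_n
      }),
      contact_time = purrr::map_dbl(.data$curve, function(cv) {
        if (nrow(cv) == 0) {
          return(0)
        }
        nrow(cv) / rate_of(cv)
      })
    )
}

#' Extract labeled, normalized footfalls from a recording
#'
#' Convenience wrapper: [detect_contacts()] then [classify_limbs()] then
#' [extract_kinetics()], with roles assigned when the operated foot is known.
#'
#' @inheritParams detect_contacts
#' @inheritParams classify_limbs
#' @param body_weight_kg Body mass (kg).
#' @param operated_foot Optional `"L"`/`"R"`; adds a `role` column
#'   (`operated` / `non_operated` / `hind`).
#' @return Footfall tibble with labels and kinetics.
#' @export
extract_trial <- function(recording, trial_type, body_weight_kg,
                          operated_foot = NULL, force_threshold = 0.02,
                          min_frames = 2) {
  ev <- detect_contacts(recording, force_threshold, min_frames)
  if (nrow(ev) == 0) {
    return(ev)
  }
  ev <- classify_limbs(ev, trial_type, sensel_pitch_cm = recording$sensel_pitch_cm)
  ev <- extract_kinetics(ev, body_weight_kg, frame_rate_hz = recording$frame_rate_hz)
  if (!is.null(operated_foot)) {
    ev <- assign_roles(ev, operated_foot)
  }
  ev
}

#' Assign operated / non-operated / hind roles to labeled footfalls
#'
#' @param footfalls Tibble with a `limb` column.
#' @param operated_foot `"L"` or `"R"`.
#' @return `footfalls` with a `role` column.
#' @export
assign_roles <- function(footfalls, operated_foot) {
  stopifnot(operated_foot %in% c("L", "R"))
  op <- paste0(operated_foot, "F")
  dplyr::mutate(footfalls, role = dplyr::case_when(
    .data$limb == op ~ "operated",
    substr(.data$limb, 2, 2) == "F" ~ "non_operated",
    TRUE ~ "hind"
  ))
}
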
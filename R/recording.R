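#' Pressure-sensitive walkway recordings
#'
#' A `psw_recording` is a time-ordered stack of calibrated force grids. The
#' grid is stored sparsely: only sensels carrying force appear in the `frames`
#' tibble (`frame` is 0-based; `row`/`col` are 1-based grid indices; `force`
#' is in newtons). The travel axis runs along columns (`x`), the mat width
#' along rows (`y`); physical coordinates in cm are `(index - 0.5) * pitch`.
#'
#' @param frames Tibble with columns `frame`, `row`, `col`, `force`.
#' @param n_frames,n_rows,n_cols Grid extent (constant across frames).
#' @param frame_rate_hz Acquisition rate (Hz), > 0.
#' @param sensel_pitch_cm Sensel spacing (cm); 0.5 at 4 sensels/cm^2.
#' @param calibration_range_psi Calibrated sensor range (psi).
#' @return An object of class `psw_recording`.
#' @export
psw_recording <- function(frames, n_frames, n_rows, n_cols,
                          frame_rate_hz = 60, sensel_pitch_cm = 0.5,
                          calibration_range_psi = 50) {
  frames <- as_tibble(frames)
  need <- c("frame", "row", "col", "force")
  if (!all(need %in% names(frames))) {
    abort("frames must have columns frame, row, col, force", class = "psw_schema_error")
  }
  if (frame_rate_hz <= 0) {
    abort("frame_rate_hz must be > 0", class = "psw_schema_error")
  }
  if (nrow(frames) > 0) {
    if (any(frames$force < 0)) {
      abort("all forces must be >= 0", class = "psw_schema_error")
    }
    if (any(frames$row < 1 | frames$row > n_rows) ||
      any(frames$col < 1 | frames$col > n_cols) ||
      any(frames$frame < 0 | frames$frame >= n_frames)) {
      abort("frame/row/col indices outside the declared grid", class = "psw_schema_error")
    }
  }
  structure(
    list(
      frames = frames,
      n_frames = as.integer(n_frames),
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      frame_rate_hz = frame_rate_hz,
      sensel_pitch_cm = sensel_pitch_cm,
      calibration_range_psi = calibration_range_psi
    ),
    class = "psw_recording"
  )
}

#' @export
print.psw_recording <- function(x, ...) {
  cat(sprintf(
    "<psw_recording> %d frames @ %g Hz, %d x %d sensels (pitch %g cm), %d active entries\n",
    x$n_frames, x$frame_rate_hz, x$n_rows, x$n_cols, x$sensel_pitch_cm,
    nrow(x$frames)
  ))
  invisible(x)
}

#' Write and read a recording container
#'
#' The on-disk container is a directory holding `meta.json` (acquisition
#' attributes and grid extent), `frames.csv` (the sparse force grid), and
#' optionally `ground_truth.json` (the simulator's per-footfall sidecar).
#' Doubles round-trip losslessly. Missing or invalid attributes raise a
#' schema error naming the field.
#'
#' @param rec A `psw_recording`.
#' @param path Directory path (created if needed).
#' @param ground_truth Optional ground-truth tibble to store as a sidecar.
#' @return `write_recording` returns `path` invisibly. `read_recording`
#'   returns the `psw_recording`; a stored sidecar is attached as attribute
#'   `"ground_truth"`.
#' @examples
#' rec <- psw_recording(
#'   tibble::tibble(frame = 0L, row = 1L, col = 1L, force = 1.5),
#'   n_frames = 2, n_rows = 4, n_cols = 4
#' )
#' p <- write_recording(rec, tempfile())
#' rec2 <- read_recording(p)
#' @export
write_recording <- function(rec, path, ground_truth = NULL) {
  stopifnot(inherits(rec, "psw_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "psw-recording",
    version = 1L,
    n_frames = rec$n_frames, n_rows = rec$n_rows, n_cols = rec$n_cols,
    frame_rate_hz = rec$frame_rate_hz,
    sensel_pitch_cm = rec$sensel_pitch_cm,
    calibration_range_psi = rec$calibration_range_psi
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  # force is serialized at 17 significant digits so doubles round-trip exactly
  out <- rec$frames
  out$force <- sprintf("%.17g", out$force)
  readr::write_csv(out, file.path(path, "frames.csv"))
  if (!is.null(ground_truth)) {
    jsonlite::write_json(ground_truth, file.path(path, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("no meta.json found under '%s'", path), class = "psw_schema_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c(
    "n_frames", "n_rows", "n_cols", "frame_rate_hz",
    "sensel_pitch_cm", "calibration_range_psi"
  )) {
    v <- meta[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(sprintf("recording schema error: missing or invalid attribute '%s'", field),
        class = "psw_schema_error"
      )
    }
  }
  if (meta$frame_rate_hz <= 0) {
    abort("recording schema error: attribute 'frame_rate_hz' must be > 0",
      class = "psw_schema_error"
    )
  }
  frames <- readr::read_csv(file.path(path, "frames.csv"),
    col_types = readr::cols(
      frame = readr::col_integer(),
      row = readr::col_integer(),
      col = readr::col_integer(),
      # parsed via base strtod (correctly rounded) for exact round-trips
      force = readr::col_character()
    ),
    progress = FALSE
  )
  frames$force <- as.numeric(frames$force)
  rec <- psw_recording(
    frames,
    n_frames = meta$n_frames, n_rows = meta$n_rows, n_cols = meta$n_cols,
    frame_rate_hz = meta$frame_rate_hz,
    sensel_pitch_cm = meta$sensel_pitch_cm,
    calibration_range_psi = meta$calibration_range_psi
  )
  gt_path <- file.path(path, "ground_truth.json")
  if (file.exists(gt_path)) {
    attr(rec, "ground_truth") <- as_tibble(
      jsonlite::read_json(gt_path, simplifyVector = TRUE)
    )
  }
  rec
}

#' Import a directory of per-frame CSV grids as a recording
#'
#' Supports a legacy layout in which each frame is a dense CSV matrix named
#' `frame_<k>.csv` (0-based), with acquisition attributes supplied by the
#' caller.
#'
#' @param dir Directory containing `frame_*.csv` files.
#' @inheritParams psw_recording
#' @return A `psw_recording` equivalent to the dense frames.
#' @export
read_recording_csv_frames <- function(dir, frame_rate_hz = 60,
                                      sensel_pitch_cm = 0.5,
                                      calibration_range_psi = 50) {
  files <- list.files(dir, pattern = "^frame_\\d+\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    abort("no frame_<k>.csv files found", class = "psw_schema_error")
  }
  idx <- as.integer(sub("^frame_(\\d+)\\.csv$", "\\1", basename(files)))
  files <- files[order(idx)]
  idx <- sort(idx)
  mats <- purrr::map(files, ~ as.matrix(readr::read_csv(.x,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_double()), progress = FALSE
  )))
  dims <- unique(purrr::map(mats, dim))
  if (length(dims) != 1) {
    abort("grid dimensions differ across frames", class = "psw_schema_error")
  }
  sparse <- purrr::map2_dfr(mats, idx, function(m, k) {
    nz <- which(m != 0, arr.ind = TRUE)
    tibble(
      frame = as.integer(k), row = as.integer(nz[, 1]),
      col = as.integer(nz[, 2]), force = m[nz]
    )
  })
  psw_recording(sparse,
    n_frames = max(idx) + 1L, n_rows = dims[[1]][1], n_cols = dims[[1]][2],
    frame_rate_hz = frame_rate_hz, sensel_pitch_cm = sensel_pitch_cm,
    calibration_range_psi = calibration_range_psi
  )
}

#' Heatmap of one frame of a recording
#'
#' @param object A `psw_recording`.
#' @param frame 0-based frame index to display; defaults to the frame with the
#'   largest total force.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psw_recording <- function(object, frame = NULL, ...) {
  d <- object$frames
  if (is.null(frame)) {
    tot <- dplyr::summarise(dplyr::group_by(d, .data$frame),
      f = sum(.data$force), .groups = "drop"
    )
    frame <- tot$frame[which.max(tot$f)]
  }
  d <- dplyr::filter(d, .data$frame == !!frame)
  pitch <- object$sensel_pitch_cm
  ggplot2::ggplot(d, ggplot2::aes(
    x = (.data$col - 0.5) * pitch,
    y = (.data$row - 0.5) * pitch, fill = .data$force
  )) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal(
      xlim = c(0, object$n_cols * pitch),
      ylim = c(0, object$n_rows * pitch)
    ) +
    ggplot2::scale_fill_viridis_c(name = "force (N)") +
    ggplot2::labs(
      x = "x (cm, travel axis)", y = "y (cm)",
      title = sprintf("frame %d (t = %.3f s)", frame, frame / object$frame_rate_hz)
    ) +
    ggplot2::theme_minimal()
}
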
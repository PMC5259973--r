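#' Generate a single-footfall force-time curve on the frame grid
#'
#' Produces the vertical ground-reaction force of one limb contact sampled at
#' the walkway's frame rate. Two analytic shapes are supported: a half-sine
#' (smooth loading/unloading, integral `(2/pi) * peak * contact_time`) and a
#' triangle (integral `peak * contact_time / 2`). Samples are taken at frame
#' midpoints so every frame of the contact carries positive force; the
#' ground-truth impulse is the frame-grid time integral of the sampled curve
#' (midpoint rule, identical to the trapezoid over the zero-padded grid that
#' [extract_kinetics()] uses), so generator and extractor agree by
#' construction up to sensor noise.
#'
#' @param peak Peak force (any consistent unit; %BW in most of this package).
#' @param contact_time Contact duration in seconds; must span >= 2 frames.
#' @param frame_rate Acquisition rate in Hz.
#' @param shape `"half_sine"` or `"triangular"`.
#' @return A tibble with one row per frame of the contact: `frame` (0-based
#'   offset from strike), `time_s` (frame midpoint), `force`, and attributes
#'   `vi` (ground-truth integral, unit x s) and `pvf` (sampled maximum).
#' @examples
#' fc <- generate_force_curve(50, 0.2, 60, "half_sine")
#' attr(fc, "vi") # close to (2 / pi) * 50 * 0.2
#' @export
generate_force_curve <- function(peak, contact_time, frame_rate,
                                 shape = c("half_sine", "triangular")) {
  shape <- match.arg(shape)
  if (!is.numeric(peak) || length(peak) != 1 || peak <= 0) {
    abort("peak force must be a single positive number", class = "psw_input_error")
  }
  if (frame_rate <= 0) abort("frame_rate must be > 0", class = "psw_input_error")
  n <- round(contact_time * frame_rate)
  if (n < 2) {
    abort("contact_time must span at least 2 frames", class = "psw_input_error")
  }
  u <- (seq_len(n) - 0.5) / n # midpoint positions in (0, 1)
  force <- switch(shape,
    half_sine = peak * sin(pi * u),
    triangular = peak * (1 - abs(2 * u - 1))
  )
  out <- fast_tb(frame = seq_len(n) - 1L, time_s = u * n / frame_rate, force = force)
  attr(out, "vi") <- sum(force) / frame_rate
  attr(out, "pvf") <- max(force)
  attr(out, "contact_time") <- n / frame_rate
  out
}
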
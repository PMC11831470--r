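#' Phasor of a multi-exponential decay
#'
#' Closed-form phasor coordinates at the modulation frequency. A single
#' exponential with lifetime tau maps to
#' `g = 1 / (1 + (omega tau)^2)`, `s = omega tau / (1 + (omega tau)^2)`,
#' which lies on the universal semicircle `(g - 1/2)^2 + s^2 = 1/4`.
#' A mixture maps to the intensity-fraction-weighted sum of its component
#' phasors (phasor linearity), which falls strictly inside the semicircle
#' whenever two distinct lifetimes contribute.
#'
#' @param decay A [decay_spec()].
#' @param mod A [modulation_context()].
#' @return A `phasor_point`: list with numeric scalars `g` and `s`.
#' @examples
#' mod <- modulation_context(80e6)
#' phasor_from_decay(decay_spec(1, 4000), mod)
#' @export
phasor_from_decay <- function(decay, mod) {
  if (!inherits(decay, "decay_spec")) stop("`decay` must be a decay_spec")
  assert_modulation_context(mod)
  wt <- omega_tau(mod, decay$lifetimes_ps)
  gi <- 1 / (1 + wt^2)
  si <- wt / (1 + wt^2)
  phasor_point(sum(decay$fractions * gi), sum(decay$fractions * si))
}

#' @rdname phasor_from_decay
#' @param g,s Phasor coordinates.
#' @export
phasor_point <- function(g, s) {
  structure(list(g = as.numeric(g), s = as.numeric(s)), class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("<phasor_point> g = %.6f, s = %.6f\n", x$g, x$s))
  invisible(x)
}

#' Signed distance to the universal semicircle
#'
#' `sqrt((g - 1/2)^2 + s^2) - 1/2`: zero for mono-exponential decays,
#' negative inside the semicircle (mixtures), positive outside (unphysical
#' for simple decays; indicates noise or miscalibration). Vectorised over
#' `g`/`s` when given a phasor field.
#'
#' @param p A `phasor_point`, or anything with `$g` and `$s`.
#' @return Signed dimensionless distance(s); `NA` where the input is invalid.
#' @export
semicircle_distance <- function(p) {
  sqrt((p$g - 0.5)^2 + p$s^2) - 0.5
}

#' Per-pixel phasor field
#'
#' Container for per-pixel phasor coordinates with a validity mask, the DC
#' intensity the phasors were normalised by, and a calibration flag. Invalid
#' pixels hold `NA` in `g`/`s` and are excluded from all statistics.
#'
#' @param g,s Numeric matrices of phasor coordinates.
#' @param valid Logical matrix; defaults to finite `g` and `s`.
#' @param intensity Optional numeric matrix of DC intensity (same shape).
#' @param calibrated Logical flag: has reference calibration been applied?
#' @return An object of class `phasor_field`.
#' @export
phasor_field <- function(g, s, valid = NULL, intensity = NULL,
                         calibrated = FALSE) {
  g <- as.matrix(g); s <- as.matrix(s)
  if (!identical(dim(g), dim(s))) stop("`g` and `s` must share shape")
  if (is.null(valid)) valid <- is.finite(g) & is.finite(s)
  valid <- as.matrix(valid)
  if (!identical(dim(valid), dim(g))) stop("`valid` must share shape with `g`")
  if (!is.null(intensity)) {
    intensity <- as.matrix(intensity)
    if (!identical(dim(intensity), dim(g))) {
      stop("`intensity` must share shape with `g`")
    }
  }
  g[!valid] <- NA_real_
  s[!valid] <- NA_real_
  structure(
    list(g = g, s = s, valid = valid, intensity = intensity,
         calibrated = isTRUE(calibrated)),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "<phasor_field> %d x %d, %d/%d valid, %s\n",
    nrow(x$g), ncol(x$g), sum(x$valid), length(x$valid),
    if (x$calibrated) "calibrated" else "uncalibrated"
  ))
  invisible(x)
}

#' Raw four-phase homodyne acquisition
#'
#' The five simultaneously digitised images of the analog detection chain:
#' the DC intensity image and the four mixer (intermediate-frequency) images
#' at reference phases 0/90/180/270 degrees.
#'
#' @param intensity_dc Numeric matrix, DC intensity image.
#' @param mixers List of four numeric matrices named `"0"`, `"90"`, `"180"`,
#'   `"270"` (same shape as `intensity_dc`).
#' @param dwell_time_us Pixel dwell time in microseconds.
#' @param n_frames_averaged Number of raw frames averaged into this frame.
#' @param meta Optional named list of acquisition metadata (protocol, seed,
#'   noise/gain settings); carried through serialisation.
#' @return An object of class `four_phase_frame`.
#' @export
four_phase_frame <- function(intensity_dc, mixers, dwell_time_us = NA_real_,
                             n_frames_averaged = 1L, meta = list()) {
  intensity_dc <- as.matrix(intensity_dc)
  phases <- c("0", "90", "180", "270")
  if (!is.list(mixers) || length(mixers) != 4L ||
      !setequal(names(mixers), phases)) {
    stop("`mixers` must be a named list with phases 0, 90, 180, 270")
  }
  mixers <- lapply(mixers[phases], as.matrix)
  for (m in mixers) {
    if (!identical(dim(m), dim(intensity_dc))) {
      stop("all five images must share shape")
    }
  }
  structure(
    list(
      intensity_dc = intensity_dc,
      mixers = mixers,
      reference_phases_deg = c(0, 90, 180, 270),
      dwell_time_us = dwell_time_us,
      n_frames_averaged = as.integer(n_frames_averaged),
      meta = meta
    ),
    class = "four_phase_frame"
  )
}

#' @export
print.four_phase_frame <- function(x, ...) {
  cat(sprintf(
    "<four_phase_frame> %d x %d, dwell %.3g us, %d frame(s) averaged\n",
    nrow(x$intensity_dc), ncol(x$intensity_dc), x$dwell_time_us,
    x$n_frames_averaged
  ))
  invisible(x)
}

#' Four-phase homodyne demodulation
#'
#' Recovers the raw (uncalibrated) phasor field from a four-phase frame by
#' quadrature differencing: `g = (D0 - D180) / (2 K I)` and
#' `s = (D90 - D270) / (2 K I)`, where `K` is the mixer conversion gain and
#' `I` the (dark-subtracted) DC intensity. Pixels whose intensity falls at or
#' below `intensity_floor` are masked invalid to avoid division blow-up.
#'
#' @param frame A [four_phase_frame()].
#' @param gain_constant Mixer conversion gain `K` (> 0); defaults to the
#'   ideal multiplier value 0.5 used by the forward simulator.
#' @param intensity_floor Pixels with dark-subtracted intensity at or below
#'   this value are invalid. Default: 1% of the 99.9th-percentile intensity
#'   (background masking).
#' @param dark_offset Constant DC offset subtracted from the intensity image
#'   before normalisation; defaults to the frame's recorded offset, else 0.
#' @return An uncalibrated [phasor_field()] carrying the intensity image.
#' @export
demodulate_four_phase <- function(frame, gain_constant = 0.5,
                                  intensity_floor = NULL,
                                  dark_offset = NULL) {
  if (!inherits(frame, "four_phase_frame")) {
    stop("`frame` must be a four_phase_frame")
  }
  if (!is.numeric(gain_constant) || gain_constant <= 0) {
    stop("`gain_constant` must be > 0")
  }
  if (is.null(dark_offset)) {
    dark_offset <- frame$meta$dark_offset %||% 0
  }
  intensity <- frame$intensity_dc - dark_offset
  floor_val <- intensity_floor %||% default_intensity_floor(intensity)
  valid <- is.finite(intensity) & intensity > floor_val
  if (!any(valid)) {
    warning("no pixel above the intensity floor; all-invalid phasor field")
  }
  denom <- 2 * gain_constant * intensity
  g <- (frame$mixers[["0"]] - frame$mixers[["180"]]) / denom
  s <- (frame$mixers[["90"]] - frame$mixers[["270"]]) / denom
  phasor_field(g, s, valid = valid, intensity = intensity, calibrated = FALSE)
}

#' Default background-masking intensity floor
#'
#' 1% of the 99.9th-percentile intensity of the field (0 if the field is
#' empty or non-positive), the threshold below which demodulated phasors are
#' treated as background.
#'
#' @param intensity Numeric matrix or vector of intensities.
#' @return A scalar floor value.
#' @export
default_intensity_floor <- function(intensity) {
  v <- intensity[is.finite(intensity)]
  if (length(v) == 0L) return(0)
  max(0.01 * stats::quantile(v, 0.999, names = FALSE), 0)
}

#' Phase and modulation lifetimes from a phasor field
#'
#' Computes the two standard frequency-domain lifetime estimates per pixel:
#' the phase lifetime `tau_phi = tan(phi) / omega` with `phi = atan2(s, g)`,
#' and the modulation lifetime `tau_m = sqrt(1/m^2 - 1) / omega` with
#' `m = sqrt(g^2 + s^2)`. They agree for mono-exponential decays and
#' `tau_m > tau_phi` for mixtures. Pixels with `m >= 1 + eps`, `m <= 0`,
#' `g <= 0` or `s < 0` are masked invalid (unphysical for simple decays).
#'
#' @param field A calibrated [phasor_field()] (a warning is attached to the
#'   result if the field is uncalibrated).
#' @param mod A [modulation_context()].
#' @param eps Tolerance above the unit circle before a pixel is invalid.
#' @return A `lifetime_field`: list with `tau_phase`, `tau_mod` (ps
#'   matrices), `valid`, and `uncalibrated_input` flag.
#' @export
lifetimes_from_phasor <- function(field, mod, eps = 1e-9) {
  if (!inherits(field, "phasor_field")) stop("`field` must be a phasor_field")
  assert_modulation_context(mod)
  uncal <- !field$calibrated
  if (uncal) {
    warning("computing lifetimes from an uncalibrated phasor field")
  }
  omega <- mod$angular_frequency
  g <- field$g
  s <- field$s
  m <- sqrt(g^2 + s^2)
  ok <- field$valid & is.finite(m) & m > 0 & m < 1 + eps & g > 0 & s >= 0
  tau_phase <- matrix(NA_real_, nrow(g), ncol(g))
  tau_mod <- matrix(NA_real_, nrow(g), ncol(g))
  tau_phase[ok] <- (s[ok] / g[ok]) / omega * 1e12
  tau_mod[ok] <- sqrt(pmax(1 / pmin(m[ok], 1)^2 - 1, 0)) / omega * 1e12
  structure(
    list(tau_phase = tau_phase, tau_mod = tau_mod, valid = ok,
         uncalibrated_input = uncal),
    class = "lifetime_field"
  )
}

#' @export
print.lifetime_field <- function(x, ...) {
  tp <- x$tau_phase[x$valid]
  cat(sprintf(
    "<lifetime_field> %d x %d, %d valid px, median tau_phi %.1f ps\n",
    nrow(x$tau_phase), ncol(x$tau_phase), sum(x$valid),
    if (length(tp)) stats::median(tp) else NA_real_
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
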
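#' Instrument calibration factors
#'
#' Phase offset and modulation scaling that map raw demodulated phasors onto
#' the true phasor of the emission, estimated from a reference fluorophore of
#' known mono-exponential lifetime (the instrument's rhodamine-standard
#' benchmarking step).
#'
#' @param phase_offset Instrument phase error in radians.
#' @param modulation_factor Instrument modulation scaling (> 0).
#' @param reference_lifetime_ps Lifetime of the reference used (ps), kept as
#'   provenance.
#' @return An object of class `calibration_factors`.
#' @export
calibration_factors <- function(phase_offset = 0, modulation_factor = 1,
                                reference_lifetime_ps = NA_real_) {
  if (!is.numeric(modulation_factor) || modulation_factor <= 0) {
    stop("`modulation_factor` must be > 0")
  }
  structure(
    list(phase_offset = as.numeric(phase_offset),
         modulation_factor = as.numeric(modulation_factor),
         reference_lifetime_ps = as.numeric(reference_lifetime_ps)),
    class = "calibration_factors"
  )
}

#' @export
print.calibration_factors <- function(x, ...) {
  cat(sprintf(
    "<calibration_factors> phase %.6g rad, modulation %.6g (ref %.5g ps)\n",
    x$phase_offset, x$modulation_factor, x$reference_lifetime_ps
  ))
  invisible(x)
}

#' Estimate calibration factors from a reference measurement
#'
#' The reference fluorophore is assumed mono-exponential with known lifetime,
#' so its true phasor is on the universal semicircle at
#' `phi = atan(omega tau_ref)`, `m = 1 / sqrt(1 + (omega tau_ref)^2)`.
#' The instrument's phase offset and modulation factor are the angle and
#' magnitude mismatch of the intensity-weighted mean measured phasor relative
#' to that truth.
#'
#' @param measured_reference An uncalibrated [phasor_field()] of the
#'   reference fluorophore.
#' @param reference_lifetime_ps Known reference lifetime (ps).
#' @param mod A [modulation_context()].
#' @return [calibration_factors()].
#' @export
estimate_calibration <- function(measured_reference, reference_lifetime_ps,
                                 mod) {
  if (!inherits(measured_reference, "phasor_field")) {
    stop("`measured_reference` must be a phasor_field")
  }
  assert_modulation_context(mod)
  ok <- measured_reference$valid
  if (!any(ok)) stop("reference field has no valid pixels")
  w <- if (is.null(measured_reference$intensity)) {
    rep(1, sum(ok))
  } else {
    measured_reference$intensity[ok]
  }
  z <- complex(real = measured_reference$g[ok],
               imaginary = measured_reference$s[ok])
  zbar <- sum(w * z) / sum(w)
  if (Mod(zbar) == 0) stop("mean reference phasor has zero magnitude")
  wt <- omega_tau(mod, reference_lifetime_ps)
  phase_true <- atan(wt)
  m_true <- 1 / sqrt(1 + wt^2)
  calibration_factors(
    phase_offset = Arg(zbar) - phase_true,
    modulation_factor = Mod(zbar) / m_true,
    reference_lifetime_ps = reference_lifetime_ps
  )
}

#' Apply (or invert) calibration on a phasor field
#'
#' Complex rotation and scaling
#' `(g + i s)_cal = (g + i s) exp(-i phase_offset) / modulation_factor`.
#' Validity masks and intensity are preserved; the calibrated flag is set.
#' Applying calibration twice is an error.
#'
#' @param field A [phasor_field()].
#' @param cal [calibration_factors()].
#' @return A calibrated [phasor_field()].
#' @export
apply_calibration <- function(field, cal) {
  if (!inherits(field, "phasor_field")) stop("`field` must be a phasor_field")
  if (!inherits(cal, "calibration_factors")) {
    stop("`cal` must be calibration_factors")
  }
  if (field$calibrated) stop("field is already calibrated")
  z <- complex(real = field$g, imaginary = field$s) *
    exp(complex(imaginary = -cal$phase_offset)) / cal$modulation_factor
  g <- matrix(Re(z), nrow(field$g), ncol(field$g))
  s <- matrix(Im(z), nrow(field$g), ncol(field$g))
  phasor_field(g, s, valid = field$valid, intensity = field$intensity,
               calibrated = TRUE)
}

#' @rdname apply_calibration
#' @export
invert_calibration <- function(field, cal) {
  if (!inherits(field, "phasor_field")) stop("`field` must be a phasor_field")
  if (!inherits(cal, "calibration_factors")) {
    stop("`cal` must be calibration_factors")
  }
  z <- complex(real = field$g, imaginary = field$s) *
    exp(complex(imaginary = cal$phase_offset)) * cal$modulation_factor
  g <- matrix(Re(z), nrow(field$g), ncol(field$g))
  s <- matrix(Im(z), nrow(field$g), ncol(field$g))
  phasor_field(g, s, valid = field$valid, intensity = field$intensity,
               calibrated = FALSE)
}
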
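#' Modulation context for frequency-domain lifetime imaging
#'
#' Bundles the excitation repetition frequency with the angular modulation
#' frequency used throughout phasor analysis. All lifetimes in this package
#' are picoseconds; the angular frequency is radians per second, so the
#' dimensionless product for a lifetime `tau_ps` is
#' `omega * tau_ps * 1e-12`.
#'
#' @param repetition_frequency Laser repetition (modulation) frequency in Hz.
#'   Defaults to the 80 MHz of a standard femtosecond Ti:sapphire source.
#' @param harmonic Harmonic order used for demodulation; fixed to 1 here
#'   (single-harmonic homodyne detection).
#' @return An object of class `modulation_context` with fields
#'   `repetition_frequency`, `angular_frequency` and `harmonic`.
#' @examples
#' mod <- modulation_context(80e6)
#' mod$angular_frequency / (2 * pi)   # 8e7
#' @export
modulation_context <- function(repetition_frequency = 80e6, harmonic = 1L) {
  if (!is.numeric(repetition_frequency) || length(repetition_frequency) != 1L ||
      !is.finite(repetition_frequency) || repetition_frequency <= 0) {
    stop("`repetition_frequency` must be a single positive number (Hz)")
  }
  harmonic <- as.integer(harmonic)
  if (length(harmonic) != 1L || is.na(harmonic) || harmonic < 1L) {
    stop("`harmonic` must be a positive integer")
  }
  if (harmonic != 1L) {
    stop("only the first harmonic is supported")
  }
  omega <- 2 * pi * repetition_frequency * harmonic
  structure(
    list(
      repetition_frequency = repetition_frequency,
      angular_frequency = omega,
      harmonic = harmonic
    ),
    class = "modulation_context"
  )
}

#' @export
print.modulation_context <- function(x, ...) {
  cat(sprintf(
    "<modulation_context> f = %.6g MHz, omega = %.6g rad/s, harmonic = %d\n",
    x$repetition_frequency / 1e6, x$angular_frequency, x$harmonic
  ))
  invisible(x)
}

# omega * tau with tau in ps
omega_tau <- function(mod, tau_ps) mod$angular_frequency * tau_ps * 1e-12

assert_modulation_context <- function(mod) {
  if (!inherits(mod, "modulation_context")) {
    stop("expected a `modulation_context`")
  }
  rel <- abs(mod$angular_frequency -
               2 * pi * mod$repetition_frequency * mod$harmonic) /
    mod$angular_frequency
  if (rel > 1e-12) stop("inconsistent modulation context")
  invisible(mod)
}

#' Multi-exponential decay specification
#'
#' Describes a fluorescence emission as a mixture of exponential decay
#' components with intensity fractions and lifetimes. Fractions are
#' intensity (steady-state) fractions, so the phasor of the mixture is their
#' weighted sum of component phasors.
#'
#' @param fractions Numeric vector of non-negative intensity fractions
#'   summing to 1 (tolerance 1e-9).
#' @param lifetimes_ps Numeric vector of non-negative lifetimes in
#'   picoseconds, same length as `fractions`.
#' @return An object of class `decay_spec`.
#' @examples
#' decay_spec(1, 2600)                    # mono-exponential eGFP-like decay
#' decay_spec(c(0.5, 0.5), c(500, 3500))  # two-state calcium-reporter mixture
#' @export
decay_spec <- function(fractions, lifetimes_ps) {
  fractions <- as.numeric(fractions)
  lifetimes_ps <- as.numeric(lifetimes_ps)
  if (length(fractions) == 0L) stop("decay must have at least one component")
  if (length(fractions) != length(lifetimes_ps)) {
    stop("`fractions` and `lifetimes_ps` must have the same length")
  }
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("fractions must be finite and non-negative")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (tolerance 1e-9)")
  }
  if (any(!is.finite(lifetimes_ps)) || any(lifetimes_ps < 0)) {
    stop("lifetimes must be finite and non-negative (ps)")
  }
  structure(
    list(fractions = fractions, lifetimes_ps = lifetimes_ps),
    class = "decay_spec"
  )
}

#' @export
print.decay_spec <- function(x, ...) {
  cat("<decay_spec>\n")
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  %5.3f x %g ps\n", x$fractions[i], x$lifetimes_ps[i]))
  }
  invisible(x)
}

is_mono_exponential <- function(decay) {
  keep <- decay$fractions > 0
  length(unique(decay$lifetimes_ps[keep])) == 1L
}
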
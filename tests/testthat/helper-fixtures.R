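# Shared fixtures for the unit suites (kept small; the heavy training run
# lives in the acceptance suite only).

fx_mod <- modulation_context(80e6)

# closed-form phasor of a decay spec (independent re-implementation of the
# package's algebra, used as an in-suite oracle)
fx_phasor_oracle <- function(fractions, lifetimes_ps, f_hz = 80e6) {
  wt <- 2 * pi * f_hz * lifetimes_ps * 1e-12
  c(g = sum(fractions / (1 + wt^2)), s = sum(fractions * wt / (1 + wt^2)))
}

fx_uniform_frame <- function(tau_ps = 2500, rate = 200, size = 64L,
                             noise = NULL, err = instrument_error(),
                             seed = 1L, dwell = 2, frames = 1L) {
  map <- uniform_emission_map(size, rate, decay_spec(1, tau_ps))
  simulate_acquisition(map, acquisition_protocol(dwell, size, frames),
                       fx_mod, err = err, noise = noise, seed = seed)
}
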
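test_that("mono-exponential phasor matches the closed form", {
  p <- phasor_from_decay(decay_spec(1, 4000), fx_mod)
  oracle <- fx_phasor_oracle(1, 4000)
  expect_equal(p$g, unname(oracle["g"]), tolerance = 1e-12)
  expect_equal(p$s, unname(oracle["s"]), tolerance = 1e-12)
  # frozen oracle values for 4000 ps at 80 MHz
  expect_equal(p$g, 0.1983108, tolerance = 1e-6)
  expect_equal(p$s, 0.3987275, tolerance = 1e-6)
})

test_that("mono-exponential phasors sit on the universal semicircle", {
  taus <- c(1, 10, 100, 500, 1680, 2500, 4080, 10000, 1e5)
  for (tau in taus) {
    p <- phasor_from_decay(decay_spec(1, tau), fx_mod)
    expect_lt(abs(semicircle_distance(p)), 1e-9)
  }
})

test_that("phasor linearity of mixtures is exact", {
  set.seed(42)
  for (k in 1:50) {
    nc <- sample(2:4, 1)
    fr <- runif(nc); fr <- fr / sum(fr)
    taus <- runif(nc, 100, 6000)
    p_mix <- phasor_from_decay(decay_spec(fr, taus), fx_mod)
    comp <- vapply(seq_len(nc), function(i) {
      p <- phasor_from_decay(decay_spec(1, taus[i]), fx_mod)
      c(p$g, p$s)
    }, numeric(2))
    expect_equal(p_mix$g, sum(fr * comp[1, ]), tolerance = 1e-12)
    expect_equal(p_mix$s, sum(fr * comp[2, ]), tolerance = 1e-12)
    # mixtures of distinct lifetimes fall strictly inside the semicircle
    expect_lt(semicircle_distance(p_mix), 0)
  }
})

test_that("equal-fraction 50/50 mixture averages the component phasors", {
  p1 <- phasor_from_decay(decay_spec(1, 500), fx_mod)
  p2 <- phasor_from_decay(decay_spec(1, 3500), fx_mod)
  pm <- phasor_from_decay(decay_spec(c(0.5, 0.5), c(500, 3500)), fx_mod)
  expect_equal(pm$g, (p1$g + p2$g) / 2, tolerance = 1e-12)
  expect_equal(pm$s, (p1$s + p2$s) / 2, tolerance = 1e-12)
})

test_that("decay_spec validates fractions and lifetimes", {
  expect_error(decay_spec(c(0.5, 0.4), c(1000, 2000)), "sum")
  expect_error(decay_spec(1, -5))
  expect_error(decay_spec(c(-0.2, 1.2), c(1000, 2000)))
  expect_silent(decay_spec(c(0.25, 0.75), c(500, 3500)))
})

test_that("noiseless simulate -> demodulate round-trips the phasor exactly", {
  frame <- fx_uniform_frame(tau_ps = 3000, noise = NULL, seed = NULL)
  pf <- demodulate_four_phase(frame)
  oracle <- fx_phasor_oracle(1, 3000)
  expect_true(all(pf$valid))
  expect_lt(max(abs(pf$g - oracle["g"])), 1e-12)
  expect_lt(max(abs(pf$s - oracle["s"])), 1e-12)
  expect_false(pf$calibrated)
})

test_that("demodulation masks background pixels below the intensity floor", {
  rate <- matrix(0, 64, 64)
  rate[17:48, 17:48] <- 100
  map <- emission_map(rate, 2500, array(1, dim = c(64, 64, 1)))
  frame <- simulate_acquisition(map, acquisition_protocol(2, 64L), fx_mod,
                                seed = 3L)
  pf <- demodulate_four_phase(frame)
  expect_true(all(pf$valid[17:48, 17:48]))
  expect_false(any(pf$valid[1:16, ]))
  expect_true(all(is.na(pf$g[!pf$valid])))
})

test_that("all-background frame warns and yields an all-invalid field", {
  map <- emission_map(matrix(0, 64, 64), 2500, array(1, dim = c(64, 64, 1)))
  frame <- simulate_acquisition(map, acquisition_protocol(2, 64L), fx_mod,
                                seed = 3L)
  expect_warning(pf <- demodulate_four_phase(frame), "intensity floor")
  expect_false(any(pf$valid))
})

test_that("phase and modulation lifetimes are exact for mono-exponentials", {
  for (tau in c(800, 1680, 2500, 4080)) {
    frame <- fx_uniform_frame(tau_ps = tau)
    pf <- demodulate_four_phase(frame)
    pf$calibrated <- TRUE  # ideal instrument, no calibration needed
    lt <- lifetimes_from_phasor(pf, fx_mod)
    expect_lt(max(abs(lt$tau_phase[lt$valid] - tau)), 1e-6)
    expect_lt(max(abs(lt$tau_mod[lt$valid] - tau)), 1e-6)
  }
})

test_that("tau_m >= tau_phi with equality only for mono-exponentials", {
  mono <- phasor_from_decay(decay_spec(1, 2500), fx_mod)
  mix <- phasor_from_decay(decay_spec(c(0.5, 0.5), c(500, 3500)), fx_mod)
  to_field <- function(p) {
    phasor_field(matrix(p$g, 1, 1), matrix(p$s, 1, 1), calibrated = TRUE)
  }
  lt_mono <- lifetimes_from_phasor(to_field(mono), fx_mod)
  lt_mix <- lifetimes_from_phasor(to_field(mix), fx_mod)
  expect_equal(lt_mono$tau_mod[1, 1], lt_mono$tau_phase[1, 1],
               tolerance = 1e-9)
  expect_gt(lt_mix$tau_mod[1, 1], lt_mix$tau_phase[1, 1])
  # frozen oracle for the 50/50 500/3500 ps mixture at 80 MHz
  expect_equal(lt_mix$tau_phase[1, 1], 1118.3264, tolerance = 1e-6)
  expect_equal(lt_mix$tau_mod[1, 1], 2147.6344, tolerance = 1e-6)
})

test_that("lifetimes from an uncalibrated field warn and flag the result", {
  frame <- fx_uniform_frame()
  pf <- demodulate_four_phase(frame)
  expect_warning(lt <- lifetimes_from_phasor(pf, fx_mod), "uncalibrated")
  expect_true(lt$uncalibrated_input)
})

test_that("unphysical phasors (outside unit circle, negative s) are masked", {
  g <- matrix(c(0.9, 0.3, -0.1, 0.3), 2, 2)
  s <- matrix(c(0.9, 0.4, 0.2, -0.05), 2, 2)
  pf <- phasor_field(g, s, calibrated = TRUE)
  lt <- lifetimes_from_phasor(pf, fx_mod)
  expect_false(lt$valid[1, 1])  # m > 1
  expect_true(lt$valid[2, 1])
  expect_false(lt$valid[1, 2])  # g < 0
  expect_false(lt$valid[2, 2])  # s < 0
})

test_that("calibration recovers injected instrument error exactly (noiseless)", {
  err <- instrument_error(phase_offset = pi / 6, modulation_loss = 0.8)
  frame_ref <- fx_uniform_frame(tau_ps = 1680, err = err, seed = NULL)
  pf_ref <- demodulate_four_phase(frame_ref)
  cal <- estimate_calibration(pf_ref, 1680, fx_mod)
  expect_equal(cal$phase_offset, pi / 6, tolerance = 1e-9)
  expect_equal(cal$modulation_factor, 0.8, tolerance = 1e-9)
  frame <- fx_uniform_frame(tau_ps = 4080, err = err, seed = NULL)
  pf <- apply_calibration(demodulate_four_phase(frame), cal)
  oracle <- fx_phasor_oracle(1, 4080)
  expect_lt(max(abs(pf$g - oracle["g"])), 1e-9)
  expect_lt(max(abs(pf$s - oracle["s"])), 1e-9)
  expect_lt(max(abs(semicircle_distance(pf)), na.rm = TRUE), 1e-9)
})

test_that("double calibration errors; invert_calibration round-trips", {
  cal <- calibration_factors(0.3, 0.9)
  pf <- phasor_field(matrix(0.4, 2, 2), matrix(0.3, 2, 2))
  cal_pf <- apply_calibration(pf, cal)
  expect_error(apply_calibration(cal_pf, cal), "already calibrated")
  back <- invert_calibration(cal_pf, cal)
  expect_equal(back$g, pf$g, tolerance = 1e-12)
  expect_equal(back$s, pf$s, tolerance = 1e-12)
})

test_that("calibration estimation fails cleanly on empty fields", {
  pf <- phasor_field(matrix(NA_real_, 2, 2), matrix(NA_real_, 2, 2))
  expect_error(estimate_calibration(pf, 1680, fx_mod), "no valid pixels")
})

test_that("modulation context computes omega consistently", {
  mod <- modulation_context(80e6)
  expect_equal(mod$angular_frequency, 2 * pi * 80e6, tolerance = 1e-12)
  expect_error(modulation_context(80e6, harmonic = 2L), "harmonic")
  expect_error(modulation_context(-1))
})
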
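test_that("protocol presets encode the fast/slow acquisition scheme", {
  fast <- protocol_fast()
  gt <- protocol_gt()
  expect_equal(fast$dwell_time_us, 2)
  expect_equal(fast$image_size, 256L)
  expect_equal(fast$n_frames, 1L)
  expect_equal(gt$dwell_time_us, 10)
  expect_equal(gt$image_size, 512L)
  expect_equal(gt$n_frames, 5L)
  expect_equal(acquisition_time(fast), 0.131072, tolerance = 1e-12)
  expect_equal(acquisition_time(gt), 13.1072, tolerance = 1e-12)
  expect_equal(speed_ratio(gt, fast), 100, tolerance = 1e-12)
})

test_that("protocol validation rejects bad settings", {
  expect_error(acquisition_protocol(0, 256L), "dwell")
  expect_error(acquisition_protocol(2, 32L), "64..2048")
  expect_error(acquisition_protocol(2, 4096L), "64..2048")
  expect_error(acquisition_protocol(2, 256L, 0L), "n_frames")
})

test_that("simulation is bitwise reproducible from the seed", {
  f1 <- fx_uniform_frame(noise = noise_model(read_noise_sigma = 1), seed = 9L)
  f2 <- fx_uniform_frame(noise = noise_model(read_noise_sigma = 1), seed = 9L)
  f3 <- fx_uniform_frame(noise = noise_model(read_noise_sigma = 1), seed = 10L)
  expect_identical(f1$intensity_dc, f2$intensity_dc)
  expect_identical(f1$mixers, f2$mixers)
  expect_false(identical(f1$intensity_dc, f3$intensity_dc))
})

test_that("with_local_seed restores the ambient RNG stream", {
  set.seed(123)
  a <- runif(3)
  set.seed(123)
  invisible(with_local_seed(77L, runif(10)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("substream seeds are deterministic and distinct", {
  s1 <- derive_substream_seeds(5L, 10L)
  s2 <- derive_substream_seeds(5L, 10L)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 10L)
  expect_false(identical(s1, derive_substream_seeds(6L, 10L)))
})

test_that("DC channel variance follows the Poisson-Gaussian law", {
  # N = 100 expected photons, gain 1.5, sigma 2 -> var = 1.5^2*100 + 4
  size <- 317L  # ~1e5 independent draws
  map <- uniform_emission_map(size, 50, decay_spec(1, 2500))
  frame <- simulate_acquisition(
    map, acquisition_protocol(2, size), fx_mod,
    noise = noise_model(gain = 1.5, read_noise_sigma = 2), seed = 5L
  )
  v <- var(as.numeric(frame$intensity_dc))
  expect_equal(v, 1.5^2 * 100 + 4, tolerance = 0.05)
})

test_that("SNR of g scales as sqrt(dwell) and sqrt(frames)", {
  sd_g <- function(dwell, frames, seed) {
    prot <- acquisition_protocol(dwell, 128L, n_frames = frames)
    map <- uniform_emission_map(128L, 50, decay_spec(1, 2500))
    frame <- simulate_acquisition(map, prot, fx_mod, noise = noise_model(),
                                  seed = seed)
    pf <- demodulate_four_phase(frame)
    sd(pf$g[pf$valid])
  }
  # 4x the dwell (or frames) should halve the phasor noise (ratio 2 +/- 10%)
  expect_equal(sd_g(2, 1L, 11L) / sd_g(8, 1L, 12L), 2, tolerance = 0.1)
  expect_equal(sd_g(2, 1L, 13L) / sd_g(2, 4L, 14L), 2, tolerance = 0.1)
})

test_that("frame averaging equals the multi-frame protocol in expectation", {
  map <- uniform_emission_map(64L, 100, decay_spec(1, 2500))
  prot1 <- acquisition_protocol(2, 64L, 1L)
  singles <- lapply(1:4, function(k) {
    simulate_acquisition(map, prot1, fx_mod, noise = noise_model(),
                         seed = 100L + k)
  })
  avg <- average_frames(singles)
  expect_equal(avg$n_frames_averaged, 4L)
  expect_equal(avg$intensity_dc,
               Reduce(`+`, lapply(singles, `[[`, "intensity_dc")) / 4)
  # averaging reduces demodulated phasor noise
  pf1 <- demodulate_four_phase(singles[[1L]])
  pf4 <- demodulate_four_phase(avg)
  expect_lt(sd(pf4$g[pf4$valid]), sd(pf1$g[pf1$valid]))
})

test_that("noiseless emission phasor equals the closed form per pixel", {
  map <- uniform_emission_map(64L, 100, decay_spec(c(0.3, 0.7), c(800, 3200)))
  ph <- emission_phasor(map, fx_mod)
  oracle <- fx_phasor_oracle(c(0.3, 0.7), c(800, 3200))
  expect_lt(max(abs(ph$g - oracle["g"])), 1e-12)
  expect_lt(max(abs(ph$s - oracle["s"])), 1e-12)
})

test_that("emission_map validates per-pixel fractions", {
  bad <- array(0.4, dim = c(64, 64, 2))  # sums to 0.8
  expect_error(emission_map(matrix(1, 64, 64), c(500, 3500), bad), "sum to 1")
  # zero-rate pixels may carry zero fractions
  rate <- matrix(0, 64, 64); rate[1, 1] <- 5
  fr <- array(0, dim = c(64, 64, 1)); fr[1, 1, 1] <- 1
  expect_silent(emission_map(rate, 2500, fr))
})

test_that("dark offset and gain are recorded and undone at demodulation", {
  nm <- noise_model(gain = 2, read_noise_sigma = 0, dark_offset = 50)
  frame <- fx_uniform_frame(tau_ps = 2500, noise = nm, seed = 8L)
  pf <- demodulate_four_phase(frame)
  oracle <- fx_phasor_oracle(1, 2500)
  # dark-subtracted intensity and unbiased phasors (statistically)
  expect_equal(mean(pf$intensity), 2 * 200 * 2, tolerance = 0.05)
  expect_equal(mean(pf$g[pf$valid]), unname(oracle["g"]), tolerance = 0.02)
  expect_equal(mean(pf$s[pf$valid]), unname(oracle["s"]), tolerance = 0.02)
})
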
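test_that("phasor histogram is a census of valid above-threshold pixels", {
  g <- matrix(runif(64 * 64, 0.1, 0.9), 64, 64)
  s <- matrix(runif(64 * 64, 0.05, 0.45), 64, 64)
  intensity <- matrix(100, 64, 64)
  intensity[1:8, ] <- 0  # background rows
  pf <- phasor_field(g, s, intensity = intensity, calibrated = TRUE)
  h <- phasor_histogram(pf, bins = 64L)
  expect_equal(sum(h$counts), sum(intensity > h$intensity_threshold))
  expect_equal(h$n_pixels, 56L * 64L)
  # empty field errors
  pf0 <- phasor_field(g, s, intensity = matrix(0, 64, 64), calibrated = TRUE)
  expect_error(phasor_histogram(pf0, threshold = 1), "no valid pixels")
})

test_that("phasor gating segments a noiseless two-population phantom", {
  p1 <- phasor_from_decay(decay_spec(1, 1200), fx_mod)
  p2 <- phasor_from_decay(decay_spec(1, 3800), fx_mod)
  truth <- matrix(rep(c(1L, 2L), each = 32 * 64), 64, 64)
  g <- matrix(ifelse(truth == 1L, p1$g, p2$g), 64, 64)
  s <- matrix(ifelse(truth == 1L, p1$s, p2$s), 64, 64)
  pf <- phasor_field(g, s, calibrated = TRUE)
  gates <- list(phasor_gate(p1$g, p1$s, 0.05, 0.05),
                phasor_gate(p2$g, p2$s, 0.05, 0.05))
  labels <- segment_by_phasor(pf, gates)
  expect_identical(labels, truth)  # 100% accuracy, noiseless
  # overlapping gates: first gate wins
  gates_wide <- list(phasor_gate(p1$g, p1$s, 1, 1),
                     phasor_gate(p2$g, p2$s, 0.05, 0.05))
  expect_warning(l2 <- segment_by_phasor(pf, gates_wide), "gate 2")
  expect_true(all(l2 == 1L))
})

test_that("rotated elliptical gates contain what they should", {
  gt <- phasor_gate(0.5, 0.3, 0.2, 0.05, angle_rad = pi / 4)
  along <- c(0.5 + 0.15 * cos(pi / 4), 0.3 + 0.15 * sin(pi / 4))
  across <- c(0.5 - 0.1 * sin(pi / 4), 0.3 + 0.1 * cos(pi / 4))
  expect_true(fdflim:::gate_contains(gt, along[1], along[2]))
  expect_false(fdflim:::gate_contains(gt, across[1], across[2]))
})

test_that("Lorentzian fit recovers peak and width from exact histograms", {
  x <- seq(500, 4500, length.out = 128)
  y <- 80 * 300^2 / ((x - 2200)^2 + 300^2)
  ft <- lorentz_fit(list(mids = x, counts = y))
  expect_equal(ft$peak_ps, 2200, tolerance = 1e-6)
  expect_equal(ft$gamma_ps, 300, tolerance = 1e-4)
  expect_lt(ft$mse, 1e-12)
  expect_match(format(ft), "2200/300 ps")
})

test_that("Lorentzian fit recovers the peak within a bin width over seeds", {
  for (sd in 1:20) {
    set.seed(sd)
    x <- rcauchy(20000, location = 2500, scale = 300)
    x <- x[x > 500 & x < 4500]
    ft <- lorentz_fit(x, bins = 64L)
    expect_lt(abs(ft$peak_ps - 2500), diff(ft$mids)[1])
  }
})

test_that("delta F over F reproduces closed forms", {
  f <- c(10, 12, 15, 10, 8)
  d <- delta_f_over_f(f)
  expect_equal(d$dff, (f - 10) / 10, tolerance = 1e-12)
  expect_equal(d$time_s, 0:4)
  # median-of-first-k baseline
  d2 <- delta_f_over_f(f, baseline = "median_k", baseline_k = 3L)
  expect_equal(d2$dff, (f - 12) / 12, tolerance = 1e-12)
  expect_error(delta_f_over_f(c(0, 1, 2)), "baseline")
  # a degree-5 polynomial trace is fitted exactly
  t <- seq(0, 10, length.out = 30)
  f5 <- 100 * (1 + 0.01 * t - 0.002 * t^2 + 3e-4 * t^3 - 1e-5 * t^5)
  d5 <- delta_f_over_f(f5, time_s = t, fit_polynomial = TRUE)
  expect_lt(max(abs(d5$dff_fit - d5$dff)), 1e-9)
  expect_length(attr(d5, "poly_coef"), 6L)
})

test_that("trace smoothing: impulse spreads to 1/9 after the mean stage", {
  tr <- rep(0, 21); tr[11] <- 1
  avg <- smooth_trace(tr, poly_stage = FALSE)
  expect_equal(avg[11], 1 / 9, tolerance = 1e-12)
  expect_equal(avg[7], 1 / 9, tolerance = 1e-12)   # window edge
  expect_equal(avg[6], 0, tolerance = 1e-12)       # outside the window
  # constant traces are fixed points of the full pipeline
  const <- rep(2.5, 15)
  expect_equal(smooth_trace(const), const, tolerance = 1e-9)
  # normalization maps to [0, 1]
  sm <- smooth_trace(sin(seq(0, 6, length.out = 40)), normalize = TRUE)
  expect_equal(range(sm), c(0, 1), tolerance = 1e-12)
  expect_error(smooth_trace(1:5), "length >= 9")
})

test_that("kymograph stacks ROI summaries over time", {
  vol <- assign_lifetimes(
    make_phantom(scene_spec("rods", field_size = 64L, density = 15,
                            seed = 8L)),
    decay_spec(1, 2500)
  )
  prof <- bessel_axial_profile(beam_spec("bessel"), seq(-25, 25, 1))
  ts <- make_timeseries(vol, dynamics_spec(), acquisition_protocol(2, 64L),
                        prof, fx_mod, noise = NULL, n_frames_t = 3L,
                        seed = 2L)
  roi <- list(rows = 20:40, cols = 10:50)
  ky_i <- kymograph(ts, roi, what = "intensity")
  expect_equal(dim(ky_i), c(3L, 41L))
  expect_equal(attr(ky_i, "time_s"), ts$time_s)
  ky_t <- kymograph(ts, roi, what = "tau_phase", mod = fx_mod)
  # static noiseless mono-exponential scene: lifetime constant where defined
  expect_equal(range(ky_t, na.rm = TRUE), c(2500, 2500), tolerance = 1e-6)
  expect_error(kymograph(ts, roi, what = "tau_phase"), "mod")
  expect_error(kymograph(ts, matrix(FALSE, 64, 64), "intensity"), "empty")
})
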
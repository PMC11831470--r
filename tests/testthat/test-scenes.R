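test_that("phantom generation is a pure function of the spec", {
  for (kind in c("rods", "network", "vessels", "somata")) {
    spec <- scene_spec(kind, field_size = 64L, seed = 4L)
    v1 <- make_phantom(spec)
    v2 <- make_phantom(spec)
    expect_identical(v1$concentration, v2$concentration)
    expect_identical(v1$decay_label, v2$decay_label)
    v3 <- make_phantom(scene_spec(kind, field_size = 64L, seed = 5L))
    expect_false(identical(v1$concentration, v3$concentration))
    # some signal, non-negative, labelled wherever lit
    expect_gt(sum(v1$concentration), 0)
    expect_true(all(v1$concentration >= 0))
    expect_true(all(v1$decay_label[v1$concentration > 0] > 0))
  }
})

test_that("object count scales with density", {
  n_obj <- function(density) {
    v <- make_phantom(scene_spec("rods", field_size = 100L,
                                 density = density, seed = 2L))
    length(setdiff(unique(as.integer(v$decay_label)), 0L))
  }
  expect_gt(n_obj(16), n_obj(4))
})

test_that("assign_lifetimes covers labels and rejects gaps", {
  vol <- make_phantom(scene_spec("rods", field_size = 64L, density = 10,
                                 seed = 3L))
  labs <- setdiff(sort(unique(as.integer(vol$decay_label))), 0L)
  expect_gt(length(labs), 1L)
  # single decay applied everywhere
  v_all <- assign_lifetimes(vol, decay_spec(1, 2500))
  expect_setequal(names(v_all$decay_table), as.character(labs))
  # missing label is an error naming the gap
  partial <- stats::setNames(rep(list(decay_spec(1, 2500)),
                                 length(labs) - 1L),
                             as.character(labs[-1L]))
  expect_error(assign_lifetimes(vol, partial), as.character(labs[1L]))
})

test_that("scene_volume rejects labels without decay entries", {
  conc <- array(1, dim = c(4, 4, 3))
  lab <- array(2L, dim = c(4, 4, 3))
  expect_error(scene_volume(conc, lab, list(`1` = decay_spec(1, 1000))),
               "labels without")
  expect_silent(scene_volume(conc, lab, list(`2` = decay_spec(1, 1000))))
})

test_that("calcium decay interpolates between the endpoint lifetimes", {
  free <- calcium_decay(0)
  bound <- calcium_decay(1)
  mid <- calcium_decay(0.5)
  expect_equal(phasor_from_decay(free, fx_mod)$g,
               phasor_from_decay(decay_spec(1, 500), fx_mod)$g)
  expect_equal(phasor_from_decay(bound, fx_mod)$g,
               phasor_from_decay(decay_spec(1, 3500), fx_mod)$g)
  pm <- phasor_from_decay(mid, fx_mod)
  pf <- phasor_from_decay(free, fx_mod)
  pb <- phasor_from_decay(bound, fx_mod)
  expect_equal(pm$g, (pf$g + pb$g) / 2, tolerance = 1e-12)
  expect_error(calcium_decay(1.2), "bound_fraction")
})

test_that("transient activation rises instantly and decays exponentially", {
  dyn <- dynamics_spec(transient_times_s = c(10, 40), transient_decay_s = 5)
  act <- fdflim:::transient_activation
  expect_equal(act(dyn, 9.999), 0)
  expect_equal(act(dyn, 10), 1)
  expect_equal(act(dyn, 15), exp(-1), tolerance = 1e-12)
  expect_equal(act(dyn, 40), 1)  # second transient resets the envelope
})

test_that("lifetime shift moves fraction from short to long component", {
  d0 <- calcium_decay(0.3)  # 0.7 x 500 ps + 0.3 x 3500 ps
  d1 <- fdflim:::shift_decay(d0, shift_ps = 300, activation = 1)
  expect_equal(sum(d1$fractions), 1, tolerance = 1e-12)
  # mean lifetime increases by the requested amount
  expect_equal(sum(d1$fractions * d1$lifetimes_ps) -
                 sum(d0$fractions * d0$lifetimes_ps), 300, tolerance = 1e-9)
  # mono-exponential decays shift the lifetime itself
  m <- fdflim:::shift_decay(decay_spec(1, 2000), 300, 1)
  expect_equal(m$lifetimes_ps, 2300)
})

test_that("drift translates the volume rigidly with background fill", {
  vol3d <- array(0, dim = c(8, 4, 2)); vol3d[3, 2, 1] <- 7
  sh <- fdflim:::shift_volume_x(vol3d, 2)
  expect_equal(sh[5, 2, 1], 7)
  expect_equal(sum(sh), 7)
  expect_equal(fdflim:::shift_volume_x(vol3d, 0), vol3d)
})

test_that("time series reproduces transients in intensity and lifetime", {
  vol <- assign_lifetimes(
    make_phantom(scene_spec("somata", field_size = 64L, density = 12,
                            seed = 6L)),
    calcium_decay(0.2)
  )
  prof <- bessel_axial_profile(beam_spec("bessel", dof_length_um = 35),
                               seq(-25, 25, 1))
  dyn <- dynamics_spec(transient_times_s = 3, intensity_amplitude = 1.8,
                       lifetime_shift_ps = 400, transient_decay_s = 4)
  ts <- make_timeseries(vol, dyn, acquisition_protocol(2, 64L), prof, fx_mod,
                        noise = NULL, n_frames_t = 8L, frame_interval_s = 1,
                        seed = 12L)
  expect_s3_class(ts, "flim_timeseries")
  expect_length(ts$frames, 8L)
  mean_i <- vapply(ts$frames, function(f) mean(f$intensity_dc), numeric(1))
  # peak intensity at the transient onset (t = 3 -> frame 4)
  expect_equal(which.max(mean_i), 4L)
  expect_gt(mean_i[4] / mean_i[1], 1.5)
  # lifetime follows the shifted decay exactly (noiseless, uniform decay)
  tau_of <- function(f) {
    pf <- demodulate_four_phase(f); pf$calibrated <- TRUE
    lt <- lifetimes_from_phasor(pf, fx_mod)
    median(lt$tau_phase[lt$valid])
  }
  tau_oracle <- function(decay) {
    p <- phasor_from_decay(decay, fx_mod)
    (p$s / p$g) / fx_mod$angular_frequency * 1e12
  }
  d0 <- calcium_decay(0.2)
  expect_equal(tau_of(ts$frames[[1L]]), tau_oracle(d0), tolerance = 1e-6)
  expect_equal(tau_of(ts$frames[[4L]]),
               tau_oracle(fdflim:::shift_decay(d0, 400, 1)),
               tolerance = 1e-6)
  expect_gt(tau_of(ts$frames[[4L]]), tau_of(ts$frames[[1L]]) + 100)
})
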
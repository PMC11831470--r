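# 2x2 block mean of a matrix (size must be even)
block_mean_2x <- function(m) {
  d <- dim(m)
  if (any(d %% 2L != 0L)) stop("matrix size must be even for 2x downsampling")
  0.25 * (m[seq(1, d[1], 2), seq(1, d[2], 2)] +
            m[seq(2, d[1], 2), seq(1, d[2], 2)] +
            m[seq(1, d[1], 2), seq(2, d[2], 2)] +
            m[seq(2, d[1], 2), seq(2, d[2], 2)])
}

# downsample an emission map 2x: photon rate by block mean, fractions by
# rate-weighted block mean (exact flux bookkeeping)
downsample_emission_map_2x <- function(map) {
  rate_lr <- block_mean_2x(map$photon_rate)
  nb <- length(map$lifetimes_ps)
  d_lr <- dim(rate_lr)
  comp <- array(0, dim = c(d_lr[1], d_lr[2], nb))
  denom <- rate_lr
  denom[denom <= 0] <- 1
  for (j in seq_len(nb)) {
    comp[, , j] <- block_mean_2x(map$photon_rate * map$fractions[, , j]) /
      denom
  }
  emission_map(rate_lr, map$lifetimes_ps, comp)
}

# acquire -> demodulate -> (optionally calibrate) -> {intensity, g, s}
# triplet with invalid pixels zero-filled; background (masked) pixels carry
# g = s = 0 so the channels are dense images suitable for training
acquire_triplet <- function(map, protocol, mod, err, noise, seed, cal = NULL) {
  frame <- simulate_acquisition(map, protocol, mod, err = err, noise = noise,
                                seed = seed)
  pf <- demodulate_four_phase(frame)
  if (!is.null(cal)) pf <- apply_calibration(pf, cal)
  g <- pf$g; s <- pf$s
  g[!pf$valid] <- 0; s[!pf$valid] <- 0
  list(intensity = pf$intensity, g = g, s = s, valid = pf$valid)
}

#' Render a paired fast/slow training dataset
#'
#' For each scene, the target triplet is rendered under the slow
#' ground-truth protocol (10 us/pixel, 5-frame average, full resolution) and
#' the input triplet under the fast protocol (2 us/pixel, single frame, half
#' resolution), both demodulated to registered `{intensity, g, s}` images.
#' Pairs are split 6:1 into train and test.
#'
#' @param n_pairs Number of scene pairs (>= 7 to honour the 6:1 split).
#' @param scene_generator Function `(seed) -> scene_volume` (with decays
#'   attached) at the target resolution; defaults to rod phantoms carrying
#'   a mitochondrial-dye-like 2500 ps decay.
#' @param seed Master seed.
#' @param target_size Target (slow-protocol) image size in pixels; the input
#'   is `target_size / 2`.
#' @param profile Axial excitation profile for projection (default 35 um
#'   Bessel flat-top).
#' @param mod,err,noise Acquisition settings shared by both protocols.
#' @return An object of class `paired_dataset`: list with `pairs` (each
#'   holding `input`, `target` triplets and the noiseless `truth` phasor),
#'   `split` (`$train`, `$test` indices), and generation metadata.
#' @export
render_paired_dataset <- function(n_pairs, scene_generator = NULL, seed = 1L,
                                  target_size = 512L, profile = NULL,
                                  mod = modulation_context(),
                                  err = instrument_error(),
                                  noise = noise_model(read_noise_sigma = 1)) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 7L) stop("`n_pairs` must be >= 7 to honour the 6:1 split")
  if (target_size %% 2L != 0L) stop("`target_size` must be even")
  if (is.null(profile)) {
    zg <- seq(-30, 30, by = 1)
    profile <- bessel_axial_profile(beam_spec("bessel"), zg)
  }
  if (is.null(scene_generator)) {
    scene_generator <- function(s) {
      assign_lifetimes(
        make_phantom(scene_spec("rods", field_size = target_size,
                                density = 12, seed = s)),
        decay_spec(1, 2500)
      )
    }
  }
  seeds <- derive_substream_seeds(seed, 3L * n_pairs)
  prot_in <- protocol_fast(target_size / 2L)
  prot_gt <- protocol_gt(target_size)
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    vol <- scene_generator(seeds[3L * i - 2L])
    map_hr <- project_volume(vol, profile)
    map_lr <- downsample_emission_map_2x(map_hr)
    truth <- emission_phasor(map_hr, mod)
    pairs[[i]] <- list(
      target = acquire_triplet(map_hr, prot_gt, mod, err, noise,
                               seeds[3L * i - 1L]),
      input = acquire_triplet(map_lr, prot_in, mod, err, noise,
                              seeds[3L * i]),
      truth = list(g = truth$g, s = truth$s,
                   photon_rate = map_hr$photon_rate)
    )
  }
  n_test <- max(1L, round(n_pairs / 7))
  idx <- seq_len(n_pairs)
  structure(
    list(pairs = pairs,
         split = list(train = idx[seq_len(n_pairs - n_test)],
                      test = idx[(n_pairs - n_test + 1L):n_pairs]),
         seed = seed,
         input_protocol = prot_in, target_protocol = prot_gt),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(
    "<paired_dataset> %d pairs (%d train / %d test), input %d^2 -> target %d^2\n",
    length(x$pairs), length(x$split$train), length(x$split$test),
    x$input_protocol$image_size, x$target_protocol$image_size
  ))
  invisible(x)
}
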
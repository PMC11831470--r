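#' Acquisition protocol
#'
#' Scan settings of one acquisition: pixel dwell time, square image size and
#' number of frames averaged. The package ships the two protocols of the
#' paired fast/slow imaging scheme as presets: [protocol_fast()]
#' (2 us/pixel, 256 x 256, 1 frame) and [protocol_gt()] (10 us/pixel,
#' 512 x 512, 5 frames).
#'
#' @param dwell_time_us Dwell time per pixel in microseconds (> 0).
#' @param image_size Square image side in pixels (64..2048).
#' @param n_frames Number of frames to average (>= 1).
#' @param frame_rate_fps Optional nominal frame rate (metadata only).
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(dwell_time_us, image_size, n_frames = 1L,
                                 frame_rate_fps = NA_real_) {
  if (!is.numeric(dwell_time_us) || dwell_time_us <= 0) {
    stop("`dwell_time_us` must be > 0")
  }
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 64L || image_size > 2048L) {
    stop("`image_size` must be in 64..2048 pixels")
  }
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("`n_frames` must be >= 1")
  structure(
    list(dwell_time_us = dwell_time_us, image_size = image_size,
         n_frames = n_frames, frame_rate_fps = frame_rate_fps),
    class = "acquisition_protocol"
  )
}

#' @rdname acquisition_protocol
#' @param image_size Override of the preset image size (the presets' dwell
#'   and frame count are kept).
#' @export
protocol_fast <- function(image_size = 256L) {
  acquisition_protocol(2, image_size, 1L, frame_rate_fps = 4)
}

#' @rdname acquisition_protocol
#' @export
protocol_gt <- function(image_size = 512L) {
  acquisition_protocol(10, image_size, 5L, frame_rate_fps = 0.04)
}

#' Poisson-Gaussian detection noise model
#'
#' @param gain Analog units per detected photoelectron (> 0).
#' @param read_noise_sigma Gaussian read-noise standard deviation in analog
#'   units (>= 0), i.i.d. per channel and frame.
#' @param dark_offset Constant DC offset in analog units.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gain = 1, read_noise_sigma = 0, dark_offset = 0) {
  if (!is.numeric(gain) || gain <= 0) stop("`gain` must be > 0")
  if (!is.numeric(read_noise_sigma) || read_noise_sigma < 0) {
    stop("`read_noise_sigma` must be >= 0")
  }
  structure(
    list(gain = gain, read_noise_sigma = read_noise_sigma,
         dark_offset = dark_offset),
    class = "noise_model"
  )
}

#' Instrument phase/modulation error
#'
#' Systematic error of the analog chain: a phase offset added to the signal
#' phase and a multiplicative modulation loss, later removed by reference
#' calibration.
#'
#' @param phase_offset Radians.
#' @param modulation_loss In (0, 1].
#' @return An object of class `instrument_error`.
#' @export
instrument_error <- function(phase_offset = 0, modulation_loss = 1) {
  if (!is.numeric(modulation_loss) || modulation_loss <= 0 ||
      modulation_loss > 1) {
    stop("`modulation_loss` must be in (0, 1]")
  }
  structure(
    list(phase_offset = as.numeric(phase_offset),
         modulation_loss = as.numeric(modulation_loss)),
    class = "instrument_error"
  )
}

#' Emission map: photon rates plus per-pixel decay mixture
#'
#' Bridges scenes to signals. Decays are stored as a small shared basis of
#' component lifetimes plus a per-pixel fraction array, so mixtures (and
#' projections of mixtures) stay exact and the phasor at any modulation
#' frequency follows from linearity.
#'
#' @param photon_rate Numeric matrix of expected photons per microsecond per
#'   pixel (>= 0).
#' @param lifetimes_ps Numeric vector: the component lifetime basis (ps).
#' @param fractions Array `nrow x ncol x n_components` of intensity
#'   fractions; each pixel's fractions must sum to 1 (pixels with zero
#'   photon rate may carry all-zero fractions).
#' @return An object of class `emission_map`.
#' @export
emission_map <- function(photon_rate, lifetimes_ps, fractions) {
  photon_rate <- as.matrix(photon_rate)
  if (any(photon_rate < 0, na.rm = TRUE)) stop("photon_rate must be >= 0")
  lifetimes_ps <- as.numeric(lifetimes_ps)
  if (any(lifetimes_ps < 0)) stop("lifetimes must be >= 0")
  fractions <- array(fractions,
                     dim = c(nrow(photon_rate), ncol(photon_rate),
                             length(lifetimes_ps)))
  tot <- apply(fractions, c(1, 2), sum)
  lit <- photon_rate > 0
  if (any(abs(tot[lit] - 1) > 1e-6)) {
    stop("per-pixel fractions must sum to 1 where photon_rate > 0")
  }
  structure(
    list(photon_rate = photon_rate, lifetimes_ps = lifetimes_ps,
         fractions = fractions),
    class = "emission_map"
  )
}

#' @rdname emission_map
#' @param image_size Side of the square map.
#' @param rate Uniform photon rate (photons/us/pixel).
#' @param decay A [decay_spec()] applied to every pixel.
#' @export
uniform_emission_map <- function(image_size, rate, decay) {
  n <- as.integer(image_size)
  fr <- array(rep(decay$fractions, each = n * n), dim = c(n, n,
              length(decay$fractions)))
  emission_map(matrix(rate, n, n), decay$lifetimes_ps, fr)
}

#' Noiseless per-pixel phasor of an emission map
#'
#' Closed-form phasor coordinates of every pixel's decay mixture at the
#' modulation frequency (the oracle the simulated acquisition chain is
#' tested against).
#'
#' @param map An [emission_map()].
#' @param mod A [modulation_context()].
#' @return List of matrices `g` and `s`.
#' @export
emission_phasor <- function(map, mod) {
  wt <- omega_tau(mod, map$lifetimes_ps)
  gk <- 1 / (1 + wt^2)
  sk <- wt / (1 + wt^2)
  d <- dim(map$fractions)
  fr <- matrix(map$fractions, d[1] * d[2], d[3])
  list(
    g = matrix(fr %*% gk, d[1], d[2]),
    s = matrix(fr %*% sk, d[1], d[2])
  )
}

#' Evaluate code under a local, restored RNG stream
#'
#' Seeds R's generator, runs `code`, and restores the caller's
#' `.Random.seed`, so seeded library internals never perturb user-level
#' random sequences. `seed = NULL` evaluates `code` unseeded.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive independent substream seeds from one master seed
#'
#' Documented scheme: the master seed seeds R's generator once, which then
#' emits one 31-bit substream seed per consumer (frame, channel, ...) in a
#' fixed order, so a single top-level seed reproduces the whole run.
#'
#' @param seed Master integer seed.
#' @param n Number of substream seeds.
#' @return Integer vector of length `n`.
#' @export
derive_substream_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Simulate a four-phase homodyne acquisition
#'
#' Forward model of the analog chain. Per pixel the expected photoelectron
#' count is `N = photon_rate * dwell_time`. The noiseless channels are
#' `I_dc = gain N + dark_offset` and
#' `D_k = K gain N (m mloss) cos(phi + phase_offset - theta_k)`
#' with `(m, phi)` the modulation depth and phase of the pixel's decay at
#' the modulation frequency and `K` the mixer constant (ideal multiplier,
#' 0.5). Shot noise draws an independent Poisson realisation of `N` per
#' channel, and Gaussian read noise is added independently per channel;
#' `n_frames` independent realisations are averaged. Fully reproducible
#' from `seed`.
#'
#' @param map An [emission_map()].
#' @param protocol An [acquisition_protocol()]; its `image_size` must match
#'   the map.
#' @param mod A [modulation_context()].
#' @param err An [instrument_error()].
#' @param noise A [noise_model()]; `NULL` disables noise (noiseless
#'   expectation with unit gain).
#' @param seed Integer seed (or `NULL` to consume the current RNG stream).
#' @param mixer_constant Mixer conversion gain `K`.
#' @return A [four_phase_frame()].
#' @export
simulate_acquisition <- function(map, protocol, mod, err = instrument_error(),
                                 noise = noise_model(), seed = NULL,
                                 mixer_constant = 0.5) {
  if (!inherits(map, "emission_map")) stop("`map` must be an emission_map")
  if (!inherits(protocol, "acquisition_protocol")) {
    stop("`protocol` must be an acquisition_protocol")
  }
  assert_modulation_context(mod)
  if (!inherits(err, "instrument_error")) {
    stop("`err` must be an instrument_error")
  }
  noiseless <- is.null(noise)
  if (noiseless) noise <- noise_model()
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model")
  if (protocol$dwell_time_us <= 0) stop("dwell time must be positive")
  if (nrow(map$photon_rate) != protocol$image_size ||
      ncol(map$photon_rate) != protocol$image_size) {
    stop("map size does not match protocol image_size")
  }

  ph <- emission_phasor(map, mod)
  m <- sqrt(ph$g^2 + ph$s^2) * err$modulation_loss
  phi <- atan2(ph$s, ph$g) + err$phase_offset
  n_exp <- map$photon_rate * protocol$dwell_time_us
  theta <- c(0, 90, 180, 270) * pi / 180
  K <- mixer_constant
  d <- dim(n_exp)
  npx <- length(n_exp)

  make_channels <- function(n_real_dc, n_real_mix, read) {
    dc <- noise$gain * n_real_dc + noise$dark_offset + read[[1L]]
    mixers <- lapply(1:4, function(k) {
      K * noise$gain * n_real_mix[[k]] * m * cos(phi - theta[k]) +
        read[[k + 1L]]
    })
    names(mixers) <- c("0", "90", "180", "270")
    list(dc = dc, mixers = mixers)
  }

  zero_read <- rep(list(matrix(0, d[1], d[2])), 5)
  if (noiseless) {
    out <- make_channels(n_exp, rep(list(n_exp), 4), zero_read)
  } else {
    seeds <- derive_substream_seeds(seed, protocol$n_frames)
    acc_dc <- matrix(0, d[1], d[2])
    acc_mix <- rep(list(matrix(0, d[1], d[2])), 4)
    for (f in seq_len(protocol$n_frames)) {
      frame_f <- with_local_seed(seeds[f], {
        n_real_dc <- matrix(stats::rpois(npx, n_exp), d[1], d[2])
        n_real_mix <- lapply(1:4, function(k) {
          matrix(stats::rpois(npx, n_exp), d[1], d[2])
        })
        read <- lapply(1:5, function(k) {
          matrix(stats::rnorm(npx, sd = noise$read_noise_sigma), d[1], d[2])
        })
        make_channels(n_real_dc, n_real_mix, read)
      })
      acc_dc <- acc_dc + frame_f$dc
      for (k in 1:4) acc_mix[[k]] <- acc_mix[[k]] + frame_f$mixers[[k]]
    }
    out <- list(dc = acc_dc / protocol$n_frames,
                mixers = lapply(acc_mix, function(x) x / protocol$n_frames))
    names(out$mixers) <- c("0", "90", "180", "270")
  }

  four_phase_frame(
    intensity_dc = out$dc,
    mixers = out$mixers,
    dwell_time_us = protocol$dwell_time_us,
    n_frames_averaged = protocol$n_frames,
    meta = list(
      seed = seed,
      dark_offset = noise$dark_offset,
      gain = noise$gain,
      read_noise_sigma = noise$read_noise_sigma,
      mixer_constant = K,
      noiseless = noiseless,
      repetition_frequency = mod$repetition_frequency
    )
  )
}

#' Average a list of four-phase frames channel-wise
#'
#' Arithmetic mean of the DC and mixer images (what analog frame averaging
#' does before demodulation); `n_frames_averaged` of the inputs are summed.
#'
#' @param frames Non-empty list of [four_phase_frame()] with equal shapes.
#' @return A [four_phase_frame()].
#' @export
average_frames <- function(frames) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list")
  }
  ref <- frames[[1L]]
  for (f in frames) {
    if (!inherits(f, "four_phase_frame")) {
      stop("all elements must be four_phase_frame")
    }
    if (!identical(dim(f$intensity_dc), dim(ref$intensity_dc))) {
      stop("all frames must share shape")
    }
  }
  n <- length(frames)
  dc <- Reduce(`+`, lapply(frames, `[[`, "intensity_dc")) / n
  mixers <- lapply(c("0", "90", "180", "270"), function(ph) {
    Reduce(`+`, lapply(frames, function(f) f$mixers[[ph]])) / n
  })
  names(mixers) <- c("0", "90", "180", "270")
  four_phase_frame(
    dc, mixers,
    dwell_time_us = ref$dwell_time_us,
    n_frames_averaged = sum(vapply(frames, `[[`, 1L, "n_frames_averaged")),
    meta = ref$meta
  )
}

#' Pure pixel acquisition time of a protocol
#'
#' `dwell_time x image_size^2 x n_frames`, in seconds. Scan flyback and
#' turnaround overheads are excluded: this is the photon-collection time the
#' speed accounting compares, not the wall-clock frame interval.
#'
#' @param protocol An [acquisition_protocol()].
#' @return Seconds.
#' @examples
#' acquisition_time(protocol_fast())  # 0.131072 s
#' acquisition_time(protocol_gt())    # 13.1072 s
#' @export
acquisition_time <- function(protocol) {
  if (!inherits(protocol, "acquisition_protocol")) {
    stop("`protocol` must be an acquisition_protocol")
  }
  protocol$dwell_time_us * 1e-6 * as.numeric(protocol$image_size)^2 *
    protocol$n_frames
}

#' Acquisition speed-up of a fast protocol over a slow one
#'
#' Ratio of pure pixel times, `acquisition_time(slow) /
#' acquisition_time(fast)`; the ground-truth protocol over the fast
#' protocol evaluates to 100.
#'
#' @param slow,fast [acquisition_protocol()] objects.
#' @return Dimensionless fold speed-up.
#' @export
speed_ratio <- function(slow, fast) {
  tf <- acquisition_time(fast)
  if (tf <= 0) stop("fast protocol has zero acquisition time")
  acquisition_time(slow) / tf
}
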
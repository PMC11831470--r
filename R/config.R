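# YAML run configuration: a single declarative file drives the CLI. Unknown
# keys are rejected so typos fail loudly rather than silently falling back to
# defaults.

config_schema <- function() {
  list(
    modulation = c("repetition_frequency_hz", "harmonic"),
    protocol = c("preset", "dwell_time_us", "image_size", "n_frames"),
    noise = c("gain", "read_noise_sigma", "dark_offset"),
    instrument = c("phase_offset_rad", "modulation_loss"),
    beam = c("kind", "numerical_aperture", "wavelength_nm",
             "refractive_index", "dof_length_um", "edge_softness_um"),
    scene = c("phantom_kind", "field_size", "depth_um", "density",
              "z_spacing_um", "base_rate", "lifetime_ps"),
    calibration = c("reference_lifetime_ps"),
    dataset = c("n_pairs", "target_size"),
    training = c("epochs", "learning_rate", "crop_size", "levels",
                 "base_channels", "schedule"),
    analysis = c("histogram_bins", "intensity_floor"),
    run = c("seed", "output_dir")
  )
}

default_run_config <- function() {
  list(
    modulation = list(repetition_frequency_hz = 80e6, harmonic = 1L),
    protocol = list(preset = "fast", dwell_time_us = NULL,
                    image_size = NULL, n_frames = NULL),
    noise = list(gain = 1, read_noise_sigma = 1, dark_offset = 0),
    instrument = list(phase_offset_rad = 0, modulation_loss = 1),
    beam = list(kind = "bessel", numerical_aperture = 0.75,
                wavelength_nm = 920, refractive_index = 1,
                dof_length_um = 35, edge_softness_um = 2),
    scene = list(phantom_kind = "rods", field_size = 64L, depth_um = 20,
                 density = 8, z_spacing_um = 2, base_rate = 50,
                 lifetime_ps = 2500),
    calibration = list(reference_lifetime_ps = 4080),
    dataset = list(n_pairs = 14L, target_size = 128L),
    training = list(epochs = 50L, learning_rate = 1e-3, crop_size = 32L,
                    levels = 2L, base_channels = 8L, schedule = "cosine"),
    analysis = list(histogram_bins = 128L, intensity_floor = NULL),
    run = list(seed = 1L, output_dir = ".")
  )
}

#' Read and validate a YAML run configuration
#'
#' Missing sections and keys fall back to defaults (80 MHz modulation, fast
#' 2 us / 256 px protocol preset, 35 um Bessel beam, Adam with cosine
#' schedule). Unknown sections or keys are an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return An object of class `run_config` (nested named list).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      schema <- config_schema()
      bad_sec <- setdiff(names(user), names(schema))
      if (length(bad_sec)) {
        stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
      }
      for (sec in names(user)) {
        bad_key <- setdiff(names(user[[sec]]), schema[[sec]])
        if (length(bad_key)) {
          stop("unknown key(s) in section '", sec, "': ",
               paste(bad_key, collapse = ", "))
        }
        for (key in names(user[[sec]])) {
          cfg[[sec]][key] <- list(user[[sec]][[key]])
        }
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (sec in names(x)) {
    kv <- vapply(names(x[[sec]]), function(k) {
      v <- x[[sec]][[k]]
      paste0(k, "=", if (is.null(v)) "default" else paste(v, collapse = ","))
    }, character(1))
    cat(sprintf("  %s: %s\n", sec, paste(kv, collapse = " ")))
  }
  invisible(x)
}

# ---- constructors from the validated config ---------------------------------

config_modulation <- function(cfg) {
  modulation_context(cfg$modulation$repetition_frequency_hz,
                     harmonic = as.integer(cfg$modulation$harmonic))
}

config_protocol <- function(cfg) {
  p <- cfg$protocol
  base <- switch(p$preset %||% "fast",
    fast = protocol_fast(),
    gt = protocol_gt(),
    custom = acquisition_protocol(p$dwell_time_us %||% 2,
                                  p$image_size %||% 256L,
                                  p$n_frames %||% 1L),
    stop("unknown protocol preset: ", p$preset)
  )
  if (!identical(p$preset, "custom")) {
    if (!is.null(p$image_size)) {
      base <- acquisition_protocol(base$dwell_time_us, p$image_size,
                                   base$n_frames)
    }
  }
  base
}

config_noise <- function(cfg) {
  noise_model(gain = cfg$noise$gain,
              read_noise_sigma = cfg$noise$read_noise_sigma,
              dark_offset = cfg$noise$dark_offset)
}

config_instrument_error <- function(cfg) {
  instrument_error(phase_offset = cfg$instrument$phase_offset_rad,
                   modulation_loss = cfg$instrument$modulation_loss)
}

config_beam <- function(cfg) {
  b <- cfg$beam
  beam_spec(b$kind, numerical_aperture = b$numerical_aperture,
            wavelength_nm = b$wavelength_nm,
            refractive_index = b$refractive_index,
            dof_length_um = b$dof_length_um,
            edge_softness_um = b$edge_softness_um)
}

config_scene <- function(cfg) {
  s <- cfg$scene
  scene_spec(s$phantom_kind, field_size = as.integer(s$field_size),
             depth_um = s$depth_um, density = s$density,
             z_spacing_um = s$z_spacing_um, base_rate = s$base_rate,
             seed = as.integer(cfg$run$seed))
}
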
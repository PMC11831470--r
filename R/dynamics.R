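#' Temporal dynamics specification for time-series scenes
#'
#' Describes calcium-transient-like dynamics layered on a static scene:
#' transient events that scale intensity and shift the lifetime, monotonic
#' photobleaching of intensity (which leaves lifetime untouched — the core
#' argument for lifetime-based calcium read-outs), and rigid lateral drift.
#'
#' @param transient_times_s Onset times of transients, in seconds.
#' @param intensity_amplitude Peak fold-change of intensity during a
#'   transient (> 0; 1 = no intensity change).
#' @param lifetime_shift_ps Peak shift of the effective lifetime during a
#'   transient (ps). For two-component calcium decays this is realised by
#'   moving intensity fraction from the short to the long component.
#' @param transient_decay_s Exponential decay constant of a transient (s).
#' @param bleaching_rate_per_s First-order photobleaching rate (1/s, >= 0).
#' @param drift_px_per_s Rigid lateral drift along x (pixels/s).
#' @return An object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(transient_times_s = numeric(0),
                          intensity_amplitude = 1,
                          lifetime_shift_ps = 0,
                          transient_decay_s = 5,
                          bleaching_rate_per_s = 0,
                          drift_px_per_s = 0) {
  if (intensity_amplitude <= 0) stop("`intensity_amplitude` must be > 0")
  if (bleaching_rate_per_s < 0) stop("`bleaching_rate_per_s` must be >= 0")
  if (transient_decay_s <= 0) stop("`transient_decay_s` must be > 0")
  structure(
    list(transient_times_s = as.numeric(transient_times_s),
         intensity_amplitude = intensity_amplitude,
         lifetime_shift_ps = lifetime_shift_ps,
         transient_decay_s = transient_decay_s,
         bleaching_rate_per_s = bleaching_rate_per_s,
         drift_px_per_s = drift_px_per_s),
    class = "dynamics_spec"
  )
}

# transient activation in [0, 1]: instant rise at each onset, exponential decay
transient_activation <- function(dyn, t) {
  if (length(dyn$transient_times_s) == 0L) return(0)
  a <- 0
  for (t0 in dyn$transient_times_s) {
    if (t >= t0) a <- max(a, exp(-(t - t0) / dyn$transient_decay_s))
  }
  a
}

# rigid x translation of a volume by the nearest integer number of pixels
# (applied identically to concentration and labels), zero/background fill
shift_volume_x <- function(vol3d, shift_px, fill = 0) {
  k <- as.integer(round(shift_px))
  if (k == 0) return(vol3d)
  d <- dim(vol3d)
  out <- array(fill, dim = d)
  if (abs(k) >= d[1]) return(out)
  if (k > 0) {
    out[(k + 1):d[1], , ] <- vol3d[1:(d[1] - k), , ]
  } else {
    out[1:(d[1] + k), , ] <- vol3d[(1 - k):d[1], , ]
  }
  out
}

# shift a decay by moving fraction toward the longest component (or the
# lifetime itself when mono-exponential), targeting a mean-lifetime change
# of `shift_ps` at activation 1
shift_decay <- function(decay, shift_ps, activation) {
  if (activation <= 0 || shift_ps == 0) return(decay)
  if (length(decay$fractions) == 1L) {
    return(decay_spec(1, max(decay$lifetimes_ps + shift_ps * activation, 0)))
  }
  i_lo <- which.min(decay$lifetimes_ps)
  i_hi <- which.max(decay$lifetimes_ps)
  span <- decay$lifetimes_ps[i_hi] - decay$lifetimes_ps[i_lo]
  if (span <= 0) return(decay)
  df <- activation * shift_ps / span
  fr <- decay$fractions
  df <- min(max(df, -fr[i_hi]), fr[i_lo])
  fr[i_lo] <- fr[i_lo] - df
  fr[i_hi] <- fr[i_hi] + df
  decay_spec(fr, decay$lifetimes_ps)
}

#' Simulate a dynamic acquisition time series
#'
#' Renders a stack of four-phase frames from a static labelled volume with
#' time-varying intensity (transients times photobleaching), transient
#' lifetime shifts (fraction shifts of the calcium-reporter decay), and
#' rigid lateral drift. Each frame is a full projection + acquisition;
#' everything is reproducible from `seed`.
#'
#' @param vol A [scene_volume()] with decays attached.
#' @param dynamics A [dynamics_spec()].
#' @param protocol,mod,err,noise Acquisition settings as in
#'   [simulate_acquisition()].
#' @param profile An [axial_profile()] for the volumetric projection.
#' @param n_frames_t Number of time points.
#' @param frame_interval_s Time between frames (s).
#' @param seed Integer seed.
#' @return An object of class `flim_timeseries`: list with `frames` (list of
#'   [four_phase_frame()]), `time_s`, and the generating settings.
#' @export
make_timeseries <- function(vol, dynamics, protocol, profile, mod,
                            err = instrument_error(), noise = noise_model(),
                            n_frames_t = 90L, frame_interval_s = 1,
                            seed = 1L) {
  if (!inherits(vol, "scene_volume")) stop("`vol` must be a scene_volume")
  if (!inherits(dynamics, "dynamics_spec")) {
    stop("`dynamics` must be a dynamics_spec")
  }
  time_s <- (seq_len(n_frames_t) - 1L) * frame_interval_s
  seeds <- derive_substream_seeds(seed, n_frames_t)
  frames <- vector("list", n_frames_t)
  for (i in seq_len(n_frames_t)) {
    t <- time_s[i]
    a <- transient_activation(dynamics, t)
    scale <- (1 + (dynamics$intensity_amplitude - 1) * a) *
      exp(-dynamics$bleaching_rate_per_s * t)
    shift <- dynamics$drift_px_per_s * t
    conc_t <- shift_volume_x(vol$concentration, shift) * scale
    lab_t <- shift_volume_x(vol$decay_label, shift, fill = 0L)
    table_t <- lapply(vol$decay_table, shift_decay,
                      shift_ps = dynamics$lifetime_shift_ps, activation = a)
    vol_t <- scene_volume(conc_t, lab_t, table_t,
                          z_spacing_um = vol$z_spacing_um,
                          check_labels = FALSE)
    map_t <- project_volume(vol_t, profile)
    frames[[i]] <- simulate_acquisition(map_t, protocol, mod, err = err,
                                        noise = noise, seed = seeds[i])
  }
  structure(
    list(frames = frames, time_s = time_s, dynamics = dynamics,
         protocol = protocol, seed = seed),
    class = "flim_timeseries"
  )
}

#' @export
print.flim_timeseries <- function(x, ...) {
  cat(sprintf("<flim_timeseries> %d frames, %.3g s span\n",
              length(x$frames), max(x$time_s)))
  invisible(x)
}
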
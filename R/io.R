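# Multi-channel 32-bit float TIFF I/O with a JSON sidecar. Each channel is
# stored as one TIFF page, rescaled into [0, 1]; the sidecar records channel
# names, per-channel ranges, NA handling and arbitrary metadata, making the
# round-trip lossless at 32-bit float precision.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a named channel stack to TIFF (+ JSON sidecar)
#'
#' @param bundle List with `channels` (named list of numeric matrices of a
#'   common shape) and optional `meta` (named list: protocol, seed,
#'   calibration state, ...).
#' @param path Output TIFF path; a sidecar `<path>.json` is written next to
#'   it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(bundle, path) {
  ch <- bundle$channels
  if (is.null(ch) || is.null(names(ch)) || any(names(ch) == "")) {
    stop("`bundle$channels` must be a fully named list of matrices")
  }
  shape <- dim(as.matrix(ch[[1L]]))
  pages <- vector("list", length(ch))
  ranges <- vector("list", length(ch))
  for (i in seq_along(ch)) {
    m <- as.matrix(ch[[i]])
    if (!identical(dim(m), shape)) stop("all channels must share shape")
    na_mask <- !is.finite(m)
    m[na_mask] <- 0
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    pages[[i]] <- (m - lo) / scale
    ranges[[i]] <- list(min = lo, max = hi, has_na = any(na_mask))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  side <- list(
    format = "fdflim-stack-v1",
    channels = names(ch),
    ranges = stats::setNames(ranges, names(ch)),
    shape = shape,
    meta = bundle$meta %||% list()
  )
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a channel stack written by [write_stack()]
#'
#' Channels are re-mapped by name from the sidecar, so any on-disk page
#' permutation recorded there is resolved. Sentinel-coded invalid pixels in
#' `g`/`s`-like channels are restored to `NA` using the `valid` channel when
#' present.
#'
#' @param path TIFF path with its `<path>.json` sidecar.
#' @return List with `channels` (named list of matrices) and `meta`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar_path(path))) {
    stop("missing sidecar: ", sidecar_path(path))
  }
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(side$channels)) {
    stop("sidecar lists ", length(side$channels), " channels but file has ",
         length(pages), " pages (found: ",
         paste(side$channels, collapse = ", "), ")")
  }
  ch <- vector("list", length(pages))
  names(ch) <- side$channels
  for (i in seq_along(pages)) {
    nm <- side$channels[i]
    r <- side$ranges[[nm]]
    ch[[i]] <- pages[[i]] * (if (r$max > r$min) r$max - r$min else 1) + r$min
  }
  if (!is.null(ch$valid)) {
    mask <- ch$valid < 0.5
    for (nm in intersect(names(ch), c("g", "s", "tau_phi_ps", "tau_mod_ps"))) {
      ch[[nm]][mask] <- NA_real_
    }
  }
  list(channels = ch, meta = side$meta)
}

#' Serialise phasor / lifetime / frame objects to channel bundles
#'
#' @param x A [phasor_field()], lifetime field, or [four_phase_frame()].
#' @param ... Extra metadata merged into the bundle's `meta`.
#' @return A bundle suitable for [write_stack()].
#' @export
as_stack_bundle <- function(x, ...) UseMethod("as_stack_bundle")

#' @export
as_stack_bundle.phasor_field <- function(x, ...) {
  list(
    channels = list(
      intensity = x$intensity %||% matrix(0, nrow(x$g), ncol(x$g)),
      g = x$g, s = x$s, valid = x$valid * 1
    ),
    meta = c(list(kind = "phasor_field", calibrated = x$calibrated),
             list(...))
  )
}

#' @export
as_stack_bundle.lifetime_field <- function(x, ...) {
  list(
    channels = list(tau_phi_ps = x$tau_phase, tau_mod_ps = x$tau_mod,
                    valid = x$valid * 1),
    meta = c(list(kind = "lifetime_field",
                  uncalibrated_input = x$uncalibrated_input), list(...))
  )
}

#' @export
as_stack_bundle.four_phase_frame <- function(x, ...) {
  list(
    channels = list(
      intensity = x$intensity_dc,
      mixer_0 = x$mixers[["0"]], mixer_90 = x$mixers[["90"]],
      mixer_180 = x$mixers[["180"]], mixer_270 = x$mixers[["270"]]
    ),
    meta = c(list(kind = "four_phase_frame",
                  dwell_time_us = x$dwell_time_us,
                  n_frames_averaged = x$n_frames_averaged), x$meta,
             list(...))
  )
}

#' Rebuild a four-phase frame from a read bundle
#'
#' @param bundle As returned by [read_stack()].
#' @return A [four_phase_frame()].
#' @export
bundle_to_frame <- function(bundle) {
  ch <- bundle$channels
  need <- c("intensity", "mixer_0", "mixer_90", "mixer_180", "mixer_270")
  if (!all(need %in% names(ch))) {
    stop("bundle lacks four-phase channels (found: ",
         paste(names(ch), collapse = ", "), ")")
  }
  four_phase_frame(
    ch$intensity,
    list(`0` = ch$mixer_0, `90` = ch$mixer_90, `180` = ch$mixer_180,
         `270` = ch$mixer_270),
    dwell_time_us = bundle$meta$dwell_time_us %||% NA_real_,
    n_frames_averaged = bundle$meta$n_frames_averaged %||% 1L,
    meta = bundle$meta
  )
}

#' Rebuild a phasor field from a read bundle
#'
#' @param bundle As returned by [read_stack()].
#' @return A [phasor_field()].
#' @export
bundle_to_phasor_field <- function(bundle) {
  ch <- bundle$channels
  if (!all(c("g", "s") %in% names(ch))) {
    stop("bundle lacks g/s channels (found: ",
         paste(names(ch), collapse = ", "), ")")
  }
  phasor_field(ch$g, ch$s,
               valid = if (!is.null(ch$valid)) ch$valid > 0.5 else NULL,
               intensity = ch$intensity,
               calibrated = isTRUE(bundle$meta$calibrated))
}
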
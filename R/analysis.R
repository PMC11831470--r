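#' 2D phasor histogram
#'
#' Counts valid, above-threshold pixels in bins over `g` in `[0, 1]` and `s`
#' in `[0, 0.7]`. Total counts equal the number of pixels that enter, so the
#' histogram is a faithful census of the phasor cloud; the universal
#' semicircle is attached as overlay metadata for plotting.
#'
#' @param field A calibrated [phasor_field()].
#' @param intensity Intensity image used for thresholding; defaults to the
#'   field's own intensity.
#' @param threshold Pixels at or below this intensity are excluded. Default:
#'   the background-masking floor of [default_intensity_floor()].
#' @param bins Number of bins per axis.
#' @return An object of class `phasor_histogram`: `counts` matrix
#'   (g-bins x s-bins), bin edges, threshold used, and `n_pixels`.
#' @export
phasor_histogram <- function(field, intensity = NULL, threshold = NULL,
                             bins = 256L) {
  if (!inherits(field, "phasor_field")) stop("`field` must be a phasor_field")
  intensity <- intensity %||% field$intensity
  keep <- field$valid
  if (!is.null(intensity)) {
    threshold <- threshold %||% default_intensity_floor(intensity)
    keep <- keep & intensity > threshold
  } else {
    threshold <- threshold %||% 0
  }
  g <- field$g[keep]; s <- field$s[keep]
  inside <- g >= 0 & g <= 1 & s >= 0 & s <= 0.7
  g <- g[inside]; s <- s[inside]
  if (length(g) == 0L) stop("no valid pixels above threshold")
  g_edges <- seq(0, 1, length.out = bins + 1L)
  s_edges <- seq(0, 0.7, length.out = bins + 1L)
  gi <- pmin(pmax(findInterval(g, g_edges, rightmost.closed = TRUE), 1L), bins)
  si <- pmin(pmax(findInterval(s, s_edges, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(gi, levels = seq_len(bins)),
               factor(si, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  structure(
    list(counts = counts, g_edges = g_edges, s_edges = s_edges,
         intensity_threshold = threshold, n_pixels = length(g)),
    class = "phasor_histogram"
  )
}

#' @export
print.phasor_histogram <- function(x, ...) {
  cat(sprintf("<phasor_histogram> %d x %d bins, %d pixels\n",
              nrow(x$counts), ncol(x$counts), x$n_pixels))
  invisible(x)
}

#' Elliptical phasor gate
#'
#' @param g0,s0 Centre of the ellipse in phasor coordinates.
#' @param rg,rs Semi-axes along g and s (> 0).
#' @param angle_rad Rotation of the ellipse.
#' @return An object of class `phasor_gate`.
#' @export
phasor_gate <- function(g0, s0, rg, rs, angle_rad = 0) {
  if (rg <= 0 || rs <= 0) stop("gate semi-axes must be > 0")
  structure(list(g0 = g0, s0 = s0, rg = rg, rs = rs,
                 angle_rad = angle_rad),
            class = "phasor_gate")
}

gate_contains <- function(gate, g, s) {
  ca <- cos(gate$angle_rad); sa <- sin(gate$angle_rad)
  dg <- g - gate$g0; ds <- s - gate$s0
  u <- ca * dg + sa * ds
  v <- -sa * dg + ca * ds
  (u / gate$rg)^2 + (v / gate$rs)^2 <= 1
}

#' Phasor-gated segmentation ("phasor-labelled image")
#'
#' Labels each valid pixel by the first gate containing its phasor (gates
#' may overlap; priority follows list order), 0 elsewhere — the standard way
#' of mapping phasor-plot clusters back onto the image.
#'
#' @param field A calibrated [phasor_field()].
#' @param gates Non-empty list of [phasor_gate()] ellipses.
#' @return Integer label matrix.
#' @export
segment_by_phasor <- function(field, gates) {
  if (!inherits(field, "phasor_field")) stop("`field` must be a phasor_field")
  if (!is.list(gates) || length(gates) == 0L) {
    stop("`gates` must be a non-empty list of phasor_gate")
  }
  labels <- matrix(0L, nrow(field$g), ncol(field$g))
  unassigned <- field$valid
  for (i in seq_along(gates)) {
    gt <- gates[[i]]
    if (!inherits(gt, "phasor_gate")) stop("gate ", i, " is not a phasor_gate")
    hit <- unassigned & gate_contains(gt, field$g, field$s)
    hit[is.na(hit)] <- FALSE
    if (!any(hit)) warning("gate ", i, " matched no pixels")
    labels[hit] <- i
    unassigned <- unassigned & !hit
  }
  labels
}

#' Lorentzian (Cauchy) fit of a lifetime histogram
#'
#' Nonlinear least-squares fit of `A * gamma^2 / ((x - x0)^2 + gamma^2)` to
#' a lifetime distribution histogram, reporting the peak position `x0`, the
#' half-width `gamma`, and the residual mean squared error — the basis of
#' the "peak / MSE" summary convention for lifetime distributions. Because
#' that convention is ambiguous between the residual and the width, both
#' `gamma` and `mse` are returned; `format()` prints "peak/width" with width
#' `gamma`, whose magnitude matches the convention's second number.
#'
#' @param lifetimes_ps Either a numeric vector of lifetimes (histogrammed
#'   internally) or a list/data.frame with `mids` and `counts`.
#' @param bins Number of histogram bins when a raw vector is given.
#' @return An object of class `lorentz_fit`: `peak_ps`, `gamma_ps`, `mse`,
#'   `fitted`, and the histogram used.
#' @export
lorentz_fit <- function(lifetimes_ps, bins = 64L) {
  if (is.numeric(lifetimes_ps)) {
    v <- lifetimes_ps[is.finite(lifetimes_ps)]
    if (length(v) < 10L) stop("need at least 10 lifetime values")
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    mids <- h$mids
    counts <- h$counts
  } else {
    mids <- lifetimes_ps$mids
    counts <- lifetimes_ps$counts
  }
  if (sum(counts > 0) < 5L) stop("need >= 5 non-empty histogram bins")
  df <- data.frame(x = mids, y = counts)
  start <- list(A = max(counts),
                x0 = mids[which.max(counts)],
                gamma = max(diff(range(mids)) / 10, diff(mids)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * gamma^2 / ((x - x0)^2 + gamma^2),
      data = df, start = start,
      lower = c(A = 0, x0 = min(mids), gamma = diff(mids)[1] / 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("Lorentzian fit did not converge (start: A=", signif(start$A, 4),
           ", x0=", signif(start$x0, 6), ", gamma=", signif(start$gamma, 4),
           "): ", conditionMessage(e))
    }
  )
  cf <- stats::coef(fit)
  structure(
    list(peak_ps = unname(cf["x0"]), gamma_ps = unname(cf["gamma"]),
         amplitude = unname(cf["A"]),
         mse = mean(stats::residuals(fit)^2),
         mids = mids, counts = counts,
         fitted = stats::fitted(fit)),
    class = "lorentz_fit"
  )
}

#' @export
format.lorentz_fit <- function(x, ...) {
  sprintf("%.0f/%.0f ps", x$peak_ps, x$gamma_ps)
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat(sprintf("<lorentz_fit> peak/width %s (residual MSE %.4g)\n",
              format(x), x$mse))
  invisible(x)
}

#' Fractional fluorescence change (dF/F)
#'
#' `(F - F0) / F0` per time point, with the baseline `F0` the initial
#' fluorescence intensity value (or, optionally, the median of the first
#' `baseline_k` points for robustness). Optionally returns a fifth-order
#' polynomial least-squares fit of the trace.
#'
#' @param intensity Numeric vector of fluorescence intensity over time.
#' @param time_s Optional time axis (defaults to 0, 1, 2, ...).
#' @param baseline `"first"` (the definition) or `"median_k"`.
#' @param baseline_k Number of initial points for the robust baseline.
#' @param fit_polynomial Fit and return a degree-5 polynomial?
#' @return A data.frame with `time_s`, `intensity`, `dff`, and (if
#'   requested) `dff_fit`; the polynomial coefficients are attached as
#'   attribute `"poly_coef"`.
#' @export
delta_f_over_f <- function(intensity, time_s = NULL,
                           baseline = c("first", "median_k"),
                           baseline_k = 5L, fit_polynomial = FALSE) {
  baseline <- match.arg(baseline)
  time_s <- time_s %||% (seq_along(intensity) - 1)
  f0 <- switch(baseline,
               first = intensity[1L],
               median_k = stats::median(utils::head(intensity, baseline_k)))
  if (!is.finite(f0) || f0 <= 0) stop("baseline fluorescence must be > 0")
  dff <- (intensity - f0) / f0
  out <- data.frame(time_s = time_s, intensity = intensity, dff = dff)
  if (fit_polynomial) {
    fit <- stats::lm(dff ~ stats::poly(time_s, 5, raw = TRUE))
    out$dff_fit <- stats::fitted(fit)
    attr(out, "poly_coef") <- unname(stats::coef(fit))
  }
  out
}

#' Smooth a time trace (mean filter + second-order polynomial)
#'
#' Two-stage smoothing of noisy traces: a 9-point moving average (4
#' neighbours on each side, shrinking symmetric window at the edges)
#' followed by a second-order Savitzky-Golay polynomial smoothing pass.
#'
#' @param trace Numeric vector, length >= 9.
#' @param sg_window Odd window length of the polynomial stage.
#' @param normalize Rescale the result to `[0, 1]`?
#' @param poly_stage Apply the second-order polynomial stage (disable to
#'   inspect the plain moving-average output)?
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_trace <- function(trace, sg_window = 9L, normalize = FALSE,
                         poly_stage = TRUE) {
  n <- length(trace)
  if (n < 9L) stop("trace must have length >= 9")
  half <- 4L
  avg <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)   # shrink symmetrically at edges
    mean(trace[(i - k):(i + k)])
  }, numeric(1))
  if (!poly_stage) {
    out <- avg
  } else {
    if (sg_window %% 2L == 0L) sg_window <- sg_window + 1L
    sg_window <- min(sg_window, if (n %% 2L == 0L) n - 1L else n)
    out <- signal::sgolayfilt(avg, p = 2, n = sg_window)
  }
  if (normalize) {
    rng <- range(out)
    if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  }
  out
}

#' Kymograph of a time series over an ROI
#'
#' Stacks a per-time-point summary (mean phase lifetime or mean intensity
#' over the ROI columns) into a time x position matrix, the standard
#' rendering of per-cell lifetime/intensity dynamics.
#'
#' @param stack A `flim_timeseries` (from [make_timeseries()]) or a list of
#'   [four_phase_frame()].
#' @param roi Logical matrix (frame shape) selecting the ROI, or a list
#'   `list(rows =, cols =)` of index vectors.
#' @param what `"tau_phase"` or `"intensity"`.
#' @param mod Required [modulation_context()] when `what = "tau_phase"`.
#' @param cal Optional [calibration_factors()] applied before lifetimes.
#' @return Numeric matrix, rows = time points, columns = ROI columns
#'   (position axis); attribute `"time_s"` carries the time axis if known.
#' @export
kymograph <- function(stack, roi, what = c("tau_phase", "intensity"),
                      mod = NULL, cal = NULL) {
  what <- match.arg(what)
  time_s <- NULL
  if (inherits(stack, "flim_timeseries")) {
    time_s <- stack$time_s
    frames <- stack$frames
  } else {
    frames <- stack
  }
  if (length(frames) == 0L) stop("empty stack")
  shape <- dim(frames[[1L]]$intensity_dc)
  if (is.list(roi) && !is.matrix(roi)) {
    mask <- matrix(FALSE, shape[1], shape[2])
    mask[roi$rows, roi$cols] <- TRUE
  } else {
    mask <- as.matrix(roi)
  }
  if (!identical(dim(mask), shape)) stop("ROI shape does not match frames")
  if (!any(mask)) stop("ROI is empty")
  cols <- which(colSums(mask) > 0)
  rows_out <- matrix(NA_real_, length(frames), length(cols))
  for (i in seq_along(frames)) {
    if (what == "intensity") {
      img <- frames[[i]]$intensity_dc
      valid <- matrix(TRUE, shape[1], shape[2])
    } else {
      if (is.null(mod)) stop("`mod` is required for lifetime kymographs")
      pf <- demodulate_four_phase(frames[[i]])
      if (!is.null(cal)) {
        pf <- apply_calibration(pf, cal)
        lf <- lifetimes_from_phasor(pf, mod)
      } else {
        pf$calibrated <- TRUE  # identity-calibrated chain
        lf <- lifetimes_from_phasor(pf, mod)
      }
      img <- lf$tau_phase
      valid <- lf$valid
    }
    for (j in seq_along(cols)) {
      sel <- mask[, cols[j]] & valid[, cols[j]]
      rows_out[i, j] <- if (any(sel)) mean(img[sel, cols[j]]) else NA_real_
    }
  }
  attr(rows_out, "time_s") <- time_s
  rows_out
}
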
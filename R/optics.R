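#' Excitation beam specification
#'
#' Describes the focal beam used for two-photon excitation: either a
#' Gaussian focus characterised by objective NA, wavelength and immersion
#' index, or an axicon-generated Bessel focus characterised by its extended
#' depth of field. Defaults: 0.75 NA / 920 nm Gaussian, 35 um Bessel DOF
#' (the volumetric brain-imaging setting); `dof_length_um = 15` is the
#' whole-cell imaging preset.
#'
#' @param kind `"gaussian"` or `"bessel"`.
#' @param numerical_aperture Objective NA (Gaussian), 0 < NA < n.
#' @param wavelength_nm Excitation wavelength in nm.
#' @param refractive_index Immersion refractive index.
#' @param dof_length_um Bessel flat-top depth of field in um (its FWHM by
#'   construction).
#' @param edge_softness_um Width of the raised-cosine edges of the Bessel
#'   flat-top, in um.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(kind = c("gaussian", "bessel"),
                      numerical_aperture = 0.75, wavelength_nm = 920,
                      refractive_index = 1, dof_length_um = 35,
                      edge_softness_um = 2) {
  kind <- match.arg(kind)
  if (wavelength_nm <= 0) stop("`wavelength_nm` must be > 0")
  if (kind == "gaussian") {
    if (numerical_aperture <= 0 || numerical_aperture >= refractive_index) {
      stop("need 0 < NA < refractive_index")
    }
  } else {
    if (dof_length_um <= 0) stop("`dof_length_um` must be > 0")
    if (edge_softness_um < 0) stop("`edge_softness_um` must be >= 0")
  }
  structure(
    list(kind = kind, numerical_aperture = numerical_aperture,
         wavelength_nm = wavelength_nm, refractive_index = refractive_index,
         dof_length_um = dof_length_um, edge_softness_um = edge_softness_um),
    class = "beam_spec"
  )
}

#' Normalised axial excitation profile
#'
#' Two-photon excitation weight versus axial position z, normalised to a
#' maximum of 1.
#'
#' @param z_um Strictly increasing numeric vector of axial positions (um).
#' @param weight Weights in `[0, 1]` with maximum 1.
#' @return An object of class `axial_profile`.
#' @export
axial_profile <- function(z_um, weight) {
  z_um <- as.numeric(z_um); weight <- as.numeric(weight)
  if (length(z_um) != length(weight)) stop("z and weight lengths differ")
  if (any(diff(z_um) <= 0)) stop("`z_um` must be strictly increasing")
  if (any(weight < -1e-12) || abs(max(weight) - 1) > 1e-9) {
    stop("weights must lie in [0, 1] with max 1")
  }
  structure(list(z_um = z_um, weight = pmin(pmax(weight, 0), 1)),
            class = "axial_profile")
}

#' Gaussian-focus two-photon axial profile
#'
#' On-axis focal intensity from the scalar paraxial pupil integral
#' `A(u) = int_0^1 exp(i u rho^2 / 2) rho d_rho` with defocus parameter
#' `u = 2 pi NA^2 z / (lambda n)`; the two-photon excitation weight is the
#' squared normalised intensity `(|A|^2 / |A(0)|^2)^2` (analytically
#' `sinc^4(u/4)` around focus). At 0.75 NA and 920 nm this gives an axial
#' FWHM of about 2.1 um.
#'
#' @param spec A Gaussian [beam_spec()].
#' @param z_um Axial grid in um.
#' @param n_pupil Number of pupil quadrature nodes.
#' @return An [axial_profile()].
#' @export
gaussian_axial_profile <- function(spec, z_um, n_pupil = 2048L) {
  if (!inherits(spec, "beam_spec") || spec$kind != "gaussian") {
    stop("`spec` must be a gaussian beam_spec")
  }
  lambda_um <- spec$wavelength_nm * 1e-3
  u <- 2 * pi * spec$numerical_aperture^2 * z_um /
    (lambda_um * spec$refractive_index)
  # midpoint rule over the pupil radius
  rho <- (seq_len(n_pupil) - 0.5) / n_pupil
  drho <- 1 / n_pupil
  ph <- exp(1i * outer(u / 2, rho^2)) * rep(rho * drho, each = length(u))
  amp <- rowSums(ph)
  intensity <- Mod(amp)^2
  i0 <- (sum(rho * drho))^2  # u = 0 reference
  w <- (intensity / i0)^2
  axial_profile(z_um, w / max(w))
}

#' Bessel-focus axial profile
#'
#' Parametric flat-top of length `dof_length_um` with raised-cosine edges of
#' width `edge_softness_um`; the half-maximum points sit exactly at
#' `+/- dof_length_um / 2`, so the FWHM equals the DOF by construction.
#' Axial sidelobes of real axicon beams are neglected.
#'
#' @param spec A Bessel [beam_spec()].
#' @param z_um Axial grid in um.
#' @return An [axial_profile()].
#' @export
bessel_axial_profile <- function(spec, z_um) {
  if (!inherits(spec, "beam_spec") || spec$kind != "bessel") {
    stop("`spec` must be a bessel beam_spec")
  }
  L <- spec$dof_length_um
  wdt <- spec$edge_softness_um
  az <- abs(z_um)
  if (wdt == 0) {
    w <- as.numeric(az <= L / 2)
  } else {
    inner <- L / 2 - wdt / 2
    w <- ifelse(az <= inner, 1,
                ifelse(az >= inner + wdt, 0,
                       0.5 * (1 + cos(pi * (az - inner) / wdt))))
  }
  if (max(w) <= 0) stop("z grid does not cover the Bessel flat-top")
  axial_profile(z_um, w / max(w))
}

#' Full width at half maximum of an axial profile
#'
#' Linear-interpolated width between the two half-maximum crossings around
#' the profile's maximum.
#'
#' @param profile An [axial_profile()].
#' @return FWHM in um.
#' @export
axial_fwhm <- function(profile) {
  if (!inherits(profile, "axial_profile")) stop("expected an axial_profile")
  z <- profile$z_um; w <- profile$weight
  half <- max(w) / 2
  imax <- which.max(w)
  cross_left <- NA_real_
  if (imax >= 2L) {
    for (i in seq(imax, 2L, by = -1L)) {
      if (w[i - 1L] < half && w[i] >= half) {
        cross_left <- z[i - 1L] + (half - w[i - 1L]) / (w[i] - w[i - 1L]) *
          (z[i] - z[i - 1L])
        break
      }
    }
  }
  cross_right <- NA_real_
  if (imax < length(w)) {
    for (i in seq(imax, length(w) - 1L)) {
      if (w[i] >= half && w[i + 1L] < half) {
        cross_right <- z[i] + (w[i] - half) / (w[i] - w[i + 1L]) *
          (z[i + 1L] - z[i])
        break
      }
    }
  }
  if (!is.finite(cross_left) || !is.finite(cross_right)) {
    stop("no half-maximum crossing within the z grid; extend z_grid")
  }
  cross_right - cross_left
}

#' 3D scene volume
#'
#' Concentration (photons per us per voxel at unit excitation) on a regular
#' grid, a label volume assigning each voxel to a region, and a table of
#' per-region decays. The axial grid is centred on the focal plane.
#'
#' @param concentration Numeric 3D array `[x, y, z]`, >= 0.
#' @param decay_label Integer 3D array of region ids (0 = empty background).
#' @param decay_table Named list mapping label id (as character) to
#'   [decay_spec()].
#' @param z_spacing_um Axial voxel spacing in um.
#' @param check_labels Require every non-zero label to have a decay (set
#'   `FALSE` for freshly generated phantoms whose decays are attached later
#'   with [assign_lifetimes()]).
#' @return An object of class `scene_volume`.
#' @export
scene_volume <- function(concentration, decay_label, decay_table,
                         z_spacing_um = 1, check_labels = TRUE) {
  concentration <- as.array(concentration)
  decay_label <- as.array(decay_label)
  if (!identical(dim(concentration), dim(decay_label))) {
    stop("concentration and decay_label must share shape")
  }
  if (length(dim(concentration)) != 3L) stop("volumes must be 3D")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  if (check_labels) {
    labs <- setdiff(sort(unique(as.integer(decay_label))), 0L)
    missing <- setdiff(as.character(labs), names(decay_table))
    if (length(missing)) {
      stop("labels without a decay_spec: ", paste(missing, collapse = ", "))
    }
  }
  for (d in decay_table) {
    if (!inherits(d, "decay_spec")) stop("decay_table entries must be decay_spec")
  }
  structure(
    list(concentration = concentration, decay_label = decay_label,
         decay_table = decay_table, z_spacing_um = z_spacing_um),
    class = "scene_volume"
  )
}

# centred axial coordinates of a volume (um)
volume_z_um <- function(vol) {
  nz <- dim(vol$concentration)[3L]
  (seq_len(nz) - (nz + 1) / 2) * vol$z_spacing_um
}

#' Project a 3D volume through an axial excitation profile
#'
#' Collapses the volume into the 2D emission map the projection microscope
#' records: per pixel, `photon_rate = sum_z w(z) concentration(x, y, z)` and
#' the effective decay is the union of contributing components with
#' fractions proportional to `w(z) * concentration * fraction`, renormalised
#' — so the projected phasor is the intensity-weighted mean of voxel
#' phasors.
#'
#' @param vol A [scene_volume()].
#' @param profile An [axial_profile()]; interpolated onto the volume's z
#'   grid (zero outside its support).
#' @return An [emission_map()].
#' @export
project_volume <- function(vol, profile) {
  if (!inherits(vol, "scene_volume")) stop("`vol` must be a scene_volume")
  if (!inherits(profile, "axial_profile")) {
    stop("`profile` must be an axial_profile")
  }
  zv <- volume_z_um(vol)
  wz <- stats::approx(profile$z_um, profile$weight, xout = zv,
                      yleft = 0, yright = 0)$y
  if (all(wz <= 0)) stop("profile and volume z ranges do not overlap")

  labs <- setdiff(sort(unique(as.integer(vol$decay_label))), 0L)
  basis <- sort(unique(unlist(lapply(vol$decay_table[as.character(labs)],
                                     `[[`, "lifetimes_ps"))))
  if (length(basis) == 0L) basis <- 0
  # label x basis fraction matrix (row 1 = background, zero emission)
  fmat <- matrix(0, length(labs) + 1L, length(basis))
  for (i in seq_along(labs)) {
    d <- vol$decay_table[[as.character(labs[i])]]
    for (j in seq_along(d$fractions)) {
      col <- match(d$lifetimes_ps[j], basis)
      fmat[i + 1L, col] <- fmat[i + 1L, col] + d$fractions[j]
    }
  }
  lab_index <- match(as.integer(vol$decay_label), labs, nomatch = 0L) + 1L
  d <- dim(vol$concentration)
  rate <- matrix(0, d[1], d[2])
  comp <- array(0, dim = c(d[1], d[2], length(basis)))
  for (iz in seq_len(d[3])) {
    if (wz[iz] <= 0) next
    cz <- wz[iz] * vol$concentration[, , iz]
    rate <- rate + cz
    li <- matrix(lab_index[((iz - 1) * d[1] * d[2] + 1):(iz * d[1] * d[2])],
                 d[1], d[2])
    for (j in seq_along(basis)) {
      fj <- matrix(fmat[li, j], d[1], d[2])
      comp[, , j] <- comp[, , j] + cz * fj
    }
  }
  tot <- rate
  tot[tot <= 0] <- 1
  for (j in seq_along(basis)) comp[, , j] <- comp[, , j] / tot
  emission_map(rate, basis, comp)
}
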
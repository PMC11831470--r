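#' Synthetic scene specification
#'
#' Parameters of the seeded 3D phantom generators that stand in for stained
#' cells and vessels: mitochondria-like rods, network-like connected
#' skeletons, branching vessels, and somata with processes. Each generated
#' object carries its own label so lifetimes can be assigned per object or
#' per population.
#'
#' @param phantom_kind One of `"rods"`, `"network"`, `"vessels"`, `"somata"`.
#' @param field_size Lateral size in pixels (square).
#' @param depth_um Axial extent of the volume in um.
#' @param density Objects per 100 x 100 pixel tile (> 0).
#' @param z_spacing_um Axial voxel spacing in um.
#' @param base_rate Peak photon rate of an object, photons/us/pixel at unit
#'   excitation.
#' @param seed Integer seed making the phantom a pure function of the spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(phantom_kind = c("rods", "network", "vessels",
                                        "somata"),
                       field_size = 64L, depth_um = 20, density = 8,
                       z_spacing_um = 2, base_rate = 50, seed = 1L) {
  phantom_kind <- match.arg(phantom_kind)
  if (!is.numeric(density) || density <= 0) stop("`density` must be > 0")
  if (depth_um <= 0 || z_spacing_um <= 0) stop("depth and z spacing must be > 0")
  structure(
    list(phantom_kind = phantom_kind, field_size = as.integer(field_size),
         depth_um = depth_um, density = density,
         z_spacing_um = z_spacing_um, base_rate = base_rate,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# soft-edged capsule: add concentration of a segment p1-p2 (voxel coords,
# z in voxel units) with radius r into acc, returning updated list
add_capsule <- function(acc, lab, p1, p2, radius, rate, id, edge = 1) {
  d <- dim(acc)
  ax <- p2 - p1
  len2 <- sum(ax^2)
  # bounding box to keep the distance computation local
  lo <- pmax(floor(pmin(p1, p2) - radius - edge - 1), c(1, 1, 1))
  hi <- pmin(ceiling(pmax(p1, p2) + radius + edge + 1), d)
  if (any(lo > hi)) return(list(conc = acc, lab = lab))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- array(xs, dim = c(length(xs), length(ys), length(zs)))
  gy <- array(rep(ys, each = length(xs)),
              dim = c(length(xs), length(ys), length(zs)))
  gz <- array(rep(zs, each = length(xs) * length(ys)),
              dim = c(length(xs), length(ys), length(zs)))
  if (len2 == 0) {
    dist <- sqrt((gx - p1[1])^2 + (gy - p1[2])^2 + (gz - p1[3])^2)
  } else {
    t_par <- ((gx - p1[1]) * ax[1] + (gy - p1[2]) * ax[2] +
                (gz - p1[3]) * ax[3]) / len2
    t_par <- pmin(pmax(t_par, 0), 1)
    dist <- sqrt((gx - (p1[1] + t_par * ax[1]))^2 +
                   (gy - (p1[2] + t_par * ax[2]))^2 +
                   (gz - (p1[3] + t_par * ax[3]))^2)
  }
  w <- pmin(pmax((radius + edge - dist) / edge, 0), 1)
  sub <- acc[xs, ys, zs, drop = FALSE]
  labsub <- lab[xs, ys, zs, drop = FALSE]
  newc <- rate * w
  take <- newc > sub
  sub[take] <- newc[take]
  labsub[take] <- id
  acc[xs, ys, zs] <- sub
  lab[xs, ys, zs] <- labsub
  list(conc = acc, lab = lab)
}

#' Generate a 3D phantom volume
#'
#' Seeded, reproducible generator mapping a [scene_spec()] to a
#' [scene_volume()]. Object count is Poisson-free: `round(density *
#' (field_size/100)^2)`, at least one object. Every object gets its own
#' label; decays are attached afterwards with [assign_lifetimes()].
#'
#' @param spec A [scene_spec()].
#' @return A [scene_volume()] whose decay table is empty (attach with
#'   [assign_lifetimes()]).
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("`spec` must be a scene_spec")
  n <- spec$field_size
  nz <- max(3L, as.integer(round(spec$depth_um / spec$z_spacing_um)))
  n_obj <- max(1L, as.integer(round(spec$density * (n / 100)^2)))
  conc <- array(0, dim = c(n, n, nz))
  lab <- array(0L, dim = c(n, n, nz))
  with_local_seed(spec$seed, {
    id <- 0L
    for (k in seq_len(n_obj)) {
      id <- id + 1L
      ctr <- c(stats::runif(2, 4, n - 3), stats::runif(1, 1.5, nz - 0.5))
      rate <- spec$base_rate * stats::runif(1, 0.7, 1.3)
      res <- switch(
        spec$phantom_kind,
        rods = {
          len <- stats::runif(1, 0.08, 0.2) * n
          dir3 <- stats::rnorm(3); dir3[3] <- dir3[3] * 0.3
          dir3 <- dir3 / sqrt(sum(dir3^2))
          add_capsule(conc, lab, ctr - dir3 * len / 2, ctr + dir3 * len / 2,
                      radius = stats::runif(1, 1.2, 2.2), rate, id)
        },
        network = {
          # short random walk of connected tubes
          nseg <- sample(3:5, 1)
          p <- ctr
          r <- list(conc = conc, lab = lab)
          for (sgg in seq_len(nseg)) {
            step <- stats::rnorm(3, sd = c(n, n, nz) * 0.08)
            q <- pmin(pmax(p + step, c(2, 2, 1)), c(n - 1, n - 1, nz))
            r <- add_capsule(r$conc, r$lab, p, q, radius = 1.4, rate, id)
            p <- q
          }
          r
        },
        vessels = {
          # trunk with two daughter branches, shrinking radius
          dir3 <- stats::rnorm(3); dir3[3] <- dir3[3] * 0.2
          dir3 <- dir3 / sqrt(sum(dir3^2))
          len <- stats::runif(1, 0.15, 0.3) * n
          tip <- ctr + dir3 * len
          r <- add_capsule(conc, lab, ctr, tip, radius = 2.5, rate, id)
          for (b in 1:2) {
            bd <- dir3 + stats::rnorm(3, sd = 0.5)
            bd <- bd / sqrt(sum(bd^2))
            r <- add_capsule(r$conc, r$lab, tip, tip + bd * len * 0.6,
                             radius = 1.6, rate, id)
          }
          r
        },
        somata = {
          rad <- stats::runif(1, 0.04, 0.08) * n
          r <- add_capsule(conc, lab, ctr, ctr, radius = rad, rate, id)
          for (b in seq_len(sample(2:4, 1))) {
            bd <- stats::rnorm(3); bd[3] <- bd[3] * 0.3
            bd <- bd / sqrt(sum(bd^2))
            r <- add_capsule(r$conc, r$lab, ctr + bd * rad,
                             ctr + bd * (rad + stats::runif(1, 0.1, 0.25) * n),
                             radius = 1.0, rate * 0.8, id)
          }
          r
        }
      )
      conc <- res$conc
      lab <- res$lab
    }
  })
  scene_volume(conc, lab, stats::setNames(list(), character()),
               z_spacing_um = spec$z_spacing_um, check_labels = FALSE)
}

#' Attach decays to the labelled regions of a volume
#'
#' @param vol A [scene_volume()].
#' @param table Either a single [decay_spec()] applied to every label, or a
#'   named list mapping label id (as character) to [decay_spec()]. Every
#'   label present in the volume must be covered.
#' @return The volume with its decay table set.
#' @export
assign_lifetimes <- function(vol, table) {
  if (!inherits(vol, "scene_volume")) stop("`vol` must be a scene_volume")
  labs <- setdiff(sort(unique(as.integer(vol$decay_label))), 0L)
  if (inherits(table, "decay_spec")) {
    table <- stats::setNames(rep(list(table), length(labs)),
                             as.character(labs))
  }
  missing <- setdiff(as.character(labs), names(table))
  if (length(missing)) {
    stop("no decay_spec for labels: ", paste(missing, collapse = ", "))
  }
  scene_volume(vol$concentration, vol$decay_label, table,
               z_spacing_um = vol$z_spacing_um)
}

#' Two-state calcium-reporter decay
#'
#' Standard frequency-domain treatment of a calcium indicator: a mixture of
#' a free (short-lifetime) and a calcium-bound (long-lifetime) state whose
#' bound intensity fraction encodes the calcium level. The endpoint
#' lifetimes default to 500 and 3500 ps; these are configurable placeholders
#' for the reporter's true endpoints, not measured values.
#'
#' @param bound_fraction Intensity fraction of the bound (long) state.
#' @param tau_free_ps,tau_bound_ps Endpoint lifetimes (ps).
#' @return A [decay_spec()].
#' @export
calcium_decay <- function(bound_fraction, tau_free_ps = 500,
                          tau_bound_ps = 3500) {
  if (bound_fraction < 0 || bound_fraction > 1) {
    stop("`bound_fraction` must be in [0, 1]")
  }
  decay_spec(c(1 - bound_fraction, bound_fraction),
             c(tau_free_ps, tau_bound_ps))
}

#' Mono-exponential presets for common reporters
#'
#' Placeholder mono-exponential lifetimes for scene presets (eGFP 2600 ps,
#' SR101 4300 ps, FITC 4000 ps). These defaults are conventional stand-ins,
#' not measured two-photon in-vivo values; override freely.
#'
#' @param name One of `"egfp"`, `"sr101"`, `"fitc"`.
#' @param tau_ps Optional lifetime override (ps).
#' @return A [decay_spec()].
#' @export
reporter_decay <- function(name = c("egfp", "sr101", "fitc"),
                           tau_ps = NULL) {
  name <- match.arg(name)
  default <- c(egfp = 2600, sr101 = 4300, fitc = 4000)[[name]]
  decay_spec(1, tau_ps %||% default)
}
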
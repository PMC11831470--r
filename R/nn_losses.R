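#' Loss configuration for the restoration models
#'
#' Each image channel has exactly one primary loss: contextual-bilateral
#' (CoBi) for the `g` channel (robust to slight input/target misalignment)
#' and perceptual (feature-space) loss for the `s` and intensity channels.
#' Both are stabilised by a weighted pixel MAE term.
#'
#' @param channel_loss Named character vector mapping channel to loss kind.
#' @param cobi_spatial_weight Weight of the normalised spatial-distance term
#'   inside the CoBi patch match.
#' @param cobi_patch_size Side of the square raw-pixel patch features.
#' @param cobi_max_patches Patch-sampling budget per image.
#' @param perceptual_layer_ids Which extractor layers enter the feature
#'   distance (the default extractor has two convolutional layers).
#' @param pixel_term_weight Weight of the pixel MAE term added to either
#'   primary loss.
#' @param extractor_seed Seed of the fixed random-weight feature extractor
#'   (a random-projection perceptual loss; no pretrained weights needed).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(channel_loss = c(g = "cobi", s = "perceptual",
                                         intensity = "perceptual"),
                        cobi_spatial_weight = 0.1, cobi_patch_size = 3L,
                        cobi_max_patches = 256L,
                        perceptual_layer_ids = c(1L, 2L),
                        pixel_term_weight = 1,
                        extractor_seed = 99L) {
  if (!all(channel_loss %in% c("cobi", "perceptual"))) {
    stop("losses must be 'cobi' or 'perceptual'")
  }
  structure(
    list(channel_loss = channel_loss,
         cobi_spatial_weight = cobi_spatial_weight,
         cobi_patch_size = as.integer(cobi_patch_size),
         cobi_max_patches = as.integer(cobi_max_patches),
         perceptual_layer_ids = as.integer(perceptual_layer_ids),
         pixel_term_weight = pixel_term_weight,
         extractor_seed = as.integer(extractor_seed)),
    class = "loss_config"
  )
}

# ---- CoBi: contextual bilateral loss ---------------------------------------

# extract patch matrix [n_loc, p*p] at sampled locations (centres)
extract_patches <- function(img, locs, p) {
  half <- p %/% 2L
  n <- nrow(locs)
  out <- matrix(0, n, p * p)
  col <- 0L
  for (dj in -half:half) {
    for (di in -half:half) {
      col <- col + 1L
      out[, col] <- img[cbind(locs[, 1] + di, locs[, 2] + dj)]
    }
  }
  out
}

patch_grid <- function(d, p, max_patches, jitter = FALSE) {
  half <- p %/% 2L
  lo <- half + 1L
  hi_r <- d[1] - half; hi_c <- d[2] - half
  n_side <- ceiling(sqrt(max_patches))
  rows <- unique(round(seq(lo, hi_r, length.out = min(n_side, hi_r - lo + 1L))))
  cols <- unique(round(seq(lo, hi_c, length.out = min(n_side, hi_c - lo + 1L))))
  g <- as.matrix(expand.grid(rows, cols))
  if (jitter && nrow(g) > 0) {
    g[, 1] <- pmin(pmax(g[, 1] + sample(-1:1, nrow(g), TRUE), lo), hi_r)
    g[, 2] <- pmin(pmax(g[, 2] + sample(-1:1, nrow(g), TRUE), lo), hi_c)
  }
  if (nrow(g) > max_patches) g <- g[sample.int(nrow(g), max_patches), , drop = FALSE]
  g
}

cobi_core <- function(pred, target, cfg, want_grad = FALSE,
                      jitter = FALSE) {
  d <- dim(pred)
  p <- cfg$cobi_patch_size
  eps <- 1e-8
  locs_p <- patch_grid(d, p, cfg$cobi_max_patches, jitter = jitter)
  locs_t <- patch_grid(d, p, cfg$cobi_max_patches)
  P <- extract_patches(pred, locs_p, p)
  Tm <- extract_patches(target, locs_t, p)
  pn <- sqrt(rowSums(P^2)) + eps
  tn <- sqrt(rowSums(Tm^2)) + eps
  Pu <- P / pn
  Tu <- Tm / tn
  d_cos <- 1 - Pu %*% t(Tu)
  diag_len <- sqrt(sum((d - 1)^2))
  d_sp <- sqrt(outer(locs_p[, 1], locs_t[, 1], `-`)^2 +
                 outer(locs_p[, 2], locs_t[, 2], `-`)^2) / diag_len
  dtot <- d_cos + cfg$cobi_spatial_weight * d_sp
  jstar <- max.col(-dtot, ties.method = "first")
  loss <- mean(dtot[cbind(seq_len(nrow(P)), jstar)])
  if (!want_grad) return(list(loss = loss))
  # gradient of the cosine term through the matched target patches
  grad <- matrix(0, d[1], d[2])
  That <- Tu[jstar, , drop = FALSE]
  dot_pt <- rowSums(Pu * That)
  gP <- -(That - Pu * dot_pt) / pn / nrow(P)
  half <- p %/% 2L
  col <- 0L
  for (dj in -half:half) {
    for (di in -half:half) {
      col <- col + 1L
      idx <- cbind(locs_p[, 1] + di, locs_p[, 2] + dj)
      grad[idx] <- grad[idx] + gP[, col]
    }
  }
  list(loss = loss, grad = grad)
}

#' Contextual bilateral (CoBi) loss
#'
#' Patch-feature matching loss: for every sampled prediction patch, the
#' minimum over target patches of cosine feature distance plus a weighted
#' normalised spatial distance, averaged over prediction patches. Because
#' matches are free to move a little spatially, the loss tolerates the mild
#' misalignment between fast input and slow target acquisitions. Raw pixel
#' patches are the features; a pixel MAE term (weight
#' `pixel_term_weight`) stabilises training.
#'
#' @param pred,target Numeric matrices of equal shape.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar loss.
#' @export
cobi_loss <- function(pred, target, cfg = loss_config()) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!identical(dim(pred), dim(target))) stop("shapes differ")
  cobi_core(pred, target, cfg)$loss +
    cfg$pixel_term_weight * mean(abs(pred - target))
}

# ---- Perceptual loss through a fixed random-projection extractor -----------

extractor_cache <- new.env(parent = emptyenv())

perceptual_extractor <- function(seed) {
  key <- as.character(seed)
  if (!is.null(extractor_cache[[key]])) return(extractor_cache[[key]])
  rng <- he_rng()
  ext <- with_local_seed(seed, list(
    conv1 = conv_params(1L, 8L, rng),
    conv2 = conv_params(8L, 16L, rng)
  ))
  extractor_cache[[key]] <- ext
  ext
}

extractor_forward <- function(img, ext) {
  x <- as_cube(as.matrix(img))
  a1 <- conv_fwd(x, ext$conv1$w, ext$conv1$b)
  f1 <- relu_fwd(a1)
  a2 <- conv_fwd(f1, ext$conv2$w, ext$conv2$b)
  f2 <- relu_fwd(a2)
  list(x = x, a1 = a1, f1 = f1, a2 = a2, f2 = f2)
}

perceptual_core <- function(pred, target, cfg, want_grad = FALSE) {
  ext <- perceptual_extractor(cfg$extractor_seed)
  fp <- extractor_forward(pred, ext)
  ft <- extractor_forward(target, ext)
  layers <- cfg$perceptual_layer_ids
  feats <- list(`1` = "f1", `2` = "f2")
  loss <- 0
  gl <- list(`1` = NULL, `2` = NULL)
  for (l in layers) {
    fname <- feats[[as.character(l)]]
    diff <- fp[[fname]] - ft[[fname]]
    loss <- loss + mean(diff^2)
    if (want_grad) gl[[as.character(l)]] <- 2 * diff / length(diff)
  }
  loss <- loss / length(layers)
  if (!want_grad) return(list(loss = loss))
  g2 <- gl[["2"]]
  g1_direct <- gl[["1"]]
  gf1 <- NULL
  if (!is.null(g2)) {
    gb2 <- relu_bwd(fp$a2, g2 / length(layers))
    gf1 <- conv_bwd(fp$f1, ext$conv2$w, gb2)$gx
  }
  if (!is.null(g1_direct)) {
    add <- g1_direct / length(layers)
    gf1 <- if (is.null(gf1)) add else gf1 + add
  }
  gb1 <- relu_bwd(fp$a1, gf1)
  gx <- conv_bwd(fp$x, ext$conv1$w, gb1)$gx
  list(loss = loss, grad = gx[, , 1L])
}

#' Perceptual (feature-space) loss
#'
#' Mean squared distance between feature maps of a fixed, seeded
#' random-weight convolutional extractor (a random-projection perceptual
#' loss requiring no pretrained backbone), plus `pixel_term_weight` times
#' the pixel MAE.
#'
#' @inheritParams cobi_loss
#' @return Non-negative scalar loss; zero for identical images.
#' @export
perceptual_loss <- function(pred, target, cfg = loss_config()) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!identical(dim(pred), dim(target))) stop("shapes differ")
  perceptual_core(pred, target, cfg)$loss +
    cfg$pixel_term_weight * mean(abs(pred - target))
}

# loss value and gradient w.r.t. pred for one channel
channel_loss_grad <- function(pred, target, kind, cfg) {
  n <- length(pred)
  pix_g <- cfg$pixel_term_weight * sign(pred - target) / n
  pix_l <- cfg$pixel_term_weight * mean(abs(pred - target))
  if (kind == "cobi") {
    core <- cobi_core(pred, target, cfg, want_grad = TRUE, jitter = TRUE)
  } else {
    core <- perceptual_core(pred, target, cfg, want_grad = TRUE)
  }
  list(loss = core$loss + pix_l, grad = core$grad + pix_g)
}
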
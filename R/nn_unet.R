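#' Restoration network configuration
#'
#' An encoder-decoder (U-Net style) network with a convolutional block
#' attention module (CBAM) at every level, mapping an `H x W` single-channel
#' image to a denoised `2H x 2W` image. The 2x upsampling is performed by a
#' sub-pixel (pixel-shuffle) head added to a bicubic global skip, so the
#' network learns a residual correction.
#'
#' @param levels Encoder depth (number of pooling steps).
#' @param base_channels Channels of the first level; doubled per level.
#' @param cbam_reduction Channel-attention bottleneck reduction ratio.
#' @return An object of class `network_config`.
#' @export
network_config <- function(levels = 4L, base_channels = 32L,
                           cbam_reduction = 16L) {
  levels <- as.integer(levels)
  base_channels <- as.integer(base_channels)
  if (levels < 1L) stop("`levels` must be >= 1")
  if (base_channels < 1L) stop("`base_channels` must be >= 1")
  structure(
    list(levels = levels, base_channels = base_channels,
         cbam_reduction = as.integer(cbam_reduction),
         upsample_factor = 2L, in_channels = 1L, out_channels = 1L),
    class = "network_config"
  )
}

he_rng <- function() {
  function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))
}

conv_params <- function(cin, cout, rng, k = 3L, zero = FALSE) {
  fan_in <- k * k * cin
  w <- if (zero) matrix(0, fan_in, cout) else
    matrix(rng(fan_in * cout, fan_in), fan_in, cout)
  list(w = w, b = numeric(cout))
}

level_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$levels) - 1L)

#' Build a restoration network
#'
#' Deterministically initialises all weights from `seed` (He initialisation;
#' the residual head starts at zero so the untrained network reproduces the
#' bicubic upsample of its input).
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `flim_network`: `params` (named list of
#'   arrays), `cfg`, and `n_parameters`.
#' @export
build_network <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "network_config")) stop("`cfg` must be a network_config")
  rng <- he_rng()
  ch <- level_channels(cfg)
  params <- list()
  with_local_seed(seed, {
    cin <- cfg$in_channels
    for (i in seq_len(cfg$levels)) {
      params[[paste0("enc", i, "_conv1")]] <- conv_params(cin, ch[i], rng)
      params[[paste0("enc", i, "_conv2")]] <- conv_params(ch[i], ch[i], rng)
      params[[paste0("enc", i, "_cbam")]] <-
        cbam_params(ch[i], cfg$cbam_reduction, rng)
      cin <- ch[i]
    }
    cb <- ch[cfg$levels] * 2L
    params[["bot_conv1"]] <- conv_params(cin, cb, rng)
    params[["bot_conv2"]] <- conv_params(cb, cb, rng)
    params[["bot_cbam"]] <- cbam_params(cb, cfg$cbam_reduction, rng)
    cin <- cb
    for (i in rev(seq_len(cfg$levels))) {
      params[[paste0("dec", i, "_up")]] <- conv_params(cin, ch[i], rng)
      params[[paste0("dec", i, "_conv1")]] <- conv_params(2L * ch[i], ch[i], rng)
      params[[paste0("dec", i, "_conv2")]] <- conv_params(ch[i], ch[i], rng)
      params[[paste0("dec", i, "_cbam")]] <-
        cbam_params(ch[i], cfg$cbam_reduction, rng)
      cin <- ch[i]
    }
    params[["head_conv"]] <- conv_params(ch[1], 4L, rng, zero = TRUE)
  })
  n_par <- sum(vapply(unlist(params, recursive = FALSE),
                      function(a) length(a), numeric(1)))
  structure(list(params = params, cfg = cfg, n_parameters = n_par),
            class = "flim_network")
}

#' @export
print.flim_network <- function(x, ...) {
  cat(sprintf("<flim_network> %d level(s), base %d channels, %d parameters\n",
              x$cfg$levels, x$cfg$base_channels, x$n_parameters))
  invisible(x)
}

check_input_size <- function(cfg, d) {
  div <- 2^cfg$levels
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop("input size ", d[1], "x", d[2],
         " is not divisible by 2^levels = ", div)
  }
}

double_conv_fwd <- function(h, p1, p2, cache, tag) {
  a1 <- conv_fwd(h, p1$w, p1$b)
  r1 <- relu_fwd(a1)
  a2 <- conv_fwd(r1, p2$w, p2$b)
  r2 <- relu_fwd(a2)
  cache[[tag]] <- list(x1 = h, a1 = a1, x2 = r1, a2 = a2)
  list(h = r2, cache = cache)
}

double_conv_bwd <- function(cache_blk, g, p1, p2, grads, tag1, tag2) {
  g <- relu_bwd(cache_blk$a2, g)
  b2 <- conv_bwd(cache_blk$x2, p2$w, g)
  grads[[tag2]] <- list(w = b2$gw, b = as.numeric(b2$gb))
  g <- relu_bwd(cache_blk$a1, b2$gx)
  b1 <- conv_bwd(cache_blk$x1, p1$w, g)
  grads[[tag1]] <- list(w = b1$gw, b = as.numeric(b1$gb))
  list(g = b1$gx, grads = grads)
}

# forward pass; returns prediction and (optionally) the cache for backprop
unet_forward <- function(net, x, want_cache = FALSE) {
  cfg <- net$cfg
  p <- net$params
  x <- as_cube(x)
  check_input_size(cfg, dim(x))
  cache <- list(x = x)
  skips <- list()
  pools <- list()
  h <- x
  for (i in seq_len(cfg$levels)) {
    dc <- double_conv_fwd(h, p[[paste0("enc", i, "_conv1")]],
                          p[[paste0("enc", i, "_conv2")]],
                          cache, paste0("enc", i))
    cache <- dc$cache
    cb <- cbam_fwd(dc$h, p[[paste0("enc", i, "_cbam")]])
    cache[[paste0("enc", i, "_cbam")]] <- cb$cache
    skips[[i]] <- cb$z
    mp <- nn_maxpool_fwd(cb$z)
    pools[[i]] <- list(idx = mp$idx, d = dim(cb$z))
    h <- mp$y
  }
  dc <- double_conv_fwd(h, p$bot_conv1, p$bot_conv2, cache, "bot")
  cache <- dc$cache
  cb <- cbam_fwd(dc$h, p$bot_cbam)
  cache$bot_cbam <- cb$cache
  h <- cb$z
  for (i in rev(seq_len(cfg$levels))) {
    up <- upsample_nearest_fwd(h)
    a_up <- conv_fwd(up, p[[paste0("dec", i, "_up")]]$w,
                     p[[paste0("dec", i, "_up")]]$b)
    r_up <- relu_fwd(a_up)
    cache[[paste0("dec", i, "_upc")]] <- list(x = up, a = a_up)
    hcat <- array(c(skips[[i]], r_up),
                  dim = c(dim(r_up)[1], dim(r_up)[2], 2L * dim(r_up)[3]))
    dc <- double_conv_fwd(hcat, p[[paste0("dec", i, "_conv1")]],
                          p[[paste0("dec", i, "_conv2")]],
                          cache, paste0("dec", i))
    cache <- dc$cache
    cb <- cbam_fwd(dc$h, p[[paste0("dec", i, "_cbam")]])
    cache[[paste0("dec", i, "_cbam")]] <- cb$cache
    h <- cb$z
  }
  h4 <- conv_fwd(h, p$head_conv$w, p$head_conv$b)
  cache$head_x <- h
  res <- pixel_shuffle_fwd(h4)
  skip <- bicubic_upsample_2x(x[, , 1L])
  y <- res + skip
  cache$skips_d <- lapply(skips, dim)
  cache$pools <- pools
  list(y = y, cache = if (want_cache) cache else NULL)
}

# backward pass from d(loss)/d(prediction); returns named gradient list
unet_backward <- function(net, cache, gy) {
  cfg <- net$cfg
  p <- net$params
  grads <- list()
  g4 <- pixel_shuffle_bwd(gy)
  bh <- conv_bwd(cache$head_x, p$head_conv$w, g4)
  grads$head_conv <- list(w = bh$gw, b = as.numeric(bh$gb))
  g <- bh$gx
  for (i in seq_len(cfg$levels)) {
    cb <- cbam_bwd(cache[[paste0("dec", i, "_cbam")]], g,
                   p[[paste0("dec", i, "_cbam")]])
    grads[[paste0("dec", i, "_cbam")]] <- cb$grads
    dcb <- double_conv_bwd(cache[[paste0("dec", i)]], cb$gx,
                           p[[paste0("dec", i, "_conv1")]],
                           p[[paste0("dec", i, "_conv2")]], grads,
                           paste0("dec", i, "_conv1"),
                           paste0("dec", i, "_conv2"))
    grads <- dcb$grads
    ghcat <- dcb$g
    nch <- dim(ghcat)[3] / 2L
    gskip <- ghcat[, , seq_len(nch), drop = FALSE]
    gr_up <- ghcat[, , nch + seq_len(nch), drop = FALSE]
    upc <- cache[[paste0("dec", i, "_upc")]]
    gr_up <- relu_bwd(upc$a, gr_up)
    bu <- conv_bwd(upc$x, p[[paste0("dec", i, "_up")]]$w, gr_up)
    grads[[paste0("dec", i, "_up")]] <- list(w = bu$gw, b = as.numeric(bu$gb))
    g <- upsample_nearest_bwd(bu$gx)
    # stash skip gradient for the encoder sweep
    cache[[paste0("gskip", i)]] <- gskip
  }
  cb <- cbam_bwd(cache$bot_cbam, g, p$bot_cbam)
  grads$bot_cbam <- cb$grads
  dcb <- double_conv_bwd(cache$bot, cb$gx, p$bot_conv1, p$bot_conv2,
                         grads, "bot_conv1", "bot_conv2")
  grads <- dcb$grads
  g <- dcb$g
  for (i in rev(seq_len(cfg$levels))) {
    pool <- cache$pools[[i]]
    gup <- nn_maxpool_bwd(g, pool$idx, pool$d[1], pool$d[2], pool$d[3])
    gz <- gup + cache[[paste0("gskip", i)]]
    cb <- cbam_bwd(cache[[paste0("enc", i, "_cbam")]], gz,
                   p[[paste0("enc", i, "_cbam")]])
    grads[[paste0("enc", i, "_cbam")]] <- cb$grads
    dcb <- double_conv_bwd(cache[[paste0("enc", i)]], cb$gx,
                           p[[paste0("enc", i, "_conv1")]],
                           p[[paste0("enc", i, "_conv2")]], grads,
                           paste0("enc", i, "_conv1"),
                           paste0("enc", i, "_conv2"))
    grads <- dcb$grads
    g <- dcb$g
  }
  grads
}

#' Run the restoration network on an image
#'
#' @param net A [build_network()] network (or a trained model's network).
#' @param img Numeric matrix `H x W`.
#' @return Numeric matrix `2H x 2W`.
#' @export
predict_network <- function(net, img) {
  if (inherits(net, "flim_model")) {
    img <- img / net$norm
    out <- unet_forward(net$network, as_cube(img))$y * net$norm
    return(out)
  }
  unet_forward(net, as_cube(img))$y
}
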
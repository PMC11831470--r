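# Neural building blocks for the restoration network. Tensors are numeric
# 3D arrays [H, W, C]; convolutions run through the compiled im2col kernels.
# Every layer has an explicit backward pass (no autodiff available here).

as_cube <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

conv_fwd <- function(x, w, b, k = 3L) nn_conv_fwd(as_cube(x), w, b, k)

conv_bwd <- function(x, w, gy, k = 3L) nn_conv_bwd(as_cube(x), w, gy, k)

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(x, gy) {
  gy * (x > 0)
}

upsample_nearest_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, dim = c(2L * d[1], 2L * d[2], d[3]))
  io <- seq(1L, 2L * d[1], 2L); jo <- seq(1L, 2L * d[2], 2L)
  y[io, jo, ] <- x
  y[io + 1L, jo, ] <- x
  y[io, jo + 1L, ] <- x
  y[io + 1L, jo + 1L, ] <- x
  y
}

upsample_nearest_bwd <- function(gy) {
  d <- dim(gy)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  gy[io, jo, , drop = FALSE] + gy[io + 1L, jo, , drop = FALSE] +
    gy[io, jo + 1L, , drop = FALSE] + gy[io + 1L, jo + 1L, , drop = FALSE]
}

# sub-pixel (pixel-shuffle) rearrangement of 4 channels into a 2x finer
# single-channel image; avoids checkerboard artifacts of strided deconv
pixel_shuffle_fwd <- function(x) {
  d <- dim(x)
  stopifnot(d[3] == 4L)
  y <- matrix(0, 2L * d[1], 2L * d[2])
  io <- seq(1L, 2L * d[1], 2L); jo <- seq(1L, 2L * d[2], 2L)
  y[io, jo] <- x[, , 1L]
  y[io + 1L, jo] <- x[, , 2L]
  y[io, jo + 1L] <- x[, , 3L]
  y[io + 1L, jo + 1L] <- x[, , 4L]
  y
}

pixel_shuffle_bwd <- function(gy) {
  d <- dim(gy)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  g <- array(0, dim = c(d[1] / 2L, d[2] / 2L, 4L))
  g[, , 1L] <- gy[io, jo]
  g[, , 2L] <- gy[io + 1L, jo]
  g[, , 3L] <- gy[io, jo + 1L]
  g[, , 4L] <- gy[io + 1L, jo + 1L]
  g
}

# ---- CBAM: sequential channel then spatial attention -----------------------

cbam_params <- function(channels, reduction, rng) {
  hidden <- max(1L, channels %/% reduction)
  list(
    fc1_w = matrix(rng(hidden * channels, channels), hidden, channels),
    fc1_b = numeric(hidden),
    fc2_w = matrix(rng(channels * hidden, hidden), channels, hidden),
    fc2_b = numeric(channels),
    sp_w = matrix(rng(49L * 2L, 2L * 49L), 49L * 2L, 1L),
    sp_b = numeric(1L)
  )
}

cbam_fwd <- function(x, p) {
  d <- dim(x)
  C <- d[3]
  npx <- d[1] * d[2]
  xm <- matrix(x, npx, C)
  s_avg <- colMeans(xm)
  imax <- max.col(t(xm), ties.method = "first")  # argmax pixel per channel
  s_max <- xm[cbind(imax, seq_len(C))]
  h_avg <- pmax(p$fc1_w %*% s_avg + p$fc1_b, 0)
  h_max <- pmax(p$fc1_w %*% s_max + p$fc1_b, 0)
  e <- p$fc2_w %*% h_avg + p$fc2_w %*% h_max + 2 * p$fc2_b
  a_ch <- as.numeric(sigmoid(e))
  y <- x * rep(a_ch, each = npx)
  ym <- matrix(y, npx, C)
  m_avg <- rowMeans(ym)
  cmax <- max.col(ym, ties.method = "first")    # argmax channel per pixel
  m_max <- ym[cbind(seq_len(npx), cmax)]
  msk <- array(c(m_avg, m_max), dim = c(d[1], d[2], 2L))
  pre_sp <- conv_fwd(msk, p$sp_w, p$sp_b, k = 7L)
  a_sp <- sigmoid(pre_sp[, , 1L])
  z <- y * as.vector(a_sp)
  list(z = z,
       cache = list(x = x, s_avg = s_avg, s_max = s_max, imax = imax,
                    h_avg = h_avg, h_max = h_max, a_ch = a_ch, y = y,
                    msk = msk, a_sp = a_sp, cmax = cmax))
}

cbam_bwd <- function(cache, gz, p) {
  d <- dim(cache$x)
  C <- d[3]
  npx <- d[1] * d[2]
  # spatial attention
  ga_sp <- apply(gz * cache$y, c(1, 2), sum)
  gy <- gz * as.vector(cache$a_sp)
  gpre_sp <- array(ga_sp * cache$a_sp * (1 - cache$a_sp), dim = c(d[1], d[2], 1L))
  bw_sp <- conv_bwd(cache$msk, p$sp_w, gpre_sp, k = 7L)
  gmsk <- bw_sp$gx
  gym <- matrix(gy, npx, C) + as.vector(gmsk[, , 1L]) / C   # mean branch
  gmax_px <- as.vector(gmsk[, , 2L])             # max branch
  idx <- cbind(seq_len(npx), cache$cmax)
  gym[idx] <- gym[idx] + gmax_px
  gy_total <- array(gym, dim = d)
  # channel attention
  ga_ch <- colSums(matrix(gy_total * cache$x, npx, C))
  gx <- gy_total * rep(cache$a_ch, each = npx)
  ge <- ga_ch * cache$a_ch * (1 - cache$a_ch)
  g_fc2_w <- outer(ge, as.numeric(cache$h_avg)) +
    outer(ge, as.numeric(cache$h_max))
  g_fc2_b <- 2 * ge
  gh_avg <- as.numeric(t(p$fc2_w) %*% ge) * (cache$h_avg > 0)
  gh_max <- as.numeric(t(p$fc2_w) %*% ge) * (cache$h_max > 0)
  g_fc1_w <- outer(as.numeric(gh_avg), cache$s_avg) +
    outer(as.numeric(gh_max), cache$s_max)
  g_fc1_b <- as.numeric(gh_avg) + as.numeric(gh_max)
  gs_avg <- as.numeric(t(p$fc1_w) %*% gh_avg)
  gs_max <- as.numeric(t(p$fc1_w) %*% gh_max)
  gxm <- matrix(gx, npx, C)
  gxm <- gxm + rep(gs_avg / npx, each = npx)
  gxm[cbind(cache$imax, seq_len(C))] <-
    gxm[cbind(cache$imax, seq_len(C))] + gs_max
  list(gx = array(gxm, dim = d),
       grads = list(fc1_w = g_fc1_w, fc1_b = g_fc1_b,
                    fc2_w = g_fc2_w, fc2_b = g_fc2_b,
                    sp_w = bw_sp$gw, sp_b = as.numeric(bw_sp$gb)))
}
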
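#' Bicubic 2x upsampling (interpolation baseline)
#'
#' Separable Catmull-Rom (a = -0.5) bicubic interpolation to twice the
#' size, with clamped borders. This is the non-learned baseline the
#' restoration network is compared against.
#'
#' @param img Numeric matrix.
#' @return Numeric matrix of twice the size.
#' @export
bicubic_upsample_2x <- function(img) {
  img <- as.matrix(img)
  wr <- bicubic_weights_2x(nrow(img))
  wc <- bicubic_weights_2x(ncol(img))
  wr %*% img %*% t(wc)
}

cubic_kernel <- function(d, a = -0.5) {
  d <- abs(d)
  ifelse(d <= 1, (a + 2) * d^3 - (a + 3) * d^2 + 1,
         ifelse(d < 2, a * (d^3 - 5 * d^2 + 8 * d - 4), 0))
}

bicubic_weight_cache <- new.env(parent = emptyenv())

bicubic_weights_2x <- function(n) {
  key <- as.character(n)
  if (!is.null(bicubic_weight_cache[[key]])) {
    return(bicubic_weight_cache[[key]])
  }
  w <- matrix(0, 2L * n, n)
  for (io in seq_len(2L * n)) {
    p <- (io - 0.5) / 2 + 0.5       # continuous source position, 1-based
    base <- floor(p)
    for (t in -1:2) {
      src <- min(max(base + t, 1L), n)   # clamp at borders
      w[io, src] <- w[io, src] + cubic_kernel(p - (base + t))
    }
  }
  bicubic_weight_cache[[key]] <- w
  w
}

#' Image quality metrics (PSNR, SSIM, RMSE, MAE)
#'
#' Standard full-reference metrics with the data range taken as
#' `max(target) - min(target)`. PSNR of identical images is infinite and is
#' reported as the capped sentinel 120 dB. SSIM uses the conventional
#' 11 x 11 Gaussian window (sigma 1.5, K1 = 0.01, K2 = 0.03) averaged over
#' the interior (a 5-pixel border is excluded to avoid padding effects).
#'
#' @param pred,target Numeric matrices of equal shape.
#' @return An object of class `quality_metrics`: list with `psnr_db`,
#'   `ssim`, `rmse`, `mae`.
#' @export
evaluate_metrics <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  if (!identical(dim(pred), dim(target))) stop("shapes differ")
  rng <- max(target) - min(target)
  if (rng <= 0) stop("target has zero data range")
  err <- pred - target
  mse <- mean(err^2)
  psnr <- if (mse == 0) 120 else min(10 * log10(rng^2 / mse), 120)
  structure(
    list(psnr_db = psnr, ssim = ssim_index(pred, target, rng),
         rmse = sqrt(mse), mae = mean(abs(err))),
    class = "quality_metrics"
  )
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("<quality_metrics> PSNR %.2f dB, SSIM %.4f, RMSE %.4g, MAE %.4g\n",
              x$psnr_db, x$ssim, x$rmse, x$mae))
  invisible(x)
}

gaussian_window_11 <- function(sigma = 1.5) {
  g <- exp(-((-5:5)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

ssim_filter <- function(img, k) {
  w <- matrix(as.numeric(k), ncol = 1L)
  out <- nn_conv_fwd(array(img, dim = c(dim(img), 1L)), w, 0, 11L)[, , 1L]
  d <- dim(img)
  out[6:(d[1] - 5), 6:(d[2] - 5), drop = FALSE]
}

ssim_index <- function(pred, target, rng) {
  d <- dim(pred)
  if (any(d < 12L)) {
    # too small for the windowed statistic: fall back to global moments
    mu_x <- mean(pred); mu_y <- mean(target)
    vx <- stats::var(as.numeric(pred)); vy <- stats::var(as.numeric(target))
    cxy <- stats::cov(as.numeric(pred), as.numeric(target))
    c1 <- (0.01 * rng)^2; c2 <- (0.03 * rng)^2
    return(((2 * mu_x * mu_y + c1) * (2 * cxy + c2)) /
             ((mu_x^2 + mu_y^2 + c1) * (vx + vy + c2)))
  }
  k <- gaussian_window_11()
  mu_x <- ssim_filter(pred, k)
  mu_y <- ssim_filter(target, k)
  xx <- ssim_filter(pred^2, k) - mu_x^2
  yy <- ssim_filter(target^2, k) - mu_y^2
  xy <- ssim_filter(pred * target, k) - mu_x * mu_y
  c1 <- (0.01 * rng)^2; c2 <- (0.03 * rng)^2
  smap <- ((2 * mu_x * mu_y + c1) * (2 * xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (xx + yy + c2))
  mean(smap)
}
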
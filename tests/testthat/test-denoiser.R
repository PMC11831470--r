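test_that("network maps H x W to 2H x 2W with deterministic init", {
  cfg <- network_config(levels = 2L, base_channels = 4L)
  n1 <- build_network(cfg, seed = 3L)
  n2 <- build_network(cfg, seed = 3L)
  n3 <- build_network(cfg, seed = 4L)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params, n3$params))
  expect_gt(n1$n_parameters, 0)
  x <- matrix(rnorm(32 * 32), 32, 32)
  y <- predict_network(n1, x)
  expect_equal(dim(y), c(64L, 64L))
  # zero input -> finite output
  y0 <- predict_network(n1, matrix(0, 32, 32))
  expect_true(all(is.finite(y0)))
  # size not divisible by 2^levels errors
  expect_error(predict_network(n1, matrix(0, 30, 30)), "divisible")
})

test_that("untrained network reproduces the bicubic upsample (zero head)", {
  net <- build_network(network_config(levels = 1L, base_channels = 4L),
                       seed = 1L)
  x <- matrix(rnorm(16 * 16), 16, 16)
  expect_equal(predict_network(net, x), bicubic_upsample_2x(x),
               tolerance = 1e-12)
})

test_that("network backprop matches finite differences", {
  cfg <- network_config(levels = 1L, base_channels = 2L, cbam_reduction = 1L)
  net <- build_network(cfg, seed = 7L)
  set.seed(42)
  x <- matrix(rnorm(8 * 8), 8, 8)
  tg <- matrix(rnorm(16 * 16), 16, 16)
  fw <- fdflim:::unet_forward(net, fdflim:::as_cube(x), want_cache = TRUE)
  gy <- 2 * (fw$y - tg) / length(tg)
  grads <- fdflim:::unet_backward(net, fw$cache, gy)
  loss_of <- function(nn) {
    mean((fdflim:::unet_forward(nn, fdflim:::as_cube(x))$y - tg)^2)
  }
  eps <- 1e-5
  # spot-check a parameter in every kind of block
  for (leaf in list(c("enc1_conv1", "w"), c("enc1_cbam", "fc1_w"),
                    c("enc1_cbam", "sp_w"), c("bot_conv2", "b"),
                    c("dec1_up", "w"), c("dec1_cbam", "fc2_w"),
                    c("head_conv", "w"))) {
    p <- net$params[[leaf[1]]][[leaf[2]]]
    i <- ((seq_along(p)[length(p) %/% 2L]) %% length(p)) + 1L
    np <- net
    np$params[[leaf[1]]][[leaf[2]]][i] <- p[i] + eps
    lp <- loss_of(np)
    np$params[[leaf[1]]][[leaf[2]]][i] <- p[i] - eps
    lm <- loss_of(np)
    num <- (lp - lm) / (2 * eps)
    ana <- grads[[leaf[1]]][[leaf[2]]][i]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste("grad", leaf[1], leaf[2]))
  }
})

test_that("losses are >= 0 and ~ 0 at identity", {
  set.seed(9)
  cfg <- loss_config(cobi_max_patches = 36L)
  for (k in 1:20) {
    a <- matrix(rnorm(20 * 20), 20, 20)
    b <- matrix(rnorm(20 * 20), 20, 20)
    expect_gte(cobi_loss(a, b, cfg), 0)
    expect_gte(perceptual_loss(a, b, cfg), 0)
  }
  a <- matrix(rnorm(20 * 20), 20, 20)
  expect_lt(cobi_loss(a, a, cfg), 1e-6)
  expect_equal(perceptual_loss(a, a, cfg), 0)
})

test_that("CoBi contextual term tolerates translation better than scrambling", {
  # pixel term off to isolate the unaligned patch-matching behaviour; a
  # dense smooth field so scrambling destroys local patch structure
  cfg <- loss_config(cobi_max_patches = 64L, pixel_term_weight = 0)
  smooth_field <- function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(32 * 32), 32, 32)
    k <- dnorm(-3:3, sd = 1.2); k <- k / sum(k)
    sm <- function(v) stats::filter(c(v[30:32], v, v[1:3]), k)[4:35]
    x <- apply(x, 2, sm)
    t(apply(t(x), 2, sm))
  }
  for (sd_i in 1:3) {
    img <- smooth_field(sd_i)
    shifted <- rbind(img[-1, ], img[1, ])        # 1-px cyclic translation
    set.seed(1000 + sd_i)
    permuted <- matrix(sample(img), 32, 32)      # same pixels, scrambled
    expect_lt(cobi_loss(shifted, img, cfg),
              cobi_loss(permuted, img, cfg) / 2)
  }
})

test_that("perceptual loss grows monotonically with noise amplitude", {
  set.seed(11)
  img <- matrix(rnorm(24 * 24), 24, 24)
  noise <- matrix(rnorm(24 * 24), 24, 24)
  l <- vapply(c(0.1, 0.4, 1.6),
              function(a) perceptual_loss(img + a * noise, img),
              numeric(1))
  expect_true(all(diff(l) > 0))
})

test_that("perceptual loss is nearly symmetric", {
  set.seed(12)
  a <- matrix(rnorm(24 * 24), 24, 24)
  b <- a + 0.1 * matrix(rnorm(24 * 24), 24, 24)
  expect_equal(perceptual_loss(a, b), perceptual_loss(b, a),
               tolerance = 1e-8)
})

test_that("quality metrics satisfy their closed-form identities", {
  set.seed(13)
  tg <- matrix(runif(32 * 32), 32, 32)
  m_id <- evaluate_metrics(tg, tg)
  expect_equal(m_id$psnr_db, 120)  # capped sentinel for identical images
  expect_equal(m_id$ssim, 1, tolerance = 1e-9)
  expect_equal(m_id$rmse, 0)
  expect_equal(m_id$mae, 0)
  # constant offset: rmse = mae = |c|
  m_c <- evaluate_metrics(tg + 0.05, tg)
  expect_equal(m_c$rmse, 0.05, tolerance = 1e-12)
  expect_equal(m_c$mae, 0.05, tolerance = 1e-12)
  # doubling gaussian noise sigma drops PSNR by ~6.02 dB
  n <- matrix(rnorm(32 * 32), 32, 32)
  p1 <- evaluate_metrics(tg + 0.01 * n, tg)$psnr_db
  p2 <- evaluate_metrics(tg + 0.02 * n, tg)$psnr_db
  expect_equal(p1 - p2, 20 * log10(2), tolerance = 1e-9)
  expect_error(evaluate_metrics(tg, matrix(1, 32, 32)), "zero data range")
})

test_that("bicubic upsampling doubles size and preserves constants", {
  x <- matrix(3.7, 10, 14)
  y <- bicubic_upsample_2x(x)
  expect_equal(dim(y), c(20L, 28L))
  expect_equal(y, matrix(3.7, 20, 28), tolerance = 1e-12)
  # reproduces a linear ramp away from borders
  r <- matrix(rep(seq_len(16), each = 16), 16, 16)
  yr <- bicubic_upsample_2x(r)
  interior <- yr[8:24, 8:24]
  expect_lt(max(abs(diff(t(interior)) - 0.5)), 1e-9)
})

test_that("smoke training runs end-to-end and reduces the loss", {
  ds <- render_paired_dataset(8L, seed = 11L, target_size = 128L)
  expect_s3_class(ds, "paired_dataset")
  expect_length(ds$pairs, 8L)
  expect_length(ds$split$test, 1L)
  expect_equal(dim(ds$pairs[[1]]$input$g), c(64L, 64L))
  expect_equal(dim(ds$pairs[[1]]$target$g), c(128L, 128L))
  m <- train_model(ds, channels = "intensity",
                   train_cfg = train_config_scaled(epochs = 5L, seed = 2L))
  h <- m$intensity$history
  expect_equal(nrow(h), 5L)
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_true(m$intensity$best_epoch >= 1L)
  out <- denoise_image(m$intensity, ds$pairs[[1]]$input$intensity)
  expect_equal(dim(out), c(128L, 128L))
})

test_that("augmentation changes the training history", {
  ds <- render_paired_dataset(7L, seed = 11L, target_size = 128L)
  m_on <- train_model(ds, channels = "g",
                      train_cfg = train_config(epochs = 2L, augment = TRUE,
                                               crop_size = 32L, seed = 2L))
  m_off <- train_model(ds, channels = "g",
                       train_cfg = train_config(epochs = 2L, augment = FALSE,
                                                crop_size = 32L, seed = 2L))
  expect_false(identical(m_on$g$history$train_loss,
                         m_off$g$history$train_loss))
})

test_that("train_config records overrides and rejects empty datasets", {
  tc <- train_config()
  expect_length(tc$overrides, 0L)
  tc2 <- train_config_scaled()
  expect_true(all(c("learning_rate", "epochs", "crop_size") %in%
                    tc2$overrides))
  expect_error(train_model(list(), train_cfg = tc), "paired_dataset")
})

test_that("enhance_and_reanalyze requires all three channel models", {
  ds <- render_paired_dataset(7L, seed = 11L, target_size = 128L)
  m <- train_model(ds, channels = "intensity",
                   train_cfg = train_config_scaled(epochs = 1L, seed = 2L))
  tri <- ds$pairs[[1]]$input[c("intensity", "g", "s")]
  expect_error(enhance_and_reanalyze(m, tri, fx_mod), "missing model")
})
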
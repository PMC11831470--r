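#' Training configuration
#'
#' Defaults echo the restoration recipe: Adam (learning rate 1e-4, betas
#' 0.9/0.999) with a cosine learning-rate schedule over 500 epochs,
#' flip/rotate augmentation, 6:1 train/test split (held by the dataset).
#' Scaled-down presets override epochs, crop size and learning rate; every
#' override from the defaults is recorded in `$overrides`.
#'
#' @param learning_rate Adam step size.
#' @param betas Adam moment decay rates.
#' @param epochs Training epochs.
#' @param schedule `"cosine"` or `"constant"`.
#' @param augment Apply random horizontal/vertical flips and 90-degree
#'   rotations (identically to input and target)?
#' @param crop_size Optional square crop side at input resolution (must be
#'   divisible by `2^levels`); `NULL` trains on full images.
#' @param seed Seed controlling initialisation, shuffling, augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, betas = c(0.9, 0.999),
                         epochs = 500L, schedule = c("cosine", "constant"),
                         augment = TRUE, crop_size = NULL, seed = 1L) {
  schedule <- match.arg(schedule)
  defaults <- list(learning_rate = 1e-4, betas = c(0.9, 0.999),
                   epochs = 500L, schedule = "cosine", augment = TRUE,
                   crop_size = NULL)
  actual <- list(learning_rate = learning_rate, betas = betas,
                 epochs = as.integer(epochs), schedule = schedule,
                 augment = augment, crop_size = crop_size)
  overrides <- names(defaults)[!vapply(names(defaults), function(nm) {
    identical(defaults[[nm]], actual[[nm]])
  }, logical(1))]
  structure(c(actual, list(seed = as.integer(seed), overrides = overrides)),
            class = "train_config")
}

#' @rdname train_config
#' @export
train_config_scaled <- function(epochs = 50L, crop_size = 32L,
                                learning_rate = 1e-3, seed = 1L) {
  train_config(learning_rate = learning_rate, epochs = epochs,
               crop_size = crop_size, seed = seed)
}

# ---- Adam over the nested parameter list ------------------------------------

adam_init <- function(params) {
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else x * 0  # keeps vector/matrix shape
  }
  list(m = walk(params), v = walk(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - betas[1]^state$t
  bc2 <- 1 - betas[2]^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- betas[1] * m + (1 - betas[1]) * g
    v <- betas[2] * v + (1 - betas[2]) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# flips / rot90 applied identically to input and target
augment_pair <- function(xin, xtg) {
  if (stats::runif(1) < 0.5) {
    xin <- xin[nrow(xin):1, , drop = FALSE]
    xtg <- xtg[nrow(xtg):1, , drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {
    xin <- xin[, ncol(xin):1, drop = FALSE]
    xtg <- xtg[, ncol(xtg):1, drop = FALSE]
  }
  k <- sample(0:3, 1)
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  for (i in seq_len(k)) {
    xin <- rot90(xin); xtg <- rot90(xtg)
  }
  list(input = xin, target = xtg)
}

crop_pair <- function(xin, xtg, crop) {
  if (is.null(crop) || crop >= nrow(xin)) return(list(input = xin, target = xtg))
  i0 <- sample.int(nrow(xin) - crop + 1L, 1L)
  j0 <- sample.int(ncol(xin) - crop + 1L, 1L)
  list(
    input = xin[i0:(i0 + crop - 1L), j0:(j0 + crop - 1L)],
    target = xtg[(2 * i0 - 1):(2 * (i0 + crop - 1L)),
                 (2 * j0 - 1):(2 * (j0 + crop - 1L))]
  )
}

cosine_lr <- function(lr0, epoch, epochs, schedule) {
  if (schedule == "constant" || epochs <= 1L) return(lr0)
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

#' Train one restoration model per image channel
#'
#' Trains independent networks for the `g`, `s` and intensity channels
#' (weights are not shared across channels). The `g` model uses CoBi loss,
#' `s` and intensity use perceptual loss, all with a pixel-MAE
#' stabiliser; optimisation is Adam with a cosine schedule, and the best
#' checkpoint per channel is chosen by validation MAE on the held-out split.
#'
#' @param dataset A [render_paired_dataset()] result.
#' @param channels Channels to train (subset of `"intensity"`, `"g"`, `"s"`).
#' @param net_cfg A [network_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch progress?
#' @return An object of class `flim_model_set`: named list of `flim_model`
#'   (each with `$network`, `$norm`, `$history`, `$best_epoch`).
#' @export
train_model <- function(dataset, channels = c("intensity", "g", "s"),
                        net_cfg = network_config(levels = 2L,
                                                 base_channels = 8L),
                        loss_cfg = loss_config(),
                        train_cfg = train_config(),
                        verbose = FALSE) {
  if (!inherits(dataset, "paired_dataset")) {
    stop("`dataset` must be a paired_dataset")
  }
  if (length(dataset$pairs) == 0L) stop("empty dataset")
  channels <- match.arg(channels, c("intensity", "g", "s"),
                        several.ok = TRUE)
  models <- stats::setNames(vector("list", length(channels)), channels)
  seeds <- derive_substream_seeds(train_cfg$seed, length(channels))
  for (ci in seq_along(channels)) {
    models[[ci]] <- train_channel(dataset, channels[ci], net_cfg, loss_cfg,
                                  train_cfg, seeds[ci], verbose)
  }
  structure(models, class = "flim_model_set")
}

train_channel <- function(dataset, channel, net_cfg, loss_cfg, train_cfg,
                          seed, verbose = FALSE) {
  kind <- loss_cfg$channel_loss[[channel]]
  tr <- dataset$split$train
  te <- dataset$split$test
  norm <- if (channel == "intensity") {
    stats::quantile(unlist(lapply(dataset$pairs[tr],
                                  function(p) p$target$intensity)),
                    0.99, names = FALSE)
  } else {
    1
  }
  if (!is.finite(norm) || norm <= 0) norm <- 1
  get_pair <- function(i) {
    list(input = dataset$pairs[[i]]$input[[channel]] / norm,
         target = dataset$pairs[[i]]$target[[channel]] / norm)
  }
  net <- build_network(net_cfg, seed = seed)
  state <- adam_init(net$params)
  best <- list(mae = Inf, params = net$params, epoch = 0L)
  hist <- vector("list", train_cfg$epochs)
  with_local_seed(seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs)) {
      lr <- cosine_lr(train_cfg$learning_rate, epoch, train_cfg$epochs,
                      train_cfg$schedule)
      order_idx <- sample(tr)
      tot <- 0
      for (i in order_idx) {
        pr <- get_pair(i)
        pr <- crop_pair(pr$input, pr$target, train_cfg$crop_size)
        if (train_cfg$augment) pr <- augment_pair(pr$input, pr$target)
        fw <- unet_forward(net, as_cube(pr$input), want_cache = TRUE)
        lg <- channel_loss_grad(fw$y, pr$target, kind, loss_cfg)
        tot <- tot + lg$loss
        grads <- unet_backward(net, fw$cache, lg$grad)
        st <- adam_step(net$params, grads, state, lr, train_cfg$betas)
        net$params <- st$params
        state <- st$state
      }
      val_mae <- mean(vapply(te, function(i) {
        pr <- get_pair(i)
        mean(abs(unet_forward(net, as_cube(pr$input))$y - pr$target))
      }, numeric(1)))
      if (val_mae < best$mae) {
        best <- list(mae = val_mae, params = net$params, epoch = epoch)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = tot / length(order_idx),
                                  val_mae = val_mae)
      if (verbose) {
        message(sprintf("[%s] epoch %d/%d loss %.5f val MAE %.5f", channel,
                        epoch, train_cfg$epochs, tot / length(order_idx),
                        val_mae))
      }
    }
  })
  net$params <- best$params
  structure(
    list(network = net, channel = channel, norm = norm,
         history = do.call(rbind, hist), best_epoch = best$epoch,
         loss_kind = kind, train_cfg = train_cfg),
    class = "flim_model"
  )
}

#' @export
print.flim_model <- function(x, ...) {
  cat(sprintf(
    "<flim_model> channel %s (%s loss), best epoch %d (val MAE %.5g)\n",
    x$channel, x$loss_kind, x$best_epoch,
    min(x$history$val_mae)
  ))
  invisible(x)
}

#' @export
print.flim_model_set <- function(x, ...) {
  cat("<flim_model_set>\n")
  for (m in x) print(m)
  invisible(x)
}

#' Denoise a single channel image
#'
#' @param model A trained `flim_model`.
#' @param img Numeric matrix at input resolution.
#' @return Restored matrix at twice the resolution.
#' @export
denoise_image <- function(model, img) {
  if (!inherits(model, "flim_model")) stop("`model` must be a flim_model")
  predict_network(model, as.matrix(img))
}

#' Restore a triplet and recompute lifetime / phasor read-outs
#'
#' Runs the per-channel restoration models on an `{intensity, g, s}` input
#' triplet, rebuilds a phasor field from the enhanced channels, and
#' recomputes phase/modulation lifetime maps and the phasor histogram — the
#' enhanced end of the analysis pipeline.
#'
#' @param models A `flim_model_set` holding `intensity`, `g` and `s` models.
#' @param triplet List with matrices `intensity`, `g`, `s` (input
#'   resolution, already demodulated/calibrated).
#' @param mod A [modulation_context()].
#' @param intensity_floor Optional threshold for the enhanced validity mask.
#' @param histogram_bins Bins of the returned phasor histogram.
#' @return List with `triplet` (enhanced, 2x resolution), `field`
#'   ([phasor_field()]), `lifetimes` (lifetime field) and `histogram`.
#' @export
enhance_and_reanalyze <- function(models, triplet, mod,
                                  intensity_floor = NULL,
                                  histogram_bins = 128L) {
  for (ch in c("intensity", "g", "s")) {
    if (is.null(models[[ch]])) stop("missing model for channel ", ch)
    if (is.null(triplet[[ch]])) stop("missing triplet channel ", ch)
  }
  enh <- list(
    intensity = denoise_image(models$intensity, triplet$intensity),
    g = denoise_image(models$g, triplet$g),
    s = denoise_image(models$s, triplet$s)
  )
  floor_val <- intensity_floor %||% default_intensity_floor(enh$intensity)
  valid <- enh$intensity > floor_val
  field <- phasor_field(enh$g, enh$s, valid = valid,
                        intensity = enh$intensity, calibrated = TRUE)
  lifetimes <- lifetimes_from_phasor(field, mod)
  hist <- phasor_histogram(field, threshold = floor_val,
                           bins = histogram_bins)
  list(triplet = enh, field = field, lifetimes = lifetimes,
       histogram = hist)
}
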
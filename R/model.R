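#' Network and training configuration
#'
#' The predictor is a 2D fully-convolutional residual encoder-decoder: a
#' convolutional front-end that downsamples the slices to one-fourth of
#' their resolution, a stack of residual blocks at low resolution, and a
#' transposed-convolutional back-end that restores the input resolution.
#' Input: three channels (Dixon in-phase, Dixon out-of-phase, four-class
#' mu-map); output: one channel, linear activation (correction values can be
#' negative). Trained with Adam on a masked L2 loss for `epochs` epochs with
#' a learning rate held constant until `decay_start` and then decayed
#' linearly to zero at the final epoch.
#'
#' Defaults describe the full-size model (9 residual blocks, 64 base
#' filters, 100 epochs, decay from 50); unit tests and desk-scale studies
#' use reduced settings. Learning rate, batch size and filter counts are
#' package defaults, not literature-prescribed values.
#'
#' @param n_resblocks Residual blocks at low resolution.
#' @param base_filters Filters in the first convolution; doubled after the
#'   first downsampling stage.
#' @param downsample Total downsampling factor; a power of 2.
#' @param epochs Training epochs.
#' @param lr Base Adam learning rate.
#' @param batch_size Slices per batch.
#' @param decay_start Epoch at which the linear LR decay begins (< epochs).
#' @param seed Seed for initialization and shuffling.
#' @param in_channels Input channel count.
#' @param front_kernel Kernel size of the first full-resolution convolution.
#' @param out_kernel Kernel size of the output convolution.
#' @return A list of class `net_config`.
#' @export
net_config <- function(n_resblocks = 9, base_filters = 64, downsample = 4,
                       epochs = 100, lr = 2e-4, batch_size = 16,
                       decay_start = 50, seed = 1, in_channels = 3,
                       front_kernel = 7, out_kernel = 3) {
  cfg <- list(n_resblocks = as.integer(n_resblocks),
              base_filters = as.integer(base_filters),
              downsample = as.integer(downsample),
              epochs = as.integer(epochs), lr = lr,
              batch_size = as.integer(batch_size),
              decay_start = as.integer(decay_start), seed = as.integer(seed),
              in_channels = as.integer(in_channels),
              front_kernel = as.integer(front_kernel),
              out_kernel = as.integer(out_kernel))
  class(cfg) <- "net_config"
  if (cfg$downsample < 1 || bitwAnd(cfg$downsample, cfg$downsample - 1L) != 0L)
    stop("downsample must be a power of 2")
  if (cfg$decay_start >= cfg$epochs) stop("decay_start must be < epochs")
  if (cfg$n_resblocks < 1) stop("need at least one residual block")
  cfg
}

#' Learning-rate schedule: constant, then linear decay to zero
#' @param epoch Epoch number (1-based).
#' @param cfg A [net_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (epoch <= cfg$decay_start) return(cfg$lr)
  cfg$lr * (cfg$epochs - epoch) / (cfg$epochs - cfg$decay_start)
}

#' Build the residual encoder-decoder network
#'
#' Parameter initialization is seeded from `cfg$seed`: two builds from the
#' same config are identical. Input slices must have sides divisible by
#' `cfg$downsample`.
#'
#' @param cfg A [net_config()].
#' @return A list of class `corr_net` with the layer stack and config.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  set.seed(cfg$seed)
  f <- cfg$base_filters
  n_down <- as.integer(round(log2(cfg$downsample)))
  layers <- list(layer_conv(cfg$in_channels, f, cfg$front_kernel),
                 layer_inorm(f), layer_relu())
  ch <- f
  for (i in seq_len(n_down)) {
    nxt <- if (i == 1L) 2L * f else ch
    layers <- c(layers, list(layer_conv(ch, nxt, 4L, stride = 2L, pad = 1L),
                             layer_inorm(nxt), layer_relu()))
    ch <- nxt
  }
  for (i in seq_len(cfg$n_resblocks))
    layers <- c(layers, list(layer_resblock(ch)))
  for (i in seq_len(n_down)) {
    nxt <- if (i == n_down) f else ch
    layers <- c(layers, list(layer_tconv(ch, nxt, 4L, stride = 2L, pad = 1L),
                             layer_inorm(nxt), layer_relu()))
    ch <- nxt
  }
  layers <- c(layers, list(layer_conv(ch, 1L, cfg$out_kernel)))
  structure(list(layers = layers, cfg = cfg), class = "corr_net")
}

net_forward <- function(net, x4) {
  for (l in net$layers) x4 <- layer_forward(l, x4)
  x4
}

net_backward <- function(net, dy4) {
  for (l in rev(net$layers)) dy4 <- layer_backward(l, dy4)
  dy4
}

#' @export
print.corr_net <- function(x, ...) {
  np <- sum(vapply(collect_param_layers(x$layers),
                   function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("<corr_net> %d resblocks, %d base filters, %s parameters\n",
              x$cfg$n_resblocks, x$cfg$base_filters, format(np, big.mark = ",")))
  invisible(x)
}

#' Assemble network input channels from a phantom
#'
#' Min-max scales each input volume (Dixon in-phase, Dixon out-of-phase,
#' four-class mu-map) to [0, 1] per volume, then zeroes everything outside
#' the body contour derived from the in-phase image. Volumes not on
#' `pet_grid` are first resampled onto it by trilinear interpolation.
#' Scaling is per volume, not per slice, so inter-slice intensity relations
#' are preserved.
#'
#' @param phantom A `phantom` (or any list with `dixon_ip`, `dixon_op`).
#' @param mu4c Four-class `mu_map`.
#' @param pet_grid Optional `image_volume` defining the PET grid; defaults
#'   to the phantom grid.
#' @return List: `channels` array (H, W, 3, n_slices), `body_mask`.
#' @export
preprocess_inputs <- function(phantom, mu4c, pet_grid = NULL) {
  vols <- list(phantom$dixon_ip, phantom$dixon_op, mu4c$volume)
  if (!is.null(pet_grid))
    vols <- lapply(vols, resample_to_grid, target = pet_grid)
  scaled <- lapply(vols, function(v) {
    rng <- range(v$data)
    if (diff(rng) <= 0) stop("cannot min-max scale a constant volume")
    (v$data - rng[1]) / diff(rng)
  })
  body <- body_contour_mask(with_data(vols[[1]], scaled[[1]]))
  d <- dim(scaled[[1]])
  ch <- array(0, dim = c(d[1], d[2], 3, d[3]))
  for (k in 1:3) {
    s <- scaled[[k]]
    s[!body] <- 0
    ch[, , k, ] <- aperm(s, c(1, 2, 3))
  }
  list(channels = ch, body_mask = body)
}

#' Build training samples from a phantom and its exact correction map
#'
#' Pairs each axial slice's input channels with the corresponding
#' correction-map slice and its validity mask (the loss weight). Slices with
#' no valid voxels are dropped. Targets are clamped to `clamp_range` — the
#' same range applied to predictions before use — so capacity is not spent
#' on correction values the applied map could never express.
#'
#' @param phantom A `phantom`.
#' @param mu4c Four-class `mu_map`.
#' @param cmap Exact `correction_map` from [compute_correction_map()].
#' @param clamp_range Clamp interval for the training targets.
#' @return List of samples: `x` (H, W, 3), `target` (H, W), `weight` (H, W).
#' @export
make_training_samples <- function(phantom, mu4c, cmap, clamp_range = c(-2, 1)) {
  pp <- preprocess_inputs(phantom, mu4c)
  d <- dim(phantom$dixon_ip$data)
  out <- list()
  for (z in seq_len(d[3])) {
    w <- cmap$valid_mask[, , z] * 1
    if (!any(w > 0)) next
    tgt <- pmin(pmax(cmap$volume$data[, , z], clamp_range[1]), clamp_range[2])
    out[[length(out) + 1L]] <- list(x = pp$channels[, , , z],
                                    target = tgt,
                                    weight = w)
  }
  out
}

masked_mse <- function(pred, target, weight) {
  sw <- sum(weight)
  if (sw <= 0) return(list(loss = 0, grad = pred * 0))
  diff <- (pred - target) * weight
  list(loss = sum(diff * (pred - target)) / sw, grad = 2 * diff / sw)
}

stack_batch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$x)
  B <- length(idx)
  x <- array(0, dim = c(d[1], d[2], d[3], B))
  t <- array(0, dim = c(d[1], d[2], 1, B))
  w <- array(0, dim = c(d[1], d[2], 1, B))
  for (i in seq_along(idx)) {
    x[, , , i] <- samples[[idx[i]]]$x
    t[, , 1, i] <- samples[[idx[i]]]$target
    w[, , 1, i] <- samples[[idx[i]]]$weight
  }
  list(x = x, target = t, weight = w)
}

eval_loss <- function(net, samples, batch_size = 16L) {
  n <- length(samples)
  tot <- 0; wtot <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    b <- stack_batch(samples, idx)
    pred <- net_forward(net, b$x)
    sw <- sum(b$weight)
    tot <- tot + sum(b$weight * (pred - b$target)^2)
    wtot <- wtot + sw
  }
  tot / max(wtot, 1e-12)
}

#' Train the correction-map network
#'
#' Masked L2 loss (mean squared error over valid-mask voxels only; voxels
#' outside the mask carry zero weight and do not bias the network toward
#' zero at mask borders), Adam optimizer, learning rate per [lr_schedule()].
#' When validation samples are given, the parameter snapshot with the best
#' validation loss is restored at the end.
#'
#' @param net A `corr_net` from [build_network()].
#' @param samples Training samples from [make_training_samples()].
#' @param val_samples Optional validation samples.
#' @param verbose Print per-epoch losses?
#' @return The trained `corr_net`, with a `history` data.frame attached
#'   (`epoch`, `lr`, `train_loss`, `val_loss`).
#' @export
train_network <- function(net, samples, val_samples = NULL, verbose = FALSE) {
  if (!length(samples)) stop("empty training set")
  cfg <- net$cfg
  pl <- collect_param_layers(net$layers)
  n <- length(samples)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_loss = numeric())
  best_val <- Inf; best_snap <- NULL
  t_adam <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch, cfg)
    set.seed(cfg$seed + 1000L * epoch)
    ord <- sample.int(n)
    ep_loss <- 0; ep_w <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      b <- stack_batch(samples, idx)
      pred <- net_forward(net, b$x)
      lm <- masked_mse(pred, b$target, b$weight)
      if (!is.finite(lm$loss))
        stop(sprintf("non-finite loss at epoch %d (lr %.2g)", epoch, lr))
      ep_loss <- ep_loss + lm$loss * sum(b$weight)
      ep_w <- ep_w + sum(b$weight)
      if (lr > 0) {
        net_backward(net, lm$grad)
        t_adam <- t_adam + 1L
        adam_step(pl, lr, t_adam)
      }
    }
    train_loss <- ep_loss / max(ep_w, 1e-12)
    val_loss <- if (!is.null(val_samples)) eval_loss(net, val_samples,
                                                     cfg$batch_size) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = train_loss,
                                   val_loss = val_loss))
    if (!is.null(val_samples) && is.finite(val_loss) && val_loss < best_val) {
      best_val <- val_loss
      best_snap <- snapshot_params(pl)
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.5f  val %s", epoch, lr,
                      train_loss,
                      if (is.na(val_loss)) "-" else sprintf("%.5f", val_loss)))
  }
  if (!is.null(best_snap)) restore_params(pl, best_snap)
  net$history <- hist
  net
}

#' Save a trained network to disk
#'
#' The checkpoint embeds the full [net_config()] together with every
#' parameter tensor and the loss history; geometry caches are not stored.
#'
#' @param net A `corr_net`.
#' @param path Output path (an RDS file).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  pl <- collect_param_layers(net$layers)
  saveRDS(list(cfg = net$cfg, params = snapshot_params(pl),
               history = net$history), path)
  invisible(path)
}

#' Load a network saved by [save_network()]
#' @param path Path to the checkpoint.
#' @return A `corr_net` with restored parameters and history.
#' @export
load_network <- function(path) {
  chk <- readRDS(path)
  net <- build_network(chk$cfg)
  restore_params(collect_param_layers(net$layers), chk$params)
  net$history <- chk$history
  net
}

#' Predict a correction map for a phantom
#'
#' Runs slice-wise inference on the preprocessed input channels, reassembles
#' the axial slices into a 3D map, clamps the values to `clamp_range`, and
#' zeroes everything outside the pelvic mask (the map is only estimated
#' there). Deterministic.
#'
#' @param net A trained `corr_net`.
#' @param phantom A `phantom`.
#' @param mu4c Four-class `mu_map`.
#' @param pelvic_mask Logical array; defaults to `phantom$pelvic_mask`.
#' @param pet_grid Optional target grid for resampling.
#' @param clamp_range Clamp interval applied to the prediction.
#' @param batch_size Slices per inference batch.
#' @return A `correction_map` with `valid_mask = pelvic_mask`.
#' @export
predict_correction_map <- function(net, phantom, mu4c, pelvic_mask = NULL,
                                   pet_grid = NULL, clamp_range = c(-2, 1),
                                   batch_size = 16L) {
  if (is.null(pelvic_mask)) pelvic_mask <- phantom$pelvic_mask
  pp <- preprocess_inputs(phantom, mu4c, pet_grid)
  d <- dim(pp$channels)
  nz <- d[4]
  out <- array(0, dim = c(d[1], d[2], nz))
  for (start in seq(1, nz, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, nz)
    x <- pp$channels[, , , idx, drop = FALSE]
    pred <- net_forward(net, x)
    out[, , idx] <- pred[, , 1, ]
  }
  out <- pmin(pmax(out, clamp_range[1]), clamp_range[2])
  out[!pelvic_mask] <- 0
  ref <- if (is.null(pet_grid)) phantom$dixon_ip else pet_grid
  correction_map(image_volume(out, ref$spacing, ref$origin, "dimensionless"),
                 pelvic_mask)
}
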
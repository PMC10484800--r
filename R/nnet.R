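# Minimal 2D convolutional network engine.
#
# Activations are 4D arrays (H, W, C, B). Convolutions are im2col gathers
# followed by BLAS matrix multiplies; transposed convolutions reuse the same
# geometry through the adjoint (scatter) path. Each layer is an environment
# holding parameters, Adam state and the forward cache. Everything is
# deterministic given the R RNG state at initialization.

conv_geometry <- function(H, W, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  outH <- (Hp - k) %/% stride + 1L
  outW <- (Wp - k) %/% stride + 1L
  if ((Hp - k) %% stride != 0L || (Wp - k) %% stride != 0L)
    stop("input size incompatible with kernel/stride/padding")
  i0 <- (seq_len(outH) - 1L) * stride + 1L
  j0 <- (seq_len(outW) - 1L) * stride + 1L
  base <- as.integer(outer(i0, (j0 - 1L) * Hp, "+"))    # P, i fastest
  koff <- as.integer(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))  # k^2
  Idx <- outer(base, koff, "+")                          # P x k^2, padded
  # re-express in unpadded coordinates; 0 marks a padding position
  pr <- (Idx - 1L) %% Hp + 1L - pad
  pc <- (Idx - 1L) %/% Hp + 1L - pad
  ok <- pr >= 1L & pr <= H & pc >= 1L & pc <= W
  Idx0 <- ifelse(ok, pr + (pc - 1L) * H, 0L)
  list(H = H, W = W, outH = outH, outW = outW,
       k = k, stride = stride, pad = pad, Idx0 = Idx0)
}

# Full gather index for a batched, multi-channel activation (H, W, C, B):
# rows are (output position, batch), columns are (kernel element, channel),
# so one gather yields the whole im2col matrix. Zeros mark padding.
full_index <- function(geom, C, B) {
  P <- nrow(geom$Idx0)
  plane <- geom$H * geom$W
  M <- geom$Idx0[rep(seq_len(P), B), , drop = FALSE]
  sentinel <- M == 0L
  M <- M + rep((seq_len(B) - 1L) * plane * C, each = P)
  out <- do.call(cbind, lapply(seq_len(C) - 1L, function(c0) M + c0 * plane))
  out[rep(sentinel, C)] <- 0L
  out
}

# gather the im2col matrix ((P*B) x (k^2*C)) from a padded activation
im2col <- function(xp, IdxF) {
  gather_cols(xp, IdxF)
}

# adjoint of im2col: scatter-add columns back into an activation
col2im <- function(cols, IdxF, H, W, C, B, k2) {
  acc <- scatter_add_cols(cols, IdxF, H * W * C * B)
  array(acc, dim = c(H, W, C, B))
}

he_init <- function(n_in, n_out, k2) {
  matrix(rnorm(k2 * n_in * n_out, sd = sqrt(2 / (k2 * n_in))), k2 * n_in, n_out)
}

layer_conv <- function(Cin, Cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$pad <- as.integer(pad); e$Cin <- Cin; e$Cout <- Cout
  e$W <- he_init(Cin, Cout, k * k)
  e$b <- numeric(Cout)
  e$geo <- NULL; e$idx_cache <- list()
  e
}

layer_tconv <- function(Cin, Cout, k, stride = 2L, pad = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "tconv"; e$k <- as.integer(k); e$stride <- as.integer(stride)
  e$pad <- as.integer(pad); e$Cin <- Cin; e$Cout <- Cout
  # weight indexed like the adjoint conv: (k^2*Cout) x Cin
  e$W <- matrix(rnorm(k * k * Cout * Cin, sd = sqrt(2 / (k * k * Cin))),
                k * k * Cout, Cin)
  e$b <- numeric(Cout)
  e$geo <- NULL; e$idx_cache <- list()
  e
}

layer_inorm <- function(C, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "inorm"; e$C <- C; e$eps <- eps
  e$W <- rep(1, C)     # gamma
  e$b <- rep(0, C)     # beta
  e
}

layer_relu <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "relu"; e
}

layer_resblock <- function(C, k = 3L) {
  e <- new.env(parent = emptyenv())
  e$type <- "resblock"
  e$inner <- list(layer_conv(C, C, k), layer_inorm(C), layer_relu(),
                  layer_conv(C, C, k), layer_inorm(C))
  e
}

get_idx <- function(layer, geo, C, B) {
  key <- paste0(C, "_", B)
  idx <- layer$idx_cache[[key]]
  if (is.null(idx)) {
    idx <- full_index(geo, C, B)
    layer$idx_cache[[key]] <- idx
  }
  idx
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      d <- dim(x); B <- d[4]
      if (is.null(layer$geo) || layer$geo$H != d[1] || layer$geo$W != d[2]) {
        layer$geo <- conv_geometry(d[1], d[2], layer$k, layer$stride, layer$pad)
        layer$idx_cache <- list()
      }
      g <- layer$geo
      IdxF <- get_idx(layer, g, layer$Cin, B)
      X <- im2col(x, IdxF)
      Y <- sweep(X %*% layer$W, 2, layer$b, "+")
      layer$cache <- list(X = X, B = B, d = d)
      aperm(array(Y, dim = c(g$outH, g$outW, B, layer$Cout)), c(1, 2, 4, 3))
    },
    tconv = {
      d <- dim(x); B <- d[4]
      outH <- d[1] * layer$stride; outW <- d[2] * layer$stride
      if (is.null(layer$geo) || layer$geo$H != outH || layer$geo$W != outW) {
        layer$geo <- conv_geometry(outH, outW, layer$k, layer$stride, layer$pad)
        if (layer$geo$outH != d[1] || layer$geo$outW != d[2])
          stop("transposed-conv geometry inconsistent")
        layer$idx_cache <- list()
      }
      g <- layer$geo
      IdxF <- get_idx(layer, g, layer$Cout, B)
      Um <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * B, layer$Cin)
      S <- Um %*% t(layer$W)                       # (P*B) x (k^2*Cout)
      y <- col2im(S, IdxF, outH, outW, layer$Cout, B, g$k^2)
      y <- sweep(y, 3, layer$b, "+")
      layer$cache <- list(Um = Um, B = B, d = d)
      y
    },
    inorm = {
      d <- dim(x); N <- d[1] * d[2]
      M <- matrix(x, N, d[3] * d[4])
      mu <- colMeans(M)
      v <- colMeans(M * M) - mu^2
      inv <- 1 / sqrt(v + layer$eps)
      Xh <- (M - rep(mu, each = N)) * rep(inv, each = N)
      grep_ <- rep(layer$W, d[4]); brep <- rep(layer$b, d[4])
      Y <- Xh * rep(grep_, each = N) + rep(brep, each = N)
      layer$cache <- list(Xh = Xh, inv = inv, d = d, N = N)
      array(Y, dim = d)
    },
    relu = {
      layer$cache <- list(mask = x > 0)
      x * layer$cache$mask
    },
    resblock = {
      h <- x
      for (l in layer$inner) h <- layer_forward(l, h)
      x + h
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, dy) {
  force(dy)   # dy may be a lazy expression whose evaluation fills the caches
  switch(layer$type,
    conv = {
      g <- layer$geo; cc <- layer$cache; B <- cc$B
      dYm <- matrix(aperm(dy, c(1, 2, 4, 3)), g$outH * g$outW * B, layer$Cout)
      layer$dW <- crossprod(cc$X, dYm)
      layer$db <- colSums(dYm)
      dX <- dYm %*% t(layer$W)
      IdxF <- get_idx(layer, g, layer$Cin, B)
      col2im(dX, IdxF, cc$d[1], cc$d[2], layer$Cin, B, g$k^2)
    },
    tconv = {
      g <- layer$geo; cc <- layer$cache; B <- cc$B
      layer$db <- apply(dy, 3, sum)
      IdxF <- get_idx(layer, g, layer$Cout, B)
      Xdy <- im2col(dy, IdxF)
      layer$dW <- crossprod(Xdy, cc$Um)
      dUm <- Xdy %*% layer$W
      aperm(array(dUm, dim = c(cc$d[1], cc$d[2], B, layer$Cin)), c(1, 2, 4, 3))
    },
    inorm = {
      cc <- layer$cache; d <- cc$d; N <- cc$N
      D <- matrix(dy, N, d[3] * d[4])
      grep_ <- rep(layer$W, d[4])
      dg_cb <- colSums(D * cc$Xh)
      db_cb <- colSums(D)
      layer$dW <- rowSums(matrix(dg_cb, d[3], d[4]))
      layer$db <- rowSums(matrix(db_cb, d[3], d[4]))
      dXh <- D * rep(grep_, each = N)
      s1 <- colSums(dXh)
      s2 <- colSums(dXh * cc$Xh)
      dx <- (dXh - rep(s1 / N, each = N) - cc$Xh * rep(s2 / N, each = N)) *
        rep(cc$inv, each = N)
      array(dx, dim = d)
    },
    relu = dy * layer$cache$mask,
    resblock = {
      dh <- dy
      for (l in rev(layer$inner)) dh <- layer_backward(l, dh)
      dy + dh
    },
    stop("unknown layer type"))
}

collect_param_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "resblock") out <- c(out, collect_param_layers(l$inner))
    else if (!is.null(l$W)) out <- c(out, list(l))
  }
  out
}

adam_step <- function(param_layers, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in param_layers) {
    if (is.null(l$mW)) {
      l$mW <- l$W * 0; l$vW <- l$W * 0
      l$mb <- l$b * 0; l$vb <- l$b * 0
    }
    l$mW <- beta1 * l$mW + (1 - beta1) * l$dW
    l$vW <- beta2 * l$vW + (1 - beta2) * l$dW^2
    l$mb <- beta1 * l$mb + (1 - beta1) * l$db
    l$vb <- beta2 * l$vb + (1 - beta2) * l$db^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    l$W <- l$W - lr * (l$mW / c1) / (sqrt(l$vW / c2) + eps)
    l$b <- l$b - lr * (l$mb / c1) / (sqrt(l$vb / c2) + eps)
  }
  invisible(NULL)
}

snapshot_params <- function(param_layers) {
  lapply(param_layers, function(l) list(W = l$W, b = l$b))
}

restore_params <- function(param_layers, snap) {
  for (i in seq_along(param_layers)) {
    param_layers[[i]]$W <- snap[[i]]$W
    param_layers[[i]]$b <- snap[[i]]$b
  }
  invisible(NULL)
}
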
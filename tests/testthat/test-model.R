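tiny_cfg <- function(...) {
  net_config(n_resblocks = 1, base_filters = 8, epochs = 2, decay_start = 1,
             batch_size = 2, seed = 5, ...)
}

test_that("the network preserves spatial resolution and rejects bad sizes", {
  net <- build_network(tiny_cfg())
  for (hw in list(c(32L, 32L), c(48L, 64L))) {
    x <- array(runif(prod(hw) * 3 * 2), c(hw, 3L, 2L))
    y <- net_forward(net, x)
    expect_identical(dim(y), c(hw, 1L, 2L))
    expect_true(all(is.finite(y)))
  }
  net2 <- build_network(tiny_cfg())
  x <- array(runif(30 * 30 * 3), c(30, 30, 3, 1))   # not divisible by 4
  expect_error(net_forward(net2, x), "incompatible")
})

test_that("two builds from the same seed have identical parameters", {
  p1 <- petcorr:::collect_param_layers(build_network(tiny_cfg())$layers)
  p2 <- petcorr:::collect_param_layers(build_network(tiny_cfg())$layers)
  for (i in seq_along(p1)) expect_identical(p1[[i]]$W, p2[[i]]$W)
})

test_that("analytic gradients match central finite differences", {
  net <- build_network(net_config(n_resblocks = 1, base_filters = 4,
                                  epochs = 2, decay_start = 1, seed = 2))
  set.seed(14)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  loss <- function() { p <- net_forward(net, x); sum(p^2) / 2 }
  invisible(petcorr:::net_backward(net, net_forward(net, x)))
  pl <- petcorr:::collect_param_layers(net$layers)
  eps <- 1e-5
  for (l in pl[c(1, 3, 5, length(pl))]) {
    i <- min(3, length(l$W)); w0 <- l$W[i]
    l$W[i] <- w0 + eps; fp <- loss()
    l$W[i] <- w0 - eps; fm <- loss()
    l$W[i] <- w0
    num <- (fp - fm) / (2 * eps)
    expect_equal(l$dW[i], num, tolerance = 1e-5)
  }
})

test_that("the learning-rate schedule is constant then linearly decaying", {
  cfg <- net_config(epochs = 100, decay_start = 50, lr = 2e-4)
  expect_equal(lr_schedule(1, cfg), 2e-4)
  expect_equal(lr_schedule(50, cfg), 2e-4)
  expect_equal(lr_schedule(75, cfg), 1e-4)
  expect_equal(lr_schedule(100, cfg), 0)
})

test_that("preprocessing min-max scales per volume and zeroes outside the body", {
  cs <- small_case()
  pp <- preprocess_inputs(cs$phantom, cs$mu4c)
  for (k in 1:3) {
    ch <- pp$channels[, , k, ]
    expect_gte(min(ch), 0); expect_lte(max(ch), 1)
    expect_true(all(ch[!pp$body_mask] == 0))
  }
  # scaling is exact: a volume with min 10 max 110 maps v to (v-10)/100
  v <- cs$phantom$dixon_ip
  rng <- range(v$data)
  scaled <- (v$data - rng[1]) / diff(rng)
  inside <- pp$body_mask
  expect_equal(pp$channels[, , 1, ][inside], scaled[inside], tolerance = 1e-12)
  # constant volumes cannot be scaled
  ph2 <- cs$phantom
  ph2$dixon_op <- with_data(ph2$dixon_op, array(3, dim(ph2$dixon_op$data)))
  expect_error(preprocess_inputs(ph2, cs$mu4c), "constant")
})

test_that("training on zero targets drives predictions toward zero", {
  set.seed(20)
  samples <- lapply(1:4, function(i)
    list(x = array(runif(16 * 16 * 3), c(16, 16, 3)),
         target = matrix(0, 16, 16),
         weight = matrix(1, 16, 16)))
  cfg <- net_config(n_resblocks = 1, base_filters = 4, epochs = 10,
                    decay_start = 5, lr = 1e-3, batch_size = 4, seed = 3)
  net <- train_network(build_network(cfg), samples)
  h <- net$history$train_loss
  expect_lt(tail(h, 1), h[1])
})

test_that("the masked loss ignores target values outside the weight mask", {
  set.seed(21)
  w <- matrix(0, 16, 16); w[5:12, 5:12] <- 1
  s1 <- list(list(x = array(runif(16 * 16 * 3), c(16, 16, 3)),
                  target = matrix(rnorm(256), 16, 16), weight = w))
  s2 <- s1
  s2[[1]]$target[w == 0] <- 99        # garbage outside the mask
  net <- build_network(tiny_cfg())
  l1 <- petcorr:::eval_loss(net, s1)
  l2 <- petcorr:::eval_loss(net, s2)
  expect_identical(l1, l2)
})

test_that("training is deterministic given the seed", {
  set.seed(22)
  samples <- lapply(1:4, function(i)
    list(x = array(runif(16 * 16 * 3), c(16, 16, 3)),
         target = matrix(rnorm(256, sd = 0.1), 16, 16),
         weight = matrix(1, 16, 16)))
  cfg <- net_config(n_resblocks = 1, base_filters = 4, epochs = 3,
                    decay_start = 2, lr = 1e-3, batch_size = 2, seed = 9)
  h1 <- train_network(build_network(cfg), samples)$history
  h2 <- train_network(build_network(cfg), samples)$history
  expect_identical(h1$train_loss, h2$train_loss)
})

test_that("a single seeded sample can be overfit far below its initial loss", {
  cs <- small_case()
  samples <- make_training_samples(cs$phantom, cs$mu4c, cs$cmap)
  cfg <- net_config(n_resblocks = 1, base_filters = 8, epochs = 150,
                    decay_start = 100, lr = 2e-3, batch_size = 1, seed = 7)
  net <- train_network(build_network(cfg), samples[1])
  h <- net$history$train_loss
  expect_lt(tail(h, 1), 0.1 * h[1])
})

test_that("prediction is deterministic, clamped and masked", {
  cs <- small_case()
  cfg <- tiny_cfg()
  net <- build_network(cfg)
  p1 <- predict_correction_map(net, cs$phantom, cs$mu4c)
  p2 <- predict_correction_map(net, cs$phantom, cs$mu4c)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_true(all(p1$volume$data[!cs$phantom$pelvic_mask] == 0))
  expect_gte(min(p1$volume$data), -2)
  expect_lte(max(p1$volume$data), 1)
  # all-false mask forces the zero map
  p0 <- predict_correction_map(net, cs$phantom, cs$mu4c,
                               pelvic_mask = array(FALSE,
                                                   dim(cs$phantom$labels$data)))
  expect_true(all(p0$volume$data == 0))
})

test_that("training targets are clamped to the application range", {
  cs <- small_case()
  samples <- make_training_samples(cs$phantom, cs$mu4c, cs$cmap,
                                   clamp_range = c(-2, 1))
  tmin <- min(vapply(samples, function(s) min(s$target), numeric(1)))
  expect_gte(tmin, -2)
  raw_min <- min(cs$cmap$volume$data)
  if (raw_min < -2) expect_equal(tmin, -2)
})

test_that("a saved checkpoint restores the exact predictions", {
  cs <- small_case()
  net <- build_network(tiny_cfg())
  p1 <- predict_correction_map(net, cs$phantom, cs$mu4c)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  save_network(net, path)
  net2 <- load_network(path)
  p2 <- predict_correction_map(net2, cs$phantom, cs$mu4c)
  expect_identical(p2$volume$data, p1$volume$data)
})
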
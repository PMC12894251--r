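test_that("conv_layer matches direct convolution including dilation", {
  # frozen 1-D example: input (1,2,3,4,5), kernel (1,0,-1), dilation 2
  x <- array(c(1, 2, 3, 4, 5), c(1, 5, 1))
  w <- array(c(1, 0, -1), c(1, 3, 1, 1))
  pre <- conv_layer(x, w, 0, dilation = 2, activation = "linear")
  expect_equal(as.vector(pre), c(-3, -4, -4, 2, 3))
  expect_equal(as.vector(conv_layer(x, w, 0, dilation = 2)),
               c(0, 0, 0, 2, 3))
  # zero weights: bias fills the map, ReLU clamps negatives
  z <- array(0, c(3, 3, 2, 4))
  inp <- array(runif(18), c(3, 3, 2))
  expect_equal(as.vector(conv_layer(inp, z, c(2, -1, 0.5, -3))),
               rep(c(2, 0, 0.5, 0), each = 9))
  # 2-D random case against the brute-force oracle, rates 1 and 6
  set.seed(31)
  img <- matrix(rnorm(81), 9, 9)
  k <- matrix(rnorm(9), 3, 3)
  for (d in c(1L, 6L)) {
    got <- conv_layer(array(img, c(9, 9, 1)), array(k, c(3, 3, 1, 1)), 0,
                      dilation = d, activation = "linear")
    expect_equal(got[, , 1], conv2d_oracle(img, k, d), tolerance = 1e-12)
  }
  expect_error(conv_layer(array(0, c(4, 4, 2)), array(0, c(3, 3, 3, 1)), 0),
               "channel mismatch")
})

test_that("max pooling matches a brute-force window maximum", {
  expect_equal(as.vector(max_pool2(array(c(1, 3, 2, 4), c(2, 2, 1)))), 4)
  cst <- array(7, c(6, 6, 2))
  expect_equal(max_pool2(cst), array(7, c(3, 3, 2)))
  set.seed(17)
  x <- array(rnorm(72), c(6, 6, 2))
  got <- max_pool2(x)
  for (c in 1:2) for (i in 1:3) for (j in 1:3)
    expect_equal(got[i, j, c],
                 max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]))
})

test_that("encoder feature geometry follows the five-block topology", {
  cfg <- tiny_cfg(input_size = c(256L, 256L))
  m <- create_model(cfg, seed = 2)
  f <- encode(matrix(runif(256 * 256), 256, 256), m)
  expect_equal(vapply(list(f$E1, f$E2, f$E3, f$E4), function(e) dim(e)[1],
                      numeric(1)), c(256, 128, 64, 32))
  expect_equal(dim(f$bottleneck_in)[1:2], c(8L, 8L))
  expect_equal(dim(f$E1)[3], cfg$block_widths[1])
  expect_error(encode(matrix(0, 100, 100), m), "divisible by 32")
  expect_error(msdasp_config("desk", convs_per_block = c(2L, 2L, 2L, 2L, 2L)),
               "13 convolutional layers")
})

test_that("ASPP branches agree with direct-summation oracles", {
  cfg <- tiny_cfg()
  m <- create_model(cfg, seed = 4)
  set.seed(5)
  x <- array(rnorm(9 * 9 * 2), c(9, 9, 2))
  # rate-1 branch is an ordinary 1x1 convolution
  p1 <- m$params$aspp$branches[[1]]
  r1 <- conv_layer(x, p1$w, p1$b, dilation = 1, activation = "linear")
  w1 <- matrix(p1$w[1, 1, , ], 2, 2)
  man <- array(0, c(9, 9, 2))
  for (o in 1:2)
    man[, , o] <- x[, , 1] * w1[1, o] + x[, , 2] * w1[2, o] + p1$b[o]
  expect_equal(r1, man, tolerance = 1e-12)
  # rate-6 3x3 branch against the dilated brute-force oracle
  p6 <- m$params$aspp$branches[[2]]
  r6 <- conv_layer(x, p6$w, p6$b, dilation = 6, activation = "linear")
  for (o in 1:2) {
    acc <- matrix(p6$b[o], 9, 9)
    for (ci in 1:2)
      acc <- acc + conv2d_oracle(x[, , ci], p6$w[, , ci, o], 6L)
    expect_equal(r6[, , o], acc, tolerance = 1e-12)
  }
  # output spatial size preserved for the full configured rate set
  out <- aspp(x, m)
  expect_equal(dim(out), c(9L, 9L, cfg$aspp_out_channels))
  # constant input: every pre-fusion branch map is spatially constant and
  # the GAP branch reproduces the rate-1-style response
  xc <- array(1.5, c(8, 8, 2))
  for (i in seq_along(m$params$aspp$branches)) {
    p <- m$params$aspp$branches[[i]]
    d <- if (i <= 4) cfg$dilation_rates[i] else 1L
    b <- conv_layer(xc, p$w, p$b, dilation = d, activation = "linear")
    mid <- b[4, 4, ]  # interior pixel, away from zero padding
    expect_equal(as.vector(b[4, 5, ]), as.vector(mid), tolerance = 1e-12)
  }
  gp <- m$params$aspp$branches[[5]]
  gap_resp <- conv_layer(array(1.5, c(1, 1, 2)), gp$w, gp$b,
                         activation = "linear")
  expect_equal(dim(gap_resp)[1:2], c(1L, 1L))
})

test_that("spatial and channel attention match brute-force evaluation", {
  set.seed(42)
  X <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  w <- array(rnorm(7 * 7 * 2) * 0.3, c(7, 7, 2, 1))
  b <- 0.1
  sa <- spatial_attention(X, w, b)
  favg <- apply(X, c(1, 2), mean)
  fmax <- apply(X, c(1, 2), max)
  s <- conv2d_oracle(favg, w[, , 1, 1], 1L) +
    conv2d_oracle(fmax, w[, , 2, 1], 1L) + b
  As <- 1 / (1 + exp(-s))
  expect_equal(sa$A_s, As, tolerance = 1e-12)
  expect_equal(sa$X_s, X * as.vector(As), tolerance = 1e-12)
  expect_true(all(sa$A_s > 0 & sa$A_s < 1))
  expect_equal(spatial_attention(X * 0, w, b)$X_s, X * 0)

  Xs <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  W1 <- matrix(rnorm(8), 2, 4) * 0.5
  W2 <- matrix(rnorm(4), 2, 2) * 0.5
  b2 <- c(0.1, -0.2)
  ca <- channel_attention(Xs, W1, W2, b2)
  z <- c(apply(Xs, 3, mean), apply(Xs, 3, max))
  Ac <- as.vector(1 / (1 + exp(-(W2 %*% pmax(W1 %*% z, 0) + b2))))
  expect_equal(ca$A_c, Ac, tolerance = 1e-12)
  expect_equal(ca$X_c, Xs * rep(Ac, each = 9), tolerance = 1e-12)
  expect_true(all(ca$A_c > 0 & ca$A_c < 1))
  # an all-zero channel stays all-zero after channel scaling
  Xs0 <- Xs; Xs0[, , 2] <- 0
  expect_equal(channel_attention(Xs0, W1, W2, b2)$X_c[, , 2],
               matrix(0, 3, 3))
})

test_that("dual-headed attention composes the two gates in order", {
  cfg <- tiny_cfg()
  m <- create_model(cfg, seed = 6)
  p <- m$params$decoder$levels[[3]]$dha
  set.seed(7)
  C <- dim(p$W2)[1]
  X <- array(rnorm(8 * 8 * C), c(8, 8, C))
  out <- dha(X, p)
  expect_equal(dim(out), dim(X))
  sa <- spatial_attention(X, p$spatial$w, p$spatial$b)
  ca <- channel_attention(sa$X_s, p$W1, p$W2, p$b2)
  expect_equal(as.array(out), ca$X_c, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(out, "A_s"), sa$A_s)
  expect_equal(attr(out, "A_c"), ca$A_c)
  # saturated gates (huge positive biases, zero weights) act as identity
  sat <- p
  sat$spatial$w[] <- 0; sat$spatial$b <- 20
  sat$W1[] <- 0; sat$W2[] <- 0; sat$b2[] <- 20
  expect_lt(max(abs(dha(X, sat) - X)), 1e-3)
})

test_that("the full forward pass yields calibrated probability maps", {
  cfg <- tiny_cfg()
  m <- create_model(cfg, seed = 8)
  img <- matrix(runif(64 * 64), 64, 64)
  pred <- net_predict(m, img)
  expect_equal(dim(pred$probabilities), c(64L, 64L))
  expect_true(all(pred$probabilities > 0 & pred$probabilities < 1))
  expect_identical(pred$binary_mask,
                   array(as.integer(pred$probabilities >= 0.5), c(64L, 64L)))
  # forcing the head to a large negative bias empties the mask
  m2 <- m
  m2$params$head$w[] <- 0
  m2$params$head$b <- -20
  expect_equal(sum(net_predict(m2, img)$binary_mask), 0)
  # two inference passes are identical (dropout off at inference)
  cfg_d <- tiny_cfg(dropout_rate = 0.5)
  md <- create_model(cfg_d, seed = 9)
  expect_identical(net_predict(md, img), net_predict(md, img))
  # parameter count is reported and content-independent
  expect_identical(count_params(m),
                   sum(model_summary(m)$count))
  expect_gt(count_params(m), 0)
})

test_that("backpropagation matches finite differences end to end", {
  cfg <- tiny_cfg()
  m <- create_model(cfg, seed = 3)
  set.seed(9)
  img <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(0, 64, 64); y[20:30, 20:30] <- 1
  f <- msdaspnet:::net_forward(m, img)
  bw <- msdaspnet:::net_backward(m, f$cache, (f$prob - y) / length(y))
  g <- msdaspnet:::flatten_params(bw$grads)
  th <- msdaspnet:::flatten_params(m$params)
  skel <- m$params
  set.seed(11)
  idx <- sample(length(th), 25)
  eps <- 1e-5
  loss_at <- function(v) {
    m$params <- msdaspnet:::unflatten_like(skel, v)
    bce_loss(y, msdaspnet:::net_forward(m, img)$prob)$mean
  }
  for (i in idx) {
    tp <- th; tp[i] <- th[i] + eps; lp <- loss_at(tp)
    tp[i] <- th[i] - eps; lm <- loss_at(tp)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-3)
  }
})

test_that("encoder features are covariant under a 32-pixel shift", {
  # integer shift at every encoder stride; content kept off the borders so
  # zero-padding effects cannot reach it
  cfg <- tiny_cfg(input_size = c(128L, 128L))
  m <- create_model(cfg, seed = 12)
  img <- matrix(0, 128, 128)
  img[33:56, 33:56] <- matrix(runif(24 * 24), 24, 24)
  sh <- matrix(0, 128, 128)
  sh[65:88, 33:56] <- img[33:56, 33:56]
  f1 <- encode(img, m)
  f2 <- encode(sh, m)
  strides <- c(1L, 2L, 4L, 8L)
  for (k in 1:4) {
    e1 <- f1[[k]]; e2 <- f2[[k]]
    s <- strides[k]
    d <- 32L %/% s
    rows <- (24L %/% s):(72L %/% s)
    cols <- (24L %/% s):(104L %/% s)
    expect_lt(max(abs(e2[rows + d, cols, ] - e1[rows, cols, ])), 1e-6)
  }
})

test_that("attention saturation reduces the network to a plain skip U-net", {
  cfg <- tiny_cfg()
  m <- create_model(cfg, seed = 14)
  msat <- m
  for (k in 1:4) {
    msat$params$decoder$levels[[k]]$dha$spatial$w[] <- 0
    msat$params$decoder$levels[[k]]$dha$spatial$b <- 20
    msat$params$decoder$levels[[k]]$dha$W1[] <- 0
    msat$params$decoder$levels[[k]]$dha$W2[] <- 0
    msat$params$decoder$levels[[k]]$dha$b2[] <- 20
  }
  img <- matrix(runif(64 * 64), 64, 64)
  f <- msdaspnet:::net_forward(msat, img)
  # with unit gates, each DHA output equals its input skip feature
  for (k in 1:4)
    expect_lt(max(abs(f$cache$levels[[k]]$att$out -
                        f$cache$enc$E[[k]])), 1e-3)
})

test_that("the upsampled attention site is available and shape-consistent", {
  cfg <- tiny_cfg(attention_site = "upsampled")
  m <- create_model(cfg, seed = 15)
  img <- matrix(runif(64 * 64), 64, 64)
  pred <- net_predict(m, img)
  expect_equal(dim(pred$probabilities), c(64L, 64L))
})
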
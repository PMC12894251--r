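#' Network configuration
#'
#' Assembles the configuration of the U-shaped segmentation network: a
#' VGG-16-topology encoder (five blocks, 13 convolutional layers), an atrous
#' spatial pyramid pooling (ASPP) bottleneck, dual-headed attention (DHA)
#' gates on the skip connections, and a five-stage decoder ending in a 1x1
#' convolution with sigmoid output.
#'
#' Two named profiles are provided. `"reference"` uses the published
#' geometry: 256x256 inputs, VGG-16 encoder widths (64, 128, 256, 512, 512),
#' 256-channel ASPP branches, decoder widths (16, 32, 64, 128, 256).
#' `"desk"` is a reduced-width profile for CPU-scale experiments:
#' 128x128 inputs, encoder widths (8, 16, 32, 64, 64), 32-channel ASPP
#' branches, decoder widths (8, 16, 32, 64, 64). Both share the same
#' topology, layer count, and all other settings.
#'
#' @param profile `"reference"` or `"desk"`.
#' @param ... overrides for individual fields: `input_size`,
#'   `block_widths`, `convs_per_block`, `dilation_rates`,
#'   `include_gap_branch`, `branch_channels`, `aspp_out_channels`,
#'   `spatial_kernel`, `channel_mlp_ratio`, `level_widths`,
#'   `dropout_rate`, `attention_site` (`"skip"` or `"upsampled"`),
#'   `input_channel_replicate`, `threshold`.
#' @return an `msdasp_config` list.
#' @export
msdasp_config <- function(profile = c("reference", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    input_size = c(256L, 256L),
    block_widths = c(64L, 128L, 256L, 512L, 512L),
    convs_per_block = c(2L, 2L, 3L, 3L, 3L),
    input_channel_replicate = TRUE,
    dilation_rates = c(1L, 6L, 12L, 18L),
    include_gap_branch = TRUE,
    branch_channels = 256L,
    aspp_out_channels = 256L,
    spatial_kernel = 7L,
    channel_mlp_ratio = 8L,
    level_widths = c(16L, 32L, 64L, 128L, 256L),
    dropout_rate = 0.2,
    attention_site = "skip",
    threshold = 0.5)
  if (profile == "desk") {
    cfg$input_size <- c(128L, 128L)
    cfg$block_widths <- c(8L, 16L, 32L, 64L, 64L)
    cfg$branch_channels <- 32L
    cfg$aspp_out_channels <- 64L
    cfg$level_widths <- c(8L, 16L, 32L, 64L, 64L)
  }
  cfg <- modifyList(cfg, list(...))
  if (sum(cfg$convs_per_block) != 13L)
    stopf("encoder must have 13 convolutional layers; got %d",
          sum(cfg$convs_per_block))
  if (is.unsorted(cfg$dilation_rates, strictly = TRUE))
    stopf("dilation_rates must be strictly increasing")
  if (cfg$spatial_kernel %% 2 == 0) stopf("spatial_kernel must be odd")
  if (!cfg$attention_site %in% c("skip", "upsampled"))
    stopf("attention_site must be 'skip' or 'upsampled'")
  structure(cfg, class = "msdasp_config")
}

# ---- parameter initialisation -------------------------------------------

conv_param <- function(kh, kw, cin, cout, gain = 2) {
  sd <- sqrt(gain / (kh * kw * cin))
  list(w = array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout)),
       b = numeric(cout))
}

dha_param <- function(C, cfg) {
  k <- cfg$spatial_kernel
  hid <- max(1L, C %/% cfg$channel_mlp_ratio)
  list(spatial = conv_param(k, k, 2L, 1L, gain = 1),
       W1 = matrix(rnorm(hid * 2L * C, 0, sqrt(1 / (2 * C))), hid, 2L * C),
       W2 = matrix(rnorm(C * hid, 0, sqrt(1 / hid)), C, hid),
       b2 = numeric(C))
}

#' Create a segmentation model with freshly initialised parameters
#'
#' Convolution weights use He-normal initialisation (Xavier for the
#' sigmoid-output attention and head layers), biases start at zero, and all
#' draws come from `seed` without touching the caller's RNG state.
#' Optionally, encoder weights can be loaded from an RDS file of pretrained
#' parameters with matching shapes.
#'
#' @param cfg an [msdasp_config()].
#' @param seed integer seed for the initialisation draws.
#' @param pretrained_encoder optional path to an RDS file holding an encoder
#'   parameter list (same nested structure) to load instead of random
#'   initialisation.
#' @return an `msdasp_model`: list with `params` and `cfg`.
#' @export
create_model <- function(cfg = msdasp_config(), seed = 1L,
                         pretrained_encoder = NULL) {
  with_seed(seed, {
    bw <- cfg$block_widths
    dw <- cfg$level_widths
    enc <- list()
    cin <- if (cfg$input_channel_replicate) 3L else 1L
    for (b in 1:5) {
      blk <- list()
      for (i in seq_len(cfg$convs_per_block[b])) {
        blk[[i]] <- conv_param(3L, 3L, cin, bw[b])
        cin <- bw[b]
      }
      enc[[b]] <- blk
    }
    if (!is.null(pretrained_encoder)) {
      pe <- readRDS(pretrained_encoder)
      enc <- pe
    }
    n_dil <- length(cfg$dilation_rates)
    branches <- lapply(seq_len(n_dil), function(i) {
      k <- if (cfg$dilation_rates[i] == 1L) 1L else 3L
      conv_param(k, k, bw[5], cfg$branch_channels)
    })
    if (cfg$include_gap_branch)
      branches[[n_dil + 1L]] <- conv_param(1L, 1L, bw[5],
                                           cfg$branch_channels)
    aspp <- list(branches = branches,
                 fuse = conv_param(1L, 1L, length(branches) *
                                     cfg$branch_channels,
                                   cfg$aspp_out_channels))
    dec <- list(stem = conv_param(3L, 3L, cfg$aspp_out_channels, dw[5]),
                levels = vector("list", 4L))
    deeper <- dw[5]
    for (k in 4:1) {
      att_ch <- if (cfg$attention_site == "skip") bw[k] else dw[k]
      dec$levels[[k]] <- list(
        up = conv_param(3L, 3L, deeper, dw[k]),
        dha = dha_param(att_ch, cfg),
        conv1 = conv_param(3L, 3L, dw[k] + bw[k], dw[k]),
        conv2 = conv_param(3L, 3L, dw[k], dw[k]))
      deeper <- dw[k]
    }
    head <- conv_param(1L, 1L, dw[1], 1L, gain = 1)
    # start the output near the foreground prior: lesion masks are heavily
    # class-imbalanced, so a negative head bias avoids spending the first
    # epochs suppressing background
    head$b <- -2
    structure(list(params = list(encoder = enc, aspp = aspp, decoder = dec,
                                 head = head),
                   cfg = cfg, seed = as.integer(seed)),
              class = "msdasp_model")
  })
}

# ---- layer primitives ----------------------------------------------------

#' Convolutional layer (cross-correlation, "same" zero padding, ReLU)
#'
#' Computes `relu(W * X + b)` where `*` is dilated cross-correlation with
#' zero padding `dilation * (k - 1) / 2`, preserving the spatial size.
#'
#' @param F_prev input feature map, array `(H, W, C_in)` (a matrix is
#'   treated as one channel).
#' @param weights kernel array `(kh, kw, C_in, C_out)`.
#' @param bias numeric vector of length `C_out`.
#' @param dilation dilation (atrous) rate.
#' @param activation `"relu"` or `"linear"`.
#' @return the output feature map, array `(H, W, C_out)`.
#' @export
conv_layer <- function(F_prev, weights, bias, dilation = 1L,
                       activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  x <- as_cube(F_prev)
  d <- dim(weights)
  if (dim(x)[3] != d[3])
    stopf("channel mismatch: input has %d channels, kernel expects %d",
          dim(x)[3], d[3])
  z <- conv2d_fw_cpp(x, matrix(weights, d[1] * d[2] * d[3], d[4]),
                     bias, d[1], d[2], as.integer(dilation))
  if (activation == "relu") relu(z) else z
}

#' 2x2 max pooling with stride 2
#'
#' Per-channel maxima over non-overlapping 2x2 windows, halving the
#' spatial dimensions. Odd dimensions are padded with `-Inf`-equivalent
#' values so no real activation is lost.
#'
#' @param F input feature map, array `(H, W, C)` or matrix.
#' @return the pooled feature map, array `(ceil(H/2), ceil(W/2), C)`.
#' @export
max_pool2 <- function(F) {
  x <- as_cube(F)
  d <- dim(x)
  if (d[1] %% 2 == 1 || d[2] %% 2 == 1) {
    pad <- array(-1e300, c(d[1] + d[1] %% 2, d[2] + d[2] %% 2, d[3]))
    pad[seq_len(d[1]), seq_len(d[2]), ] <- x
    x <- pad
  }
  maxpool2_fw_cpp(x)$out
}

dropout_fw <- function(x, rate) {
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, mask = mask)
}

# ---- attention -----------------------------------------------------------

#' Spatial attention gate
#'
#' Channel-wise average and maximum descriptors per pixel are concatenated
#' into a two-channel map, convolved with a `k x k` kernel, and squashed by
#' a sigmoid into an attention map `A_s` in (0, 1); the input is reweighted
#' pixel-wise: `X_s = A_s (*) X`.
#'
#' @param X input feature map `(H, W, C)`.
#' @param weights spatial kernel, array `(k, k, 2, 1)`.
#' @param bias scalar bias.
#' @return list with `A_s` (H x W matrix in (0,1)) and `X_s` (gated map).
#' @export
spatial_attention <- function(X, weights, bias) {
  f <- spatial_attention_fw(as_cube(X), list(w = weights, b = bias))
  list(A_s = f$As, X_s = f$out)
}

spatial_attention_fw <- function(x, p) {
  d <- dim(x); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, n, C)
  favg <- rowMeans(xm)
  amax <- max.col(xm, ties.method = "first")
  fmax <- xm[cbind(seq_len(n), amax)]
  fm <- array(c(favg, fmax), c(d[1], d[2], 2L))
  kd <- dim(p$w)
  s_pre <- conv2d_fw_cpp(fm, matrix(p$w, kd[1] * kd[2] * kd[3], kd[4]),
                         p$b, kd[1], kd[2], 1L)
  As <- sigmoid(s_pre[, , 1])
  out <- array(xm * as.vector(As), d)
  list(out = out, As = As, xm = xm, fm = fm, amax = amax)
}

spatial_attention_bw <- function(dout, f, x, p) {
  d <- dim(x); n <- d[1] * d[2]; C <- d[3]
  dm <- matrix(dout, n, C)
  as_vec <- as.vector(f$As)
  dAs <- rowSums(f$xm * dm)
  dxm <- dm * as_vec
  ds <- array(dAs * as_vec * (1 - as_vec), c(d[1], d[2], 1L))
  kd <- dim(p$w)
  cb <- conv2d_bw_cpp(f$fm, matrix(p$w, kd[1] * kd[2] * kd[3], kd[4]),
                      ds, kd[1], kd[2], 1L)
  dfm <- cb$dx
  dxm <- dxm + as.vector(dfm[, , 1]) / C
  idx <- cbind(seq_len(n), f$amax)
  dxm[idx] <- dxm[idx] + as.vector(dfm[, , 2])
  list(dx = array(dxm, d),
       grads = list(w = array(cb$dw, kd), b = cb$db))
}

#' Channel attention gate
#'
#' Spatially averaged and maximal descriptors per channel (each length `C`)
#' are concatenated and passed through a two-layer dense network
#' (`W2 . relu(W1 z) + b2`, no first-layer bias) with a sigmoid output,
#' giving per-channel weights `A_c` in (0, 1); channels of the input are
#' rescaled: `X_c = A_c (*) X_s`.
#'
#' @param X_s input feature map `(H, W, C)` (typically the spatially gated
#'   map).
#' @param W1 hidden weights, `(hidden, 2C)`.
#' @param W2 output weights, `(C, hidden)`.
#' @param b2 output bias, length `C`.
#' @return list with `A_c` (length-`C` vector in (0,1)) and `X_c`.
#' @export
channel_attention <- function(X_s, W1, W2, b2) {
  f <- channel_attention_fw(as_cube(X_s), list(W1 = W1, W2 = W2, b2 = b2))
  list(A_c = f$Ac, X_c = f$out)
}

channel_attention_fw <- function(x, p) {
  d <- dim(x); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, n, C)
  favgc <- colMeans(xm)
  idx <- vapply(seq_len(C), function(j) which.max(xm[, j]), integer(1))
  fmaxc <- xm[cbind(idx, seq_len(C))]
  z <- c(favgc, fmaxc)
  hpre <- as.vector(p$W1 %*% z)
  hh <- relu(hpre)
  apre <- as.vector(p$W2 %*% hh) + p$b2
  Ac <- sigmoid(apre)
  out <- array(xm * rep(Ac, each = n), d)
  list(out = out, Ac = Ac, xm = xm, z = z, hpre = hpre, hh = hh, idx = idx)
}

channel_attention_bw <- function(dout, f, x, p) {
  d <- dim(x); n <- d[1] * d[2]; C <- d[3]
  dm <- matrix(dout, n, C)
  dAc <- colSums(f$xm * dm)
  dxm <- dm * rep(f$Ac, each = n)
  dapre <- dAc * f$Ac * (1 - f$Ac)
  dW2 <- outer(dapre, f$hh)
  dhh <- as.vector(crossprod(p$W2, dapre))
  dhpre <- dhh * (f$hpre > 0)
  dW1 <- outer(dhpre, f$z)
  dz <- as.vector(crossprod(p$W1, dhpre))
  dxm <- dxm + matrix(dz[seq_len(C)] / n, n, C, byrow = TRUE)
  sel <- cbind(f$idx, seq_len(C))
  dxm[sel] <- dxm[sel] + dz[C + seq_len(C)]
  list(dx = array(dxm, d),
       grads = list(W1 = dW1, W2 = dW2, b2 = dapre))
}

#' Dual-headed attention block
#'
#' Sequential composition of [spatial_attention()] followed by
#' [channel_attention()]; both attention maps are attached to the result for
#' inspection. With saturated gates (all sigmoids near 1) the block reduces
#' to the identity.
#'
#' @param X input feature map `(H, W, C)`.
#' @param params DHA parameter list with `spatial` (`w`, `b`), `W1`, `W2`,
#'   `b2`, as produced inside [create_model()].
#' @return the gated feature map, with attributes `A_s` and `A_c`.
#' @export
dha <- function(X, params) {
  f <- dha_fw(as_cube(X), params)
  structure(f$out, A_s = f$sp$As, A_c = f$ch$Ac)
}

dha_fw <- function(x, p) {
  sp <- spatial_attention_fw(x, p$spatial)
  ch <- channel_attention_fw(sp$out, p)
  list(out = ch$out, sp = sp, ch = ch)
}

dha_bw <- function(dout, f, x, p) {
  cb <- channel_attention_bw(dout, f$ch, f$sp$out, p)
  sb <- spatial_attention_bw(cb$dx, f$sp, x, p$spatial)
  list(dx = sb$dx,
       grads = list(spatial = sb$grads, W1 = cb$grads$W1,
                    W2 = cb$grads$W2, b2 = cb$grads$b2))
}

# ---- internal conv fw/bw with cache -------------------------------------

cv_fw <- function(x, p, dil = 1L, act = "relu") {
  d <- dim(p$w)
  z <- conv2d_fw_cpp(x, matrix(p$w, d[1] * d[2] * d[3], d[4]), p$b,
                     d[1], d[2], as.integer(dil))
  if (act == "relu") relu(z) else z
}

cv_bw <- function(dout, out, x, p, dil = 1L, act = "relu") {
  dz <- if (act == "relu") dout * (out > 0) else dout
  d <- dim(p$w)
  cb <- conv2d_bw_cpp(x, matrix(p$w, d[1] * d[2] * d[3], d[4]), dz,
                      d[1], d[2], as.integer(dil))
  list(dx = cb$dx, grads = list(w = array(cb$dw, d), b = cb$db))
}

# ---- encoder / ASPP as exposed operations -------------------------------

prep_input <- function(image, cfg) {
  x <- as_cube(image)
  if (cfg$input_channel_replicate && dim(x)[3] == 1L)
    x <- array(rep(image, 3), c(dim(x)[1], dim(x)[2], 3L))
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stopf("input height and width must be divisible by 32 (five pooling stages); got %dx%d",
          d[1], d[2])
  x
}

encoder_fw <- function(x, enc, cfg) {
  E <- vector("list", 4L)
  acts <- vector("list", 5L)   # per block: list of conv outputs
  pools <- vector("list", 5L)  # pool argmax + input dims
  cur <- x
  for (b in 1:5) {
    ins <- list(); outs <- list()
    for (i in seq_len(cfg$convs_per_block[b])) {
      ins[[i]] <- cur
      cur <- cv_fw(cur, enc[[b]][[i]])
      outs[[i]] <- cur
    }
    if (b <= 4) E[[b]] <- cur
    pf <- maxpool2_fw_cpp(cur)
    pools[[b]] <- list(arg = pf$arg, H = dim(cur)[1], W = dim(cur)[2])
    acts[[b]] <- list(ins = ins, outs = outs)
    cur <- pf$out
  }
  list(E = E, bottleneck_in = cur, acts = acts, pools = pools)
}

#' Encoder feature extraction
#'
#' Runs the five-block VGG-16-topology encoder and returns the skip
#' features `E1..E4` (last activation of blocks 1-4, before pooling, at
#' full/half/quarter/eighth resolution) and the bottleneck input (block-5
#' output after its pooling, 1/32 resolution).
#'
#' @param image 2D array (grayscale, replicated to three channels when the
#'   configuration asks for it) or `(H, W, C)` array; `H` and `W` must be
#'   divisible by 32.
#' @param model an `msdasp_model`.
#' @return list with `E1`, `E2`, `E3`, `E4`, and `bottleneck_in`.
#' @export
encode <- function(image, model) {
  x <- prep_input(image, model$cfg)
  f <- encoder_fw(x, model$params$encoder, model$cfg)
  list(E1 = f$E[[1]], E2 = f$E[[2]], E3 = f$E[[3]], E4 = f$E[[4]],
       bottleneck_in = f$bottleneck_in)
}

aspp_fw <- function(x, p, cfg, training = FALSE) {
  d <- dim(x)
  n_dil <- length(cfg$dilation_rates)
  outs <- vector("list", length(p$branches))
  gap <- NULL
  for (i in seq_len(n_dil))
    outs[[i]] <- cv_fw(x, p$branches[[i]], dil = cfg$dilation_rates[i],
                       act = "linear")
  if (cfg$include_gap_branch) {
    gm <- array(colMeans(matrix(x, d[1] * d[2], d[3])), c(1L, 1L, d[3]))
    gout <- cv_fw(gm, p$branches[[n_dil + 1L]], act = "linear")
    outs[[n_dil + 1L]] <- array(rep(as.vector(gout), each = d[1] * d[2]),
                                c(d[1], d[2], dim(gout)[3]))
    gap <- list(gm = gm, gout = gout)
  }
  cat_ <- array(unlist(outs), c(d[1], d[2],
                                length(outs) * cfg$branch_channels))
  fuse <- cv_fw(cat_, p$fuse, act = "relu")
  drop <- NULL
  out <- fuse
  if (training && cfg$dropout_rate > 0) {
    drop <- dropout_fw(fuse, cfg$dropout_rate)
    out <- drop$out
  }
  list(out = out, cat_ = cat_, fuse = fuse, gap = gap, drop = drop)
}

aspp_bw <- function(dout, f, x, p, cfg) {
  d <- dim(x)
  if (!is.null(f$drop)) dout <- dout * f$drop$mask
  fb <- cv_bw(dout, f$fuse, f$cat_, p$fuse, act = "relu")
  gb <- list(branches = vector("list", length(p$branches)))
  dx <- array(0, d)
  bc <- cfg$branch_channels
  n_dil <- length(cfg$dilation_rates)
  for (i in seq_along(p$branches)) {
    dbr <- fb$dx[, , (i - 1L) * bc + seq_len(bc), drop = FALSE]
    if (i <= n_dil) {
      cb <- cv_bw(dbr, NULL, x, p$branches[[i]],
                  dil = cfg$dilation_rates[i], act = "linear")
      dx <- dx + cb$dx
      gb$branches[[i]] <- cb$grads
    } else {
      dg <- array(colSums(matrix(dbr, d[1] * d[2], bc)), c(1L, 1L, bc))
      cb <- cv_bw(dg, NULL, f$gap$gm, p$branches[[i]], act = "linear")
      dgm <- as.vector(cb$dx)
      dx <- dx + array(rep(dgm / (d[1] * d[2]), each = d[1] * d[2]), d)
      gb$branches[[i]] <- cb$grads
    }
  }
  gb$fuse <- fb$grads
  list(dx = dx, grads = gb)
}

#' Atrous spatial pyramid pooling bottleneck
#'
#' Parallel branches on the same input: a 1x1 convolution, 3x3 convolutions
#' at the configured dilation rates, and (optionally) a global-average-
#' pooling branch whose 1x1-convolved descriptor is broadcast back to the
#' input size. Branch outputs are concatenated channel-wise in rate order
#' (GAP last) and fused by a 1x1 convolution with ReLU; the spatial size is
#' preserved.
#'
#' @param F_bottleneck input feature map `(H, W, C)`.
#' @param model an `msdasp_model` (its ASPP parameters and config are used).
#' @return the fused feature map `(H, W, aspp_out_channels)`.
#' @export
aspp <- function(F_bottleneck, model) {
  aspp_fw(as_cube(F_bottleneck), model$params$aspp, model$cfg)$out
}

# ---- full network forward / backward ------------------------------------

net_forward <- function(model, image, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  x <- prep_input(image, cfg)
  enc <- encoder_fw(x, p$encoder, cfg)
  asp <- aspp_fw(enc$bottleneck_in, p$aspp, cfg, training)
  d_asp <- dim(asp$out)
  up0 <- bilin_resize_cpp(asp$out, 2L * d_asp[1], 2L * d_asp[2])
  stem <- cv_fw(up0, p$decoder$stem)
  cur <- stem
  lv <- vector("list", 4L)
  for (k in 4:1) {
    pk <- p$decoder$levels[[k]]
    dk <- dim(cur)
    up <- bilin_resize_cpp(cur, 2L * dk[1], 2L * dk[2])
    U <- cv_fw(up, pk$up)
    E <- enc$E[[k]]
    if (cfg$attention_site == "skip") {
      att <- dha_fw(E, pk$dha)
      merged <- array(c(U, att$out),
                      c(dim(U)[1], dim(U)[2], dim(U)[3] + dim(E)[3]))
    } else {
      att <- dha_fw(U, pk$dha)
      merged <- array(c(att$out, E),
                      c(dim(U)[1], dim(U)[2], dim(U)[3] + dim(E)[3]))
    }
    h1 <- cv_fw(merged, pk$conv1)
    h2 <- cv_fw(h1, pk$conv2)
    drop <- NULL
    out <- h2
    if (training && cfg$dropout_rate > 0) {
      drop <- dropout_fw(h2, cfg$dropout_rate)
      out <- drop$out
    }
    lv[[k]] <- list(up = up, U = U, att = att, merged = merged, h1 = h1,
                    h2 = h2, drop = drop, out = out, deeper_in = cur)
    cur <- out
  }
  logits_c <- cv_fw(cur, p$head, act = "linear")
  logits <- logits_c[, , 1]
  if (!all(is.finite(logits))) stopf("non-finite activations in forward pass")
  prob <- sigmoid(logits)
  list(prob = prob, logits = logits,
       cache = list(x = x, enc = enc, asp = asp, up0 = up0, stem = stem,
                    levels = lv, d1 = cur, logits_c = logits_c))
}

net_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  p <- model$params
  layer_grads <- list()
  hb <- cv_bw(as_cube(dlogits), cache$logits_c, cache$d1, p$head,
              act = "linear")
  g_head <- hb$grads
  dcur <- hb$dx
  g_levels <- vector("list", 4L)
  dE <- vector("list", 4L)
  for (k in 1:4) {
    lc <- cache$levels[[k]]
    pk <- p$decoder$levels[[k]]
    if (!is.null(lc$drop)) dcur <- dcur * lc$drop$mask
    b2 <- cv_bw(dcur, lc$h2, lc$h1, pk$conv2)
    b1 <- cv_bw(b2$dx, lc$h1, lc$merged, pk$conv1)
    cu <- dim(lc$U)[3]
    if (cfg$attention_site == "skip") {
      dU <- b1$dx[, , seq_len(cu), drop = FALSE]
      dA <- b1$dx[, , -seq_len(cu), drop = FALSE]
      ab <- dha_bw(dA, lc$att, cache$enc$E[[k]], pk$dha)
      dE[[k]] <- ab$dx
    } else {
      ca <- dim(lc$att$out)[3]
      dA <- b1$dx[, , seq_len(ca), drop = FALSE]
      dE[[k]] <- b1$dx[, , -seq_len(ca), drop = FALSE]
      ab <- dha_bw(dA, lc$att, lc$U, pk$dha)
      dU <- ab$dx
    }
    ub <- cv_bw(dU, lc$U, lc$up, pk$up)
    din <- dim(lc$deeper_in)
    dcur <- bilin_resize_adj_cpp(ub$dx, din[1], din[2])
    g_levels[[k]] <- list(up = ub$grads, dha = ab$grads, conv1 = b1$grads,
                          conv2 = b2$grads)
    layer_grads[[paste0("decoder_level", k)]] <- dcur
  }
  sb <- cv_bw(dcur, cache$stem, cache$up0, p$decoder$stem)
  d_asp <- dim(cache$asp$out)
  d_aspp_out <- bilin_resize_adj_cpp(sb$dx, d_asp[1], d_asp[2])
  layer_grads$aspp <- d_aspp_out
  ab <- aspp_bw(d_aspp_out, cache$asp, cache$enc$bottleneck_in, p$aspp, cfg)
  # encoder backward, accumulating the skip gradients
  dcur <- ab$dx
  g_enc <- vector("list", 5L)
  for (b in 5:1) {
    pool <- cache$enc$pools[[b]]
    dcur <- maxpool2_bw_cpp(dcur, pool$arg, pool$H, pool$W)
    if (b <= 4) {
      dcur <- dcur + dE[[b]]
      layer_grads[[paste0("E", b)]] <- dcur
    }
    blk <- cache$enc$acts[[b]]
    g_blk <- vector("list", length(blk$outs))
    for (i in rev(seq_along(blk$outs))) {
      cb <- cv_bw(dcur, blk$outs[[i]], blk$ins[[i]], p$encoder[[b]][[i]])
      g_blk[[i]] <- cb$grads
      dcur <- cb$dx
    }
    g_enc[[b]] <- g_blk
  }
  list(grads = list(encoder = g_enc,
                    aspp = ab$grads,
                    decoder = list(stem = sb$grads, levels = g_levels),
                    head = g_head),
       layer_grads = layer_grads)
}

#' Segment a single slice
#'
#' Full forward pass (dropout disabled) producing the per-pixel lesion
#' probability map and its thresholded binary mask.
#'
#' @param model an `msdasp_model`.
#' @param image preprocessed 2D array whose size matches the model's
#'   divisibility requirement.
#' @param threshold probability threshold for the binary mask.
#' @return a `prediction`: list with `probabilities`, `binary_mask`, and
#'   `threshold`.
#' @export
net_predict <- function(model, image, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$cfg$threshold
  f <- net_forward(model, image, training = FALSE)
  structure(list(probabilities = f$prob,
                 binary_mask = array(as.integer(f$prob >= threshold),
                                     dim(f$prob)),
                 threshold = threshold),
            class = "prediction")
}

# ---- parameter bookkeeping ----------------------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_like <- function(skel, v) {
  i <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- v[(i + 1L):(i + n)]
    i <<- i + n
    attributes(out) <- attributes(s)
    out
  }
  rec(skel)
}

# 1 for every parameter belonging to the encoder, 0 elsewhere; used to
# freeze the encoder during training.
encoder_mask <- function(params) {
  tree <- rapply(params, function(x) x * 0, how = "replace")
  tree$encoder <- rapply(tree$encoder, function(x) x * 0 + 1,
                         how = "replace")
  flatten_params(tree)
}

#' Number of trainable parameters
#' @param model an `msdasp_model`.
#' @return integer parameter count.
#' @export
count_params <- function(model) length(flatten_params(model$params))

#' Architecture summary
#'
#' Per-tensor shapes and counts of every parameter in the model, plus the
#' total, suitable for a JSON dump.
#'
#' @param model an `msdasp_model`.
#' @param path optional path; when given, the summary is written as JSON.
#' @return a data frame with columns `tensor`, `shape`, `count`
#'   (invisibly when `path` is given).
#' @export
model_summary <- function(model, path = NULL) {
  rows <- list()
  rec <- function(x, name) {
    if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- as.character(seq_along(x))
      for (i in seq_along(x))
        rec(x[[i]], paste(name, nms[i], sep = "."))
    } else {
      shp <- if (is.null(dim(x))) length(x) else dim(x)
      rows[[length(rows) + 1L]] <<- data.frame(
        tensor = sub("^\\.", "", name),
        shape = paste(shp, collapse = "x"),
        count = length(x))
    }
  }
  rec(model$params, "")
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    jsonlite::write_json(list(profile = model$cfg$profile,
                              total_params = sum(df$count), layers = df),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(df))
  }
  df
}
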
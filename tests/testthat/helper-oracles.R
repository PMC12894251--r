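# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own kernels: plain R loops and closed forms only.

# 26-connected component count of a 3D binary array (flood fill).
cc3d_count <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  count <- 0L
  idx <- which(mask == 1)
  for (start in idx) {
    co <- arrayInd(start, d)
    if (seen[co]) next
    count <- count + 1L
    queue <- list(co)
    seen[co] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] == 1 && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  count
}

# Direct-summation dilated cross-correlation with zero padding (one in/out
# channel pair), kernel given as a k x k matrix.
conv2d_oracle <- function(img, kern, dil = 1L) {
  H <- nrow(img); W <- ncol(img); k <- nrow(kern); c <- (k + 1) / 2
  out <- matrix(0, H, W)
  for (r in 1:H) for (cc in 1:W) {
    acc <- 0
    for (i in 1:k) for (j in 1:k) {
      sr <- r + (i - c) * dil; sc <- cc + (j - c) * dil
      if (sr >= 1 && sr <= H && sc >= 1 && sc <= W)
        acc <- acc + kern[i, j] * img[sr, sc]
    }
    out[r, cc] <- acc
  }
  out
}

# Brute-force non-local means matching the documented definition:
# replicate padding, SSD patch distance, weights exp(-d2/h^2) incl. centre.
nlmeans_oracle <- function(img, patch, window, h) {
  H <- nrow(img); W <- ncol(img)
  pr <- (patch - 1) / 2; wr <- (window - 1) / 2
  at <- function(r, c) img[min(max(r, 1), H), min(max(c, 1), W)]
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    ws <- 0; vs <- 0
    for (qr in (r - wr):(r + wr)) for (qc in (c - wr):(c + wr)) {
      d2 <- 0
      for (i in -pr:pr) for (j in -pr:pr)
        d2 <- d2 + (at(r + i, c + j) - at(qr + i, qc + j))^2
      w <- exp(-d2 / h^2)
      ws <- ws + w; vs <- vs + w * at(qr, qc)
    }
    out[r, c] <- vs / ws
  }
  out
}

# Pixel-count confusion + six-metric panel, written independently.
panel_oracle <- function(pred, gt) {
  tp <- sum(pred == 1 & gt == 1); fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1); tn <- sum(pred == 0 & gt == 0)
  sr <- function(n, d, empty = 1) if (d == 0) empty else n / d
  list(dice = sr(2 * tp, 2 * tp + fp + fn),
       jaccard = sr(tp, tp + fn + fp),
       precision = sr(tp, tp + fp),
       sensitivity = sr(tp, tp + fn),
       specificity = sr(tn, tn + fp),
       fpr = sr(fp, fp + tn, empty = 0))
}

# A tiny network configuration for fast structural and gradient tests.
tiny_cfg <- function(...) {
  msdasp_config("desk", input_size = c(64L, 64L),
                block_widths = c(2L, 3L, 2L, 3L, 2L),
                branch_channels = 2L, aspp_out_channels = 3L,
                level_widths = c(2L, 2L, 3L, 2L, 3L),
                dropout_rate = 0, ...)
}

# One noise-free, skull-free phantom slice for preprocessing tests.
clean_phantom_slice <- function(seed = 5L, size = 64L, lesions = TRUE) {
  sp <- phantom_spec(shape = c(24L, size, size),
                     lesion_count = if (lesions) 2L else 0L,
                     lesion_radius_range = c(2, 4), lesion_contrast = 1.5,
                     skull_ring = FALSE,
                     bias_amplitude = 0, noise_sigma = 0, seed = seed)
  v <- generate_phantom(sp)
  sl <- slice_axial(v)
  ok <- which(vapply(sl, function(s)
    if (lesions) sum(s$mask) > 0 else sum(s$image) > 0, logical(1)))
  sl[[ok[1]]]
}
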
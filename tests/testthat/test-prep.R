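test_that("axial slicing enumerates planes in order and reconstructs", {
  sp <- phantom_spec(shape = c(32L, 32L, 32L), lesion_count = 1L,
                     lesion_radius_range = c(2, 3), seed = 4L)
  v <- generate_phantom(sp)
  slices <- slice_axial(v)
  expect_length(slices, 32L)
  expect_identical(slices[[5]]$image, v$intensity[5, , ])
  expect_identical(vapply(slices, function(s) s$slice_index, integer(1)),
                   0:31)
  recon <- aperm(simplify2array(lapply(slices, `[[`, "image")), c(3, 1, 2))
  expect_identical(recon, v$intensity)
})

test_that("slice selection applies the central band then the 5-pixel rule", {
  mk <- function(idx, npix) {
    m <- matrix(0L, 16, 16)
    if (npix > 0) m[seq_len(npix)] <- 1L
    slice_pair(matrix(0.5, 16, 16), m, "p1", idx, depth = 20L)
  }
  # depth 20, band 0.70 -> in-band indices [3, 17); lesions {3,5,9} px on
  # slices {7,10,13}, a 50-px lesion out of band on slice 1
  slices <- lapply(0:19, function(i) {
    npix <- if (i == 1) 50 else if (i == 7) 3 else if (i == 10) 5
            else if (i == 13) 9 else 0
    mk(i, npix)
  })
  kept <- select_slices(slices, slice_filter_config())
  expect_identical(vapply(kept, function(s) s$slice_index, integer(1)),
                   c(10L, 13L))
  # boundary of the pixel rule: 4 px excluded, 5 px included
  four <- select_slices(list(mk(10L, 4)), slice_filter_config())
  five <- select_slices(list(mk(10L, 5)), slice_filter_config())
  expect_length(four, 0L)
  expect_length(five, 1L)
  # idempotence and empty-mask volumes
  expect_identical(select_slices(kept, slice_filter_config()), kept)
  expect_length(select_slices(lapply(0:19, mk, npix = 0),
                              slice_filter_config()), 0L)
})

test_that("volume loading binarizes masks and rejects shape mismatches", {
  dir <- withr::local_tempdir()
  arr <- array(runif(16 * 32 * 32, 0, 100), c(16, 32, 32))
  m255 <- array(0, c(16, 32, 32)); m255[8, 10:12, 10:12] <- 255
  RNifti::writeNifti(RNifti::asNifti(arr), file.path(dir, "img.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(m255), file.path(dir, "m255.nii.gz"))
  vp <- load_volume_pair(file.path(dir, "img.nii.gz"),
                         file.path(dir, "m255.nii.gz"), "p1")
  expect_true(all(vp$mask %in% c(0L, 1L)))
  expect_equal(sum(vp$mask), 9)
  small <- array(0, c(8, 8, 8))
  RNifti::writeNifti(RNifti::asNifti(small), file.path(dir, "small.nii.gz"))
  expect_error(load_volume_pair(file.path(dir, "img.nii.gz"),
                                file.path(dir, "small.nii.gz"), "p1"),
               "mismatch")
  expect_error(load_volume_pair(file.path(dir, "nope.nii.gz"),
                                file.path(dir, "m255.nii.gz"), "p1"),
               "not found")
})

test_that("skull stripping removes a bright ring but never touches the mask", {
  # ring/disk phantom slice: bright skull ring, gap, dimmer brain disk
  n <- 64L
  rr <- sqrt(outer((1:n - 32.5)^2, (1:n - 32.5)^2, `+`))
  img <- matrix(0, n, n)
  img[rr <= 20] <- 100
  img[rr > 24 & rr <= 27] <- 180
  lesion <- matrix(0L, n, n); lesion[30:33, 30:33] <- 1L
  s <- slice_pair(img, lesion, "p1", 0L)
  out <- skull_strip(s)
  expect_identical(out$mask, lesion)
  # the surviving component is the brain disk: ring pixels excluded
  expect_equal(sum(out$brain_mask[rr > 24 & rr <= 27]), 0)
  expect_gt(sum(out$brain_mask[rr <= 19]), 0.99 * sum(rr <= 19))
  # brain-only slices keep nearly all supra-threshold pixels
  s2 <- clean_phantom_slice()
  out2 <- skull_strip(s2)
  above <- s2$image > 0
  expect_gt(sum(out2$brain_mask & above) / sum(above), 0.99)
  expect_error(skull_strip(slice_pair(matrix(1, 8, 8), matrix(0L, 8, 8),
                                      "p", 0L)), "degenerate")
})

test_that("non-local means matches its brute-force oracle", {
  set.seed(21)
  img <- matrix(runif(81), 9, 9)
  expect_equal(denoise_nlmeans(img, 3L, 5L, 0.4),
               nlmeans_oracle(img, 3L, 5L, 0.4), tolerance = 1e-12)
  cst <- matrix(2.5, 7, 7)
  expect_equal(denoise_nlmeans(cst, 3L, 5L, 1), cst)
  # smoothing reduces variance over the brain on a noisy phantom slice
  s <- clean_phantom_slice(seed = 8L)
  noisy <- s$image + matrix(rnorm(length(s$image), 0, 5), nrow(s$image))
  den <- denoise_nlmeans(noisy, 3L, 9L, 8)
  brain <- s$image > 0
  expect_lt(var(den[brain]), var(noisy[brain]))
  expect_error(denoise_nlmeans(matrix(c(NA, 1:8), 3, 3)), "non-finite")
})

test_that("polynomial bias correction flattens a known quadratic field", {
  s <- clean_phantom_slice(seed = 13L, size = 64L)
  expect_equal(bias_correct(s$image, "none"), s$image)
  # nothing to correct on a homogeneous slice: identity to 1e-6 relative
  s0 <- clean_phantom_slice(seed = 13L, size = 64L, lesions = FALSE)
  flat <- bias_correct(s0$image, "polynomial")
  brain0 <- s0$image > 0
  expect_lt(max(abs(flat[brain0] - s0$image[brain0]) / s0$image[brain0]),
            1e-6)
  brain <- s$image > 0
  # impose a quadratic multiplicative field; CV over lesion-free brain drops
  h <- nrow(s$image)
  u <- (row(s$image) - (h + 1) / 2) / h; v <- (col(s$image) - (h + 1) / 2) / h
  biased <- s$image * (1 + 0.3 * (u^2 - v^2 + u * v))
  corr <- bias_correct(biased, "polynomial")
  tissue <- brain & s$mask == 0
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(corr[tissue]), cv(biased[tissue]))
  expect_error(bias_correct(matrix(0, 8, 8), "polynomial"), "brain")
  # delegated hook is called as-is
  expect_equal(bias_correct(s$image, "delegated_n4",
                            n4_fn = function(x) x * 2), s$image * 2)
})

test_that("resizing is bilinear for images, nearest for masks", {
  img <- matrix(runif(128 * 128), 128, 128)
  m <- matrix(0L, 128, 128); m[60:63, 60:63] <- 1L
  s <- slice_pair(img, m, "p1", 0L)
  expect_identical(resize_pair(s, c(128L, 128L)), s)
  up <- resize_pair(s, c(256L, 256L))
  expect_identical(dim(up$image), c(256L, 256L))
  expect_true(all(up$mask %in% c(0L, 1L)))
  expect_equal(sum(up$mask), 64)  # 4x4 square doubles to 8x8
})

test_that("the full prep pipeline is deterministic", {
  sp <- phantom_spec(shape = c(16L, 64L, 64L), lesion_count = 2L,
                     lesion_radius_range = c(3, 5), seed = 6L)
  v <- generate_phantom(sp)
  pre <- preprocess_config(target_size = c(64L, 64L))
  a <- preprocess_volume(v, pre)
  b <- preprocess_volume(v, pre)
  expect_identical(a$slices, b$slices)
  expect_identical(a$manifest, b$manifest)
  expect_true(all(vapply(a$slices, function(s)
    all(s$mask %in% c(0L, 1L)), logical(1))))
})
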
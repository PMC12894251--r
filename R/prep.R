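#' Load an image/mask NIfTI pair as a canonical volume pair
#'
#' Reads the intensity and mask volumes, checks that their shapes agree,
#' binarizes the mask at `> 0`, and reorients the arrays so axis 1 is the
#' inferior-to-superior (axial stacking) axis. Orientation is derived from
#' the NIfTI affine; volumes with no usable affine are assumed already
#' canonical.
#'
#' @param image_path,mask_path NIfTI (.nii/.nii.gz) file paths.
#' @param patient_id identifier carried onto every slice for
#'   leakage-safe splitting.
#' @return a `volume_pair`: list with `intensity`, `mask`, `patient_id`.
#' @export
load_volume_pair <- function(image_path, mask_path, patient_id) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(msk)))
    stopf("image/mask shape mismatch: (%s) vs (%s)",
          paste(dim(img), collapse = "x"), paste(dim(msk), collapse = "x"))
  img_a <- canonical_axial(img)
  msk_a <- canonical_axial(msk)
  structure(list(intensity = img_a,
                 mask = array(as.integer(msk_a > 0), dim(msk_a)),
                 patient_id = patient_id),
            class = "volume_pair")
}

# Permute/flip a NIfTI array so dimension 1 points inferior -> superior.
canonical_axial <- function(nii) {
  a <- as.array(nii)
  orient <- tryCatch(RNifti::orientation(nii), error = function(e) NULL)
  if (is.null(orient) || is.na(orient) || nchar(orient) != 3L) return(a)
  codes <- strsplit(orient, "")[[1]]
  ax <- which(codes %in% c("S", "I"))
  if (length(ax) != 1L) return(a)
  if (codes[ax] == "I") {
    idx <- rev(seq_len(dim(a)[ax]))
    a <- switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
  }
  if (ax != 1L) a <- aperm(a, c(ax, setdiff(1:3, ax)))
  a
}

#' Decompose a volume pair into axial slice pairs
#'
#' @param vol a `volume_pair` (or `phantom_volume`).
#' @return list of `slice_pair` objects, one per plane along axis 1, in
#'   order; each carries `image`, `mask`, `patient_id`, 0-based
#'   `slice_index`, and the source volume `depth`.
#' @export
slice_axial <- function(vol) {
  d <- dim(vol$intensity)[1]
  lapply(seq_len(d) - 1L, function(k) {
    slice_pair(vol$intensity[k + 1L, , ], vol$mask[k + 1L, , ],
               vol$patient_id, k, depth = d)
  })
}

#' Construct a slice pair
#' @param image 2D numeric array.
#' @param mask 2D binary array (same shape).
#' @param patient_id patient identifier.
#' @param slice_index 0-based index along the axial axis.
#' @param depth number of axial slices in the source volume (used by the
#'   central-band slice filter); defaults to `slice_index + 1`.
#' @param augmentation provenance tag, `"orig"` for unaugmented slices.
#' @return a `slice_pair` object.
#' @export
slice_pair <- function(image, mask, patient_id, slice_index,
                       depth = slice_index + 1L, augmentation = "orig") {
  if (!identical(dim(image), dim(mask)))
    stopf("image/mask shape mismatch in slice")
  if (!is_binary(mask)) stopf("slice mask must be binary")
  structure(list(image = image, mask = array(as.integer(mask), dim(mask)),
                 patient_id = patient_id,
                 slice_index = as.integer(slice_index),
                 depth = as.integer(depth), augmentation = augmentation),
            class = "slice_pair")
}

#' Slice-retention configuration
#'
#' Slices are retained when (i) their index falls in a central band covering
#' `central_band_fraction` of the axial extent (the peripheral initial and
#' terminal slices rarely show lesions) and (ii) the lesion mask has at least
#' `min_lesion_pixels` foreground pixels (default five).
#'
#' @param min_lesion_pixels minimum mask foreground pixels (default 5).
#' @param central_band_fraction fraction of axial slices kept, in (0, 1]
#'   (default 0.70).
#' @param per_component count the largest connected lesion component instead
#'   of total foreground pixels.
#' @return a `slice_filter_config`.
#' @export
slice_filter_config <- function(min_lesion_pixels = 5L,
                                central_band_fraction = 0.70,
                                per_component = FALSE) {
  if (min_lesion_pixels < 0) stopf("min_lesion_pixels must be >= 0")
  if (central_band_fraction <= 0 || central_band_fraction > 1)
    stopf("central_band_fraction must be in (0, 1]")
  structure(list(min_lesion_pixels = as.integer(min_lesion_pixels),
                 central_band_fraction = central_band_fraction,
                 per_component = isTRUE(per_component)),
            class = "slice_filter_config")
}

#' Select lesion-bearing central slices
#'
#' Applies the central band first, then the minimum-lesion-size rule, in
#' input order. For source depth `D` and band fraction `f`, indices in
#' `[floor(D*(1-f)/2), D - ceiling(D*(1-f)/2))` are in band (0-based).
#' The operation is idempotent.
#'
#' @param slices list of `slice_pair`s from one volume.
#' @param cfg a [slice_filter_config()].
#' @return the retained subset, order preserved (possibly empty).
#' @export
select_slices <- function(slices, cfg = slice_filter_config()) {
  if (length(slices) == 0L) return(slices)
  d <- max(vapply(slices, function(s) s$depth, integer(1)))
  margin <- d * (1 - cfg$central_band_fraction) / 2
  lo <- floor(margin)
  hi <- d - ceiling(margin)  # exclusive
  keep <- vapply(slices, function(s) {
    if (s$slice_index < lo || s$slice_index >= hi) return(FALSE)
    n <- if (cfg$per_component) largest_component_size(s$mask)
         else sum(s$mask)
    n >= cfg$min_lesion_pixels
  }, logical(1))
  slices[keep]
}

largest_component_size <- function(mask) {
  if (sum(mask) == 0) return(0)
  lab <- EBImage::bwlabel(mask)
  max(tabulate(lab[lab > 0]))
}

#' Preprocessing configuration
#'
#' @param target_size output `(H, W)` in pixels (default 256 x 256).
#' @param denoise `"none"` or `"nlmeans"`.
#' @param nlmeans_patch,nlmeans_window,nlmeans_h non-local-means patch size
#'   (odd), search window (odd, >= patch), and filter strength `h`; `h = NULL`
#'   uses 0.8 x an estimated noise sigma per slice.
#' @param bias_correction `"none"`, `"polynomial"`, or `"delegated_n4"`.
#' @param bias_degree polynomial surface degree (default 2).
#' @param n4_fn function `(image) -> image` used when
#'   `bias_correction = "delegated_n4"`; hook for an external N4
#'   implementation.
#' @param skull_strip logical; run the Otsu/morphology brain extraction.
#' @param strip_radius morphological disk radius in pixels.
#' @param normalize `"minmax"` (per-slice min-max to `[0,1]`) or `"none"`.
#' @return a `preprocess_config`.
#' @export
preprocess_config <- function(target_size = c(256L, 256L),
                              denoise = c("nlmeans", "none"),
                              nlmeans_patch = 3L, nlmeans_window = 11L,
                              nlmeans_h = NULL,
                              bias_correction = c("polynomial", "none",
                                                  "delegated_n4"),
                              bias_degree = 2L, n4_fn = NULL,
                              skull_strip = TRUE, strip_radius = 3L,
                              normalize = c("minmax", "none")) {
  if (any(target_size <= 0)) stopf("target_size must be positive")
  if (nlmeans_patch %% 2 == 0) stopf("nlmeans_patch must be odd")
  if (nlmeans_window < nlmeans_patch)
    stopf("nlmeans_window must be >= nlmeans_patch")
  structure(list(target_size = as.integer(target_size),
                 denoise = match.arg(denoise),
                 nlmeans_patch = as.integer(nlmeans_patch),
                 nlmeans_window = as.integer(nlmeans_window),
                 nlmeans_h = nlmeans_h,
                 bias_correction = match.arg(bias_correction),
                 bias_degree = as.integer(bias_degree), n4_fn = n4_fn,
                 skull_strip = isTRUE(skull_strip),
                 strip_radius = as.integer(strip_radius),
                 normalize = match.arg(normalize)),
            class = "preprocess_config")
}

#' Skull stripping by thresholding and morphology
#'
#' Brain extraction on a single axial slice, in this exact order: linear
#' contrast stretch to `[0, 1]`, histogram equalization, Otsu thresholding,
#' morphological opening then closing with a disk, retention of the largest
#' connected component, and hole filling. The lesion mask is never modified.
#'
#' @param slice a `slice_pair`.
#' @param disk_radius radius of the morphological structuring disk (pixels).
#' @return the slice with `image` replaced by `image * brain_mask`, plus a
#'   `brain_mask` element (2D 0/1 array).
#' @export
skull_strip <- function(slice, disk_radius = 3L) {
  img <- slice$image
  if (diff(range(img)) == 0) stopf("degenerate intensity histogram")
  x <- minmax01(img)
  x <- EBImage::equalize(EBImage::Image(x), range = c(0, 1), levels = 256)
  thr <- EBImage::otsu(x, range = c(0, 1), levels = 256)
  bw <- EBImage::Image(as.numeric(x > thr), dim(img))
  brush <- EBImage::makeBrush(2L * disk_radius + 1L, shape = "disc")
  bw <- EBImage::closing(EBImage::opening(bw, brush), brush)
  lab <- EBImage::bwlabel(bw)
  lab_m <- as.matrix(EBImage::imageData(lab))
  if (max(lab_m) > 0) {
    biggest <- which.max(tabulate(lab_m[lab_m > 0]))
    bw <- EBImage::Image(as.numeric(lab_m == biggest), dim(img))
  }
  bw <- EBImage::fillHull(bw)
  brain <- array(as.integer(as.matrix(EBImage::imageData(bw)) > 0), dim(img))
  out <- slice
  out$image <- img * brain
  out$brain_mask <- brain
  out
}

#' Non-local-means denoising of a 2D image
#'
#' Each pixel becomes a weighted average of the pixels in its search window;
#' the weight of candidate `q` is `exp(-||P_p - P_q||^2 / h^2)` where
#' `||.||^2` is the sum of squared differences between the two patches
#' (replicate padding at the frame border), normalized per pixel.
#'
#' @param image 2D numeric array with finite values.
#' @param patch_size odd patch side length.
#' @param search_window odd search-window side length, >= `patch_size`.
#' @param filter_strength the weight bandwidth `h` (> 0).
#' @return the denoised 2D array.
#' @export
denoise_nlmeans <- function(image, patch_size = 3L, search_window = 11L,
                            filter_strength = 5) {
  if (!all(is.finite(image))) stopf("image contains non-finite pixels")
  if (patch_size %% 2 == 0) stopf("patch_size must be odd")
  if (search_window < patch_size) stopf("search_window must be >= patch_size")
  nlmeans_cpp(image, as.integer(patch_size), as.integer(search_window),
              filter_strength)
}

# Robust noise sigma estimate from the median absolute horizontal difference.
estimate_noise_sigma <- function(image) {
  d <- diff(t(image))
  stats::median(abs(d)) / (0.6745 * sqrt(2)) + 1e-8
}

#' Bias-field correction of a 2D slice
#'
#' `method = "polynomial"` fits a degree-`degree` polynomial surface to the
#' log-intensity over the brain region (pixels > 0) by least squares and
#' divides the image by the exponentiated fit, renormalized to unit mean
#' over the brain. `method = "delegated_n4"` calls the user-supplied hook
#' `n4_fn`; `"none"` is the identity.
#'
#' @param image nonnegative 2D numeric array.
#' @param method one of `"polynomial"`, `"delegated_n4"`, `"none"`.
#' @param degree polynomial surface degree.
#' @param n4_fn function `(image) -> image` for the delegated mode.
#' @return the corrected 2D array.
#' @export
bias_correct <- function(image, method = c("polynomial", "delegated_n4",
                                           "none"),
                         degree = 2L, n4_fn = NULL) {
  method <- match.arg(method)
  if (method == "none") return(image)
  if (any(image < 0)) stopf("image must be nonnegative")
  if (method == "delegated_n4") {
    if (is.null(n4_fn)) stopf("delegated_n4 requires an n4_fn hook")
    return(n4_fn(image))
  }
  brain <- image > 0
  if (!any(brain)) stopf("all-zero brain region; nothing to correct")
  h <- nrow(image); w <- ncol(image)
  rr <- (row(image)[brain] - (h + 1) / 2) / h
  cc <- (col(image)[brain] - (w + 1) / 2) / w
  X <- poly_design(rr, cc, degree)
  lv <- log(image[brain])
  beta <- qr.solve(crossprod(X), crossprod(X, lv))
  rr_all <- (row(image) - (h + 1) / 2) / h
  cc_all <- (col(image) - (w + 1) / 2) / w
  fit <- array(poly_design(as.vector(rr_all), as.vector(cc_all),
                           degree) %*% beta, dim(image))
  field <- exp(fit)
  field <- field / mean(field[brain])
  out <- image
  out[brain] <- image[brain] / field[brain]
  out
}

poly_design <- function(r, c, degree) {
  cols <- list(rep(1, length(r)))
  for (d in seq_len(degree))
    for (i in 0:d) cols[[length(cols) + 1L]] <- r^(d - i) * c^i
  do.call(cbind, cols)
}

#' Resize a slice pair
#'
#' Image resized bilinearly, mask by nearest neighbour and re-binarized.
#'
#' @param slice a `slice_pair`.
#' @param target `(H, W)` output size in pixels.
#' @return the resized `slice_pair`.
#' @export
resize_pair <- function(slice, target = c(256L, 256L)) {
  if (any(target <= 0)) stopf("target size must be positive")
  if (all(dim(slice$image) == target)) return(slice)
  out <- slice
  out$image <- as.matrix(EBImage::imageData(
    EBImage::resize(EBImage::Image(slice$image), w = target[1], h = target[2],
                    filter = "bilinear")))
  m <- as.matrix(EBImage::imageData(
    EBImage::resize(EBImage::Image(slice$mask), w = target[1], h = target[2],
                    filter = "none")))
  out$mask <- array(as.integer(m > 0.5), dim(m))
  out
}

#' Full slice preprocessing pipeline for one volume
#'
#' Axial slicing, slice selection, then per retained slice: skull stripping,
#' denoising, bias correction, intensity normalization, and resizing, in
#' that order. Deterministic for fixed inputs and configuration.
#'
#' @param vol a `volume_pair` or `phantom_volume`.
#' @param pre a [preprocess_config()].
#' @param filt a [slice_filter_config()].
#' @return list with `slices` (processed `slice_pair`s) and `manifest`
#'   (data frame: patient_id, slice_index, retained, lesion_pixels).
#' @export
preprocess_volume <- function(vol, pre = preprocess_config(),
                              filt = slice_filter_config()) {
  all_slices <- slice_axial(vol)
  kept <- select_slices(all_slices, filt)
  kept_idx <- vapply(kept, function(s) s$slice_index, integer(1))
  manifest <- data.frame(
    patient_id = vol$patient_id,
    slice_index = vapply(all_slices, function(s) s$slice_index, integer(1)),
    retained = vapply(all_slices, function(s) s$slice_index %in% kept_idx,
                      logical(1)),
    lesion_pixels = vapply(all_slices, function(s) sum(s$mask), numeric(1)))
  slices <- lapply(kept, function(s) {
    if (pre$skull_strip) s <- skull_strip(s, pre$strip_radius)
    if (pre$denoise == "nlmeans") {
      h <- pre$nlmeans_h
      if (is.null(h)) h <- 0.8 * estimate_noise_sigma(s$image)
      s$image <- denoise_nlmeans(s$image, pre$nlmeans_patch,
                                 pre$nlmeans_window, h)
    }
    if (pre$bias_correction != "none") {
      s$image[s$image < 0] <- 0
      s$image <- bias_correct(s$image, pre$bias_correction, pre$bias_degree,
                              pre$n4_fn)
    }
    if (pre$normalize == "minmax") s$image <- minmax01(s$image)
    resize_pair(s, pre$target_size)
  })
  list(slices = slices, manifest = manifest)
}

#' Write processed slices as PNGs with a manifest CSV
#'
#' Images are written 8-bit grayscale (min-max scaled), masks as 0/255.
#'
#' @param slices list of `slice_pair`s.
#' @param dir existing output directory.
#' @param manifest optional manifest data frame to write alongside.
#' @return invisibly, the manifest CSV path.
#' @export
write_slices_png <- function(slices, dir, manifest = NULL) {
  if (!dir.exists(dir)) stopf("output directory does not exist: %s", dir)
  rows <- lapply(slices, function(s) {
    stem <- sprintf("%s_s%03d_%s", s$patient_id, s$slice_index,
                    s$augmentation)
    png::writePNG(minmax01(s$image), file.path(dir, paste0(stem, ".png")))
    png::writePNG(s$mask + 0, file.path(dir, paste0(stem, "_mask.png")))
    data.frame(patient_id = s$patient_id, slice_index = s$slice_index,
               augmentation = s$augmentation, image = paste0(stem, ".png"),
               mask = paste0(stem, "_mask.png"),
               lesion_pixels = sum(s$mask))
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "slices_manifest.csv")
  write.csv(man, path, row.names = FALSE)
  if (!is.null(manifest))
    write.csv(manifest, file.path(dir, "selection_manifest.csv"),
              row.names = FALSE)
  invisible(path)
}
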
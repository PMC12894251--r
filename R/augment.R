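#' Augmentation specification
#'
#' Geometric co-transforms applied identically to image and mask: rotations
#' (bilinear image / nearest mask), centre zooms with implicit centre crop,
#' and a horizontal translation. With the defaults each input slice yields
#' seven samples: the original, three rotations, two scalings, and one
#' translation.
#'
#' @param rotation_angles rotation angles in degrees (default 45, 90, 125).
#' @param scale_factors zoom factors (default 1.5 and 2).
#' @param translate_dx horizontal shift in pixels; `NULL` means 10% of the
#'   image width.
#' @param fill_value background fill for vacated pixels.
#' @return an `augment_spec`.
#' @export
augment_spec <- function(rotation_angles = c(45, 90, 125),
                         scale_factors = c(1.5, 2),
                         translate_dx = NULL, fill_value = 0) {
  if (any(abs(rotation_angles) >= 360)) stopf("angles must be in (-360, 360)")
  if (any(scale_factors <= 0)) stopf("scale factors must be > 0")
  structure(list(rotation_angles = rotation_angles,
                 scale_factors = scale_factors,
                 translate_dx = translate_dx, fill_value = fill_value),
            class = "augment_spec")
}

# Apply the inverse-map affine src = A (dst - ctr) + ctr + shift_src to both
# channels; image bilinear, mask nearest then re-binarized.
co_affine <- function(s, A, shift_src = c(0, 0), fill = 0, tag = "aug") {
  ctr <- (dim(s$image) - 1) / 2
  b <- ctr + shift_src - A %*% ctr
  out <- s
  out$image <- affine_sample_cpp(s$image, A[1, 1], A[1, 2], A[2, 1], A[2, 2],
                                 b[1], b[2], TRUE, fill)
  m <- affine_sample_cpp(s$mask, A[1, 1], A[1, 2], A[2, 1], A[2, 2],
                         b[1], b[2], FALSE, 0)
  out$mask <- array(as.integer(m > 0.5), dim(m))
  out$augmentation <- tag
  out
}

#' Rotate a slice pair about the image centre
#'
#' Positive angles rotate the content counter-clockwise (with the column
#' axis as x and the negated row axis as y). Image sampled bilinearly, mask
#' by nearest neighbour; out-of-frame regions take `fill_value`. Output
#' shape is unchanged. Four successive 90-degree rotations restore a mask
#' exactly.
#'
#' @param s a `slice_pair`.
#' @param angle degrees.
#' @param fill_value background fill.
#' @return the rotated `slice_pair`.
#' @export
rotate_pair <- function(s, angle, fill_value = 0) {
  th <- angle * pi / 180
  # inverse map: with the row axis pointing down, counter-clockwise content
  # rotation needs destination offsets rotated by +angle in (row, col) form
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2, byrow = TRUE)
  co_affine(s, A, fill = fill_value, tag = sprintf("rot%g", angle))
}

#' Zoom a slice pair about the centre
#'
#' Scaling by `factor` about the image centre keeps the output shape, so
#' factors > 1 implicitly centre-crop. Mask nearest-neighbour, re-binarized.
#'
#' @param s a `slice_pair`.
#' @param factor zoom factor (> 0).
#' @param fill_value background fill (visible when `factor < 1`).
#' @return the scaled `slice_pair`.
#' @export
scale_pair <- function(s, factor, fill_value = 0) {
  if (factor <= 0) stopf("scale factor must be > 0")
  A <- diag(2) / factor
  co_affine(s, A, fill = fill_value, tag = sprintf("scale%g", factor))
}

#' Translate a slice pair horizontally
#'
#' Shifts both channels by `dx` columns (positive = rightwards, towards
#' higher column indices); vacated columns take `fill_value`.
#'
#' @param s a `slice_pair`.
#' @param dx shift in pixels, `|dx| <` width.
#' @param fill_value background fill.
#' @return the translated `slice_pair`.
#' @export
translate_pair <- function(s, dx, fill_value = 0) {
  if (abs(dx) >= ncol(s$image)) stopf("|dx| must be smaller than the width")
  co_affine(s, diag(2), shift_src = c(0, -dx), fill = fill_value,
            tag = sprintf("tx%g", dx))
}

#' Expand a slice set with the configured co-transforms
#'
#' Output is the originals followed by one augmented copy per listed
#' parameter (default 3 rotations + 2 scalings + 1 translation = 7x the
#' input count). Each sample carries a provenance tag in `$augmentation`.
#'
#' @param slices list of `slice_pair`s.
#' @param spec an [augment_spec()].
#' @return the expanded list of `slice_pair`s.
#' @export
augment_dataset <- function(slices, spec = augment_spec()) {
  if (length(slices) == 0L) return(slices)
  out <- list()
  for (s in slices) {
    dx <- spec$translate_dx
    if (is.null(dx)) dx <- round(0.1 * ncol(s$image))
    aug <- c(list(s),
             lapply(spec$rotation_angles, function(a)
               rotate_pair(s, a, spec$fill_value)),
             lapply(spec$scale_factors, function(f)
               scale_pair(s, f, spec$fill_value)),
             list(translate_pair(s, dx, spec$fill_value)))
    out <- c(out, aug)
  }
  out
}
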
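#' Grad-CAM attention map for a segmentation prediction
#'
#' Dense segmentation has no single class logit, so the scalar objective is
#' the mean pre-sigmoid output over the predicted-foreground pixels (over
#' all pixels when the prediction is empty). The objective's gradient at
#' the target layer is averaged spatially per channel to give channel
#' weights; the heatmap is the ReLU of the weighted sum of the target
#' activations, bilinearly upsampled to the input size and min-max
#' normalised (an identically zero map stays zero).
#'
#' @param checkpoint a `checkpoint` or `msdasp_model`.
#' @param slice a `slice_pair` (its image is used).
#' @param target_layer `"aspp"` (default, the ASPP fusion output), one of
#'   `"E1".."E4"` (encoder skip features), or `"decoder_level1".."4"`.
#' @param threshold foreground threshold for the objective.
#' @return a `cam_result`: list with `heatmap` (input-size matrix in
#'   [0, 1]), `target_layer`, `raw` (target-resolution map), and the
#'   `prediction`.
#' @export
gradcam <- function(checkpoint, slice, target_layer = "aspp",
                    threshold = 0.5) {
  model <- if (inherits(checkpoint, "checkpoint")) checkpoint$model
           else checkpoint
  f <- net_forward(model, slice$image, training = FALSE)
  acts <- list(aspp = f$cache$asp$out,
               E1 = f$cache$enc$E[[1]], E2 = f$cache$enc$E[[2]],
               E3 = f$cache$enc$E[[3]], E4 = f$cache$enc$E[[4]])
  fg <- f$prob >= threshold
  if (!any(fg)) fg <- array(TRUE, dim(f$prob))
  dlogits <- fg / sum(fg)
  bw <- net_backward(model, f$cache, dlogits)
  act <- acts[[target_layer]]
  grad <- bw$layer_grads[[target_layer]]
  if (is.null(grad) || is.null(dim(grad)) || length(dim(grad)) < 3L)
    stopf("target layer '%s' has no spatial feature map", target_layer)
  if (is.null(act)) act <- f$cache$levels[[
    as.integer(sub("decoder_level", "", target_layer))]]$deeper_in
  C <- dim(grad)[3]
  wts <- colMeans(matrix(grad, prod(dim(grad)[1:2]), C))
  raw <- relu(array(matrix(act, prod(dim(act)[1:2]), C) %*% wts,
                    dim(act)[1:2]))
  up <- bilin_resize_cpp(as_cube(raw), dim(slice$image)[1],
                         dim(slice$image)[2])[, , 1]
  heat <- if (max(up) > 0) up / max(up) else up
  structure(list(heatmap = heat, target_layer = target_layer, raw = raw,
                 prediction = f$prob),
            class = "cam_result")
}

#' Overlay a Grad-CAM heatmap on the slice
#'
#' The heatmap is colormapped (blue-cyan-yellow-red) and alpha-blended
#' pixelwise onto the min-max-scaled grayscale image:
#' `(1 - alpha) * gray + alpha * colormap`.
#'
#' @param cam a `cam_result` (or a plain heatmap matrix in [0, 1]).
#' @param image 2D array with the same spatial size as the heatmap.
#' @param alpha blend weight in [0, 1]; 0 returns the replicated grayscale
#'   image, 1 the pure colormap.
#' @param path optional PNG output path.
#' @return an `(H, W, 3)` RGB array in [0, 1].
#' @export
cam_overlay <- function(cam, image, alpha = 0.5, path = NULL) {
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  heat <- if (inherits(cam, "cam_result")) cam$heatmap else cam
  if (!identical(dim(heat), dim(image)))
    stopf("heatmap/image size mismatch")
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cm <- ramp(as.vector(heat)) / 255
  gray <- as.vector(minmax01(image))
  rgb <- (1 - alpha) * cbind(gray, gray, gray) + alpha * cm
  out <- array(rgb, c(dim(image), 3L))
  if (!is.null(path)) png::writePNG(out, path)
  out
}
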
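#' Specification of a synthetic FLAIR-like brain phantom
#'
#' Describes a 3D head phantom emulating the gross intensity structure of a
#' FLAIR brain MRI: dark background, bright brain parenchyma modelled as an
#' ellipsoid, an optional even brighter skull ring separated from the brain by
#' a dark gap, hyperintense spherical lesions, a smooth multiplicative bias
#' field, and additive Gaussian noise. Reference tissue levels are fixed
#' (background 0, brain 100, skull 180, lesion `100 * lesion_contrast` before
#' bias/noise) so downstream oracle checks are exact.
#'
#' @param shape integer vector `(depth, height, width)` in voxels; the first
#'   axis is the axial (inferior-to-superior) stacking axis. Each >= 16.
#' @param brain_axes ellipsoid semi-axes in voxels, `(a_z, a_y, a_x)`.
#' @param skull_ring logical; add a bright elliptical shell around the brain.
#' @param skull_thickness ring thickness in voxels.
#' @param lesion_count number of non-overlapping spherical lesions.
#' @param lesion_radius_range `(min, max)` lesion radius in voxels, min >= 1.
#' @param lesion_contrast multiplicative lesion intensity factor (> 1)
#'   relative to brain tissue.
#' @param bias_amplitude relative amplitude of the smooth (degree-2
#'   polynomial) multiplicative bias field; 0 disables it.
#' @param noise_sigma standard deviation of additive Gaussian noise in
#'   intensity units; 0 disables it.
#' @param voxel_spacing voxel size in mm, default isotropic 1 mm.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(24L, 96L, 96L),
                         brain_axes = NULL,
                         skull_ring = TRUE,
                         skull_thickness = 2,
                         lesion_count = 4L,
                         lesion_radius_range = c(2, 4),
                         lesion_contrast = 1.5,
                         bias_amplitude = 0.2,
                         noise_sigma = 2,
                         voxel_spacing = c(1, 1, 1),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stopf("shape must be three dimensions, each >= 16")
  if (is.null(brain_axes)) brain_axes <- shape / 2 * c(0.85, 0.72, 0.72)
  if (lesion_count < 0) stopf("lesion_count must be nonnegative")
  if (lesion_radius_range[1] < 1) stopf("lesion_radius_range min must be >= 1")
  if (diff(lesion_radius_range) < 0) stopf("lesion_radius_range must be (min, max)")
  if (lesion_contrast <= 1) stopf("lesion_contrast must be > 1")
  structure(list(shape = shape, brain_axes = brain_axes,
                 skull_ring = isTRUE(skull_ring),
                 skull_thickness = skull_thickness,
                 lesion_count = as.integer(lesion_count),
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma,
                 voxel_spacing = voxel_spacing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalized squared ellipsoid radius of every voxel for given semi-axes,
# centred on the volume centre. Returns an array of the volume's shape.
ellipsoid_rho2 <- function(shape, axes) {
  ctr <- (shape + 1) / 2
  z <- ((seq_len(shape[1]) - ctr[1]) / axes[1])^2
  y <- ((seq_len(shape[2]) - ctr[2]) / axes[2])^2
  x <- ((seq_len(shape[3]) - ctr[3]) / axes[3])^2
  outer(outer(z, y, `+`), x, `+`)
}

#' Generate a synthetic FLAIR-like brain phantom
#'
#' Builds the 3D intensity volume and exact binary lesion mask described by a
#' [phantom_spec()]. Lesions are placed by rejection sampling (at most 1000
#' attempts per lesion) as spheres fully inside the brain ellipsoid and
#' mutually separated by more than one voxel, so 26-connected labelling of
#' the mask recovers exactly `lesion_count` components. All randomness flows
#' from `spec$seed`; the caller's RNG state is untouched.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id identifier stored with the volume.
#' @return a `phantom_volume`: list with `intensity` (3D array), `mask`
#'   (3D 0/1 array), `voxel_spacing`, and `patient_id`.
#' @export
generate_phantom <- function(spec, patient_id = "phantom01") {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- spec$shape
    rho2 <- ellipsoid_rho2(shape, spec$brain_axes)
    brain <- rho2 <= 1
    vol <- array(0, shape)
    vol[brain] <- 100

    if (spec$skull_ring) {
      gap <- 2
      inner <- ellipsoid_rho2(shape, spec$brain_axes + gap) > 1
      outer_sh <- ellipsoid_rho2(shape, spec$brain_axes + gap +
                                   spec$skull_thickness) <= 1
      vol[inner & outer_sh] <- 180
    }

    mask <- array(0L, shape)
    centers <- matrix(0, 0, 3)
    radii <- numeric(0)
    ctr <- (shape + 1) / 2
    for (k in seq_len(spec$lesion_count)) {
      placed <- FALSE
      for (att in seq_len(1000L)) {
        r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        cand <- c(runif(1, 1, shape[1]), runif(1, 1, shape[2]),
                  runif(1, 1, shape[3]))
        # conservative inside-ellipsoid check with shrunken axes
        ax <- spec$brain_axes - r - 1
        if (any(ax <= 0)) next
        if (sum(((cand - ctr) / ax)^2) > 1) next
        if (nrow(centers) > 0 &&
            any(sqrt(rowSums(sweep(centers, 2, cand)^2)) < radii + r + 2)) next
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
        placed <- TRUE
        break
      }
      if (!placed)
        stopf("could not place lesion %d within 1000 attempts; reduce lesion_count or radius", k)
    }
    for (k in seq_along(radii)) {
      cnt <- centers[k, ]; r <- radii[k]
      zi <- max(1, floor(cnt[1] - r)):min(shape[1], ceiling(cnt[1] + r))
      yi <- max(1, floor(cnt[2] - r)):min(shape[2], ceiling(cnt[2] + r))
      xi <- max(1, floor(cnt[3] - r)):min(shape[3], ceiling(cnt[3] + r))
      for (z in zi) for (y in yi) for (x in xi)
        if ((z - cnt[1])^2 + (y - cnt[2])^2 + (x - cnt[3])^2 <= r^2)
          mask[z, y, x] <- 1L
    }
    vol[mask == 1L] <- 100 * spec$lesion_contrast

    if (spec$bias_amplitude > 0) {
      field <- bias_field_3d(shape, brain)
      vol <- vol * (1 + spec$bias_amplitude * field)
    }
    if (spec$noise_sigma > 0)
      vol <- vol + array(rnorm(prod(shape), 0, spec$noise_sigma), shape)

    structure(list(intensity = vol, mask = mask,
                   voxel_spacing = spec$voxel_spacing,
                   patient_id = patient_id),
              class = "phantom_volume")
  })
}

# Random degree-2 polynomial in normalized coordinates, zero mean over the
# brain and scaled to unit maximum absolute value there.
bias_field_3d <- function(shape, brain) {
  co <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  z <- array(rep(co[[1]], times = shape[2] * shape[3]), shape)
  y <- array(rep(rep(co[[2]], each = shape[1]), times = shape[3]), shape)
  x <- array(rep(co[[3]], each = shape[1] * shape[2]), shape)
  terms <- list(z, y, x, z * z, y * y, x * x, z * y, z * x, y * x)
  cf <- runif(length(terms), -1, 1)
  f <- Reduce(`+`, Map(`*`, terms, cf))
  f <- f - mean(f[brain])
  m <- max(abs(f[brain]))
  if (m > 0) f <- f / m
  f
}

#' Write a phantom (or any volume pair) as NIfTI
#'
#' Writes the intensity volume and the binary mask as two NIfTI files with
#' identical geometry: `<patient_id>_image.nii.gz` and
#' `<patient_id>_mask.nii.gz` under `dir`. The pair round-trips through
#' [load_volume_pair()] (mask exactly, intensity to float precision).
#'
#' @param vol a `phantom_volume` (or compatible list with `intensity`,
#'   `mask`, `voxel_spacing`, `patient_id`).
#' @param dir existing output directory.
#' @return invisibly, a named character vector with `image` and `mask` paths.
#' @export
write_phantom <- function(vol, dir) {
  if (!dir.exists(dir)) stopf("output directory does not exist: %s", dir)
  if (!is_binary(vol$mask)) stopf("mask must be binary (0/1) before writing")
  sp <- vol$voxel_spacing
  # affine mapping voxel axis 1 to +z (inferior -> superior), so the pair
  # reloads in canonical axial order
  aff <- rbind(c(0, 0, sp[3], 0),
               c(0, sp[2], 0, 0),
               c(sp[1], 0, 0, 0),
               c(0, 0, 0, 1))
  mk <- function(a) {
    n <- RNifti::asNifti(a, pixdim = sp)
    RNifti::`sform<-`(n, structure(aff, code = 2L))
  }
  img <- mk(vol$intensity)
  msk <- mk(array(as.integer(vol$mask), dim(vol$mask)))
  pi <- file.path(dir, paste0(vol$patient_id, "_image.nii.gz"))
  pm <- file.path(dir, paste0(vol$patient_id, "_mask.nii.gz"))
  RNifti::writeNifti(img, pi)
  RNifti::writeNifti(msk, pm)
  invisible(c(image = pi, mask = pm))
}

#' Serialize / read a phantom spec as YAML
#' @param spec a [phantom_spec()].
#' @param path file path.
#' @return `phantom_spec_to_yaml` returns `path` invisibly;
#'   `phantom_spec_from_yaml` returns a [phantom_spec()].
#' @export
phantom_spec_to_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname phantom_spec_to_yaml
#' @export
phantom_spec_from_yaml <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}
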
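#' Run the end-to-end workflow on a synthetic cohort
#'
#' Ties the stages together: phantom cohort generation, preprocessing,
#' patient-disjoint splitting, training-set augmentation, training,
#' evaluation, and optional Grad-CAM export. Every stage writes its
#' manifest (CSV with stable column order) under `out_dir`, together with a
#' run log recording the seed and configuration hash, so reruns with the
#' same config and seed reproduce identical manifests.
#'
#' @param out_dir run directory (created if missing).
#' @param n_patients number of phantom patients to simulate.
#' @param seed master seed; per-stage seeds derive from it.
#' @param stages ordered subset of
#'   `c("phantom", "prep", "augment", "train", "evaluate", "explain")`.
#' @param phantom a [phantom_spec()] template (its seed is re-derived per
#'   patient).
#' @param pre a [preprocess_config()].
#' @param filt a [slice_filter_config()].
#' @param aug an [augment_spec()], or `NULL` to skip augmentation.
#' @param model_cfg an [msdasp_config()].
#' @param tcfg a [train_config()].
#' @param checkpoint_path optional existing checkpoint to reuse when
#'   `"train"` is not among the stages.
#' @return list with `slices`, `split`, `checkpoint`, `metrics`, and
#'   `paths` of the written artifacts.
#' @export
run_pipeline <- function(out_dir, n_patients = 4L, seed = 1L,
                         stages = c("phantom", "prep", "augment", "train",
                                    "evaluate"),
                         phantom = phantom_spec(shape = c(24L, 128L, 128L),
                                                lesion_count = 3L,
                                                lesion_radius_range = c(4, 7),
                                                noise_sigma = 2,
                                                bias_amplitude = 0.1),
                         pre = preprocess_config(target_size = c(128L, 128L)),
                         filt = slice_filter_config(),
                         aug = NULL,
                         model_cfg = msdasp_config("desk"),
                         tcfg = train_config(epochs = 10L, seed = seed,
                                             freeze_epochs = 0,
                                             max_steps = 60L),
                         checkpoint_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("phantom", "prep", "augment", "train", "evaluate", "explain")
  stages <- match.arg(stages, known, several.ok = TRUE)
  paths <- list()
  log <- c(sprintf("seed: %d", seed),
           sprintf("stages: %s", paste(stages, collapse = ", ")))

  vols <- NULL
  if ("phantom" %in% stages) {
    pdir <- file.path(out_dir, "phantom")
    dir.create(pdir, showWarnings = FALSE)
    vols <- lapply(seq_len(n_patients), function(i) {
      sp <- phantom
      sp$seed <- seed * 1000L + i
      v <- generate_phantom(sp, patient_id = sprintf("p%02d", i))
      write_phantom(v, pdir)
      v
    })
    man <- data.frame(patient_id = vapply(vols, `[[`, character(1),
                                          "patient_id"),
                      lesion_voxels = vapply(vols, function(v) sum(v$mask),
                                             numeric(1)))
    paths$phantom_manifest <- file.path(pdir, "phantom_manifest.csv")
    write.csv(man, paths$phantom_manifest, row.names = FALSE)
    log <- c(log, sprintf("phantom: %d patients", n_patients))
  }

  slices <- NULL
  if ("prep" %in% stages) {
    if (is.null(vols)) stopf("stage 'prep' needs the phantom stage (or volumes)")
    prepped <- lapply(vols, preprocess_volume, pre = pre, filt = filt)
    slices <- do.call(c, lapply(prepped, `[[`, "slices"))
    man <- do.call(rbind, lapply(prepped, `[[`, "manifest"))
    paths$prep_manifest <- file.path(out_dir, "prep_manifest.csv")
    write.csv(man, paths$prep_manifest, row.names = FALSE)
    log <- c(log, sprintf("prep: %d slices retained", length(slices)))
  }

  split <- NULL
  ck <- NULL
  if ("train" %in% stages) {
    if (is.null(slices)) stopf("stage 'train' needs preprocessed slices")
    split <- split_patients(slice_ids(slices), tcfg$test_fraction,
                            seed = tcfg$seed)
    train_sl <- Filter(function(s)
      s$patient_id %in% split$train_patients, slices)
    if ("augment" %in% stages && !is.null(aug))
      train_sl <- augment_dataset(train_sl, aug)
    ck <- train_model(train_sl, tcfg, model_cfg,
                      test_patients = split$test_patients)
    ck$split <- split
    paths$checkpoint <- file.path(out_dir, "checkpoint.rds")
    save_checkpoint(ck, paths$checkpoint)
    paths$history <- file.path(out_dir, "history.csv")
    write.csv(ck$history, paths$history, row.names = FALSE)
    log <- c(log, sprintf("train: %d slices, %d steps", length(train_sl),
                          ck$steps))
  } else if (!is.null(checkpoint_path)) {
    ck <- load_checkpoint(checkpoint_path)
    split <- ck$split
  }

  metrics <- NULL
  if ("evaluate" %in% stages) {
    if (is.null(ck))
      stopf("stage 'evaluate' needs a checkpoint (run 'train' or pass checkpoint_path)")
    test_sl <- if (!is.null(split))
      Filter(function(s) s$patient_id %in% split$test_patients, slices)
    else slices
    metrics <- evaluate_slices(ck, test_sl)
    paths$metrics <- file.path(out_dir, "metrics.csv")
    write.csv(as.data.frame(unclass(metrics)), paths$metrics,
              row.names = FALSE)
    log <- c(log, sprintf("evaluate: dice %.4f on %d test slices",
                          metrics$dice, length(test_sl)))
  }

  if ("explain" %in% stages && !is.null(ck) && length(slices) > 0) {
    s <- slices[[1]]
    cam <- gradcam(ck, s)
    paths$cam <- file.path(out_dir, "gradcam_overlay.png")
    cam_overlay(cam, s$image, alpha = 0.5, path = paths$cam)
    log <- c(log, "explain: gradcam overlay written")
  }

  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(list(slices = slices, split = split, checkpoint = ck,
                 metrics = metrics, paths = paths))
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML file may hold any of the sections `phantom`, `preprocess`,
#' `slice_filter`, `augment`, `model`, `train`, plus top-level
#' `n_patients`, `seed`, and `stages`; each section is passed to the
#' corresponding constructor, so defaults apply to omitted fields.
#'
#' @param path YAML file path.
#' @return named list of arguments for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$n_patients)) args$n_patients <- y$n_patients
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$stages)) args$stages <- y$stages
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$preprocess))
    args$pre <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$slice_filter))
    args$filt <- do.call(slice_filter_config, y$slice_filter)
  if (!is.null(y$augment)) args$aug <- do.call(augment_spec, y$augment)
  if (!is.null(y$model)) args$model_cfg <- do.call(msdasp_config, y$model)
  if (!is.null(y$train)) args$tcfg <- do.call(train_config, y$train)
  args
}

#' Build a small preprocessed phantom cohort
#'
#' Convenience generator for CPU-scale experiments: simulates FLAIR-like
#' phantom patients, runs the full preprocessing chain at the requested
#' slice size, and returns the first `n_slices` retained slices (spread
#' across the patients in generation order).
#'
#' @param n_slices number of slices to return.
#' @param n_patients phantom patients to simulate.
#' @param size slice size `(H, W)` after preprocessing.
#' @param seed master seed for the phantom draws.
#' @param lesion_contrast,lesion_radius_range phantom lesion parameters.
#' @return list of preprocessed `slice_pair`s.
#' @export
desk_demo_cohort <- function(n_slices = 8L, n_patients = 2L,
                             size = c(128L, 128L), seed = 101L,
                             lesion_contrast = 1.6,
                             lesion_radius_range = c(4, 7)) {
  pre <- preprocess_config(target_size = size)
  slices <- list()
  for (i in seq_len(n_patients)) {
    sp <- phantom_spec(shape = c(24L, 128L, 128L), lesion_count = 3L,
                       lesion_radius_range = lesion_radius_range,
                       lesion_contrast = lesion_contrast, noise_sigma = 2,
                       bias_amplitude = 0.1, seed = seed + i)
    v <- generate_phantom(sp, sprintf("p%02d", i))
    slices <- c(slices, preprocess_volume(v, pre)$slices)
  }
  if (length(slices) < n_slices)
    stopf("cohort produced only %d slices", length(slices))
  slices[seq_len(n_slices)]
}
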
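#' Training configuration
#'
#' Defaults follow the published training recipe: binary cross-entropy
#' loss, Adam with learning rate 0.001, batch size 4, dropout 0.2,
#' 100 epochs, a 90:10 patient-level train/test split, and a 0.5
#' probability threshold. `freeze_epochs` controls how long the encoder is
#' excluded from updates (the default keeps it frozen for the whole run,
#' the behaviour described for a pretrained encoder; set 0 to train it —
#' the sensible choice for a randomly initialised encoder).
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training set.
#' @param dropout dropout rate used in the network during training.
#' @param test_fraction held-out patient fraction (0.10, 0.15, or 0.20 in
#'   the reported ablations; any value in (0, 1) is accepted).
#' @param seed seed governing the split, shuffling, dropout, and
#'   initialisation.
#' @param freeze_epochs epochs with the encoder frozen (default `Inf` =
#'   entire run).
#' @param threshold probability threshold for binary masks.
#' @param max_steps optional hard cap on optimizer steps (for short
#'   CPU-scale runs); `Inf` disables it.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 4L, learning_rate = 0.001,
                         epochs = 100L, dropout = 0.2,
                         test_fraction = 0.10, seed = 1L,
                         freeze_epochs = Inf, threshold = 0.5,
                         max_steps = Inf) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  if (epochs <= 0 || batch_size <= 0)
    stopf("epochs and batch_size must be positive")
  structure(list(loss = "bce", batch_size = as.integer(batch_size),
                 optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs), dropout = dropout,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 freeze_epochs = freeze_epochs, threshold = threshold,
                 max_steps = max_steps),
            class = "train_config")
}

#' Patient-level train/test split
#'
#' Patients (never slices) are shuffled with a seeded RNG and
#' `ceiling(n * test_fraction)` of them assigned to the test set, so all
#' slices of a patient end up on the same side and no patient leaks across
#' the boundary.
#'
#' @param patient_ids character vector of patient identifiers (duplicates
#'   collapse).
#' @param test_fraction fraction of patients held out.
#' @param seed integer seed; identical seeds give identical plans.
#' @return a `split_plan`: list with `train_patients` and `test_patients`.
#' @export
split_patients <- function(patient_ids, test_fraction = 0.10, seed = 1L) {
  ids <- unique(patient_ids)
  if (length(ids) < 2L) stopf("need at least 2 patients to split")
  n_test <- ceiling(length(ids) * test_fraction)
  if (n_test <= 0 || n_test >= length(ids))
    stopf("test set would be empty or contain every patient")
  shuffled <- with_seed(seed, sample(ids))
  structure(list(train_patients = sort(shuffled[-seq_len(n_test)]),
                 test_patients = sort(shuffled[seq_len(n_test)])),
            class = "split_plan")
}

#' Binary cross-entropy loss
#'
#' Per-pixel cross-entropy between a binary mask and a probability map,
#' `-sum_i [y_i log o_i + (1 - y_i) log(1 - o_i)]`, with probabilities
#' clamped to `[eps, 1 - eps]` for log stability. Both the raw sum and the
#' per-pixel mean (the quantity actually optimised, since the sum scales
#' with image size) are returned.
#'
#' @param y binary ground-truth mask.
#' @param o probability map of the same shape.
#' @param eps clamp width (default 1e-7).
#' @return list with `sum` and `mean`.
#' @export
bce_loss <- function(y, o, eps = 1e-7) {
  if (!identical(dim(y), dim(o)) || length(y) != length(o))
    stopf("mask/probability shape mismatch")
  oc <- clamp01(o, eps)
  s <- -sum(y * log(oc) + (1 - y) * log(1 - oc))
  list(sum = s, mean = s / length(y))
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, mask = NULL) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mh <- st$m / (1 - beta1^st$t)
  vh <- st$v / (1 - beta2^st$t)
  upd <- lr * mh / (sqrt(vh) + eps)
  if (!is.null(mask)) upd <- upd * mask
  list(theta = theta - upd, st = st)
}

slice_ids <- function(slices) {
  unique(vapply(slices, function(s) s$patient_id, character(1)))
}

#' Train the segmentation network
#'
#' Minibatch Adam on the mean binary cross-entropy, with seeded shuffling,
#' per-epoch history (mean loss and mean training Dice at the configured
#' threshold), encoder freezing for the first `freeze_epochs` epochs, and a
#' leakage guard: training aborts if any slice belongs to a patient listed
#' in `test_patients`.
#'
#' @param train_slices list of preprocessed `slice_pair`s, all the same
#'   shape.
#' @param cfg a [train_config()].
#' @param model_cfg an [msdasp_config()]; its `input_size` must match the
#'   slices.
#' @param model optional existing `msdasp_model` to continue training;
#'   otherwise one is created from `model_cfg` with `cfg$seed`.
#' @param test_patients optional character vector for the leakage guard.
#' @param verbose print one line per epoch.
#' @return a `checkpoint`: list with `model`, `train_cfg`, `history`
#'   (data frame epoch/loss/dice), `steps`, and `seed`.
#' @export
train_model <- function(train_slices, cfg = train_config(),
                        model_cfg = msdasp_config("desk"), model = NULL,
                        test_patients = NULL, verbose = FALSE) {
  if (length(train_slices) == 0L) stopf("training set is empty")
  leak <- intersect(slice_ids(train_slices), test_patients)
  if (length(leak) > 0)
    stopf("data leakage: test patient(s) %s present in the training set",
          paste(leak, collapse = ", "))
  shp <- dim(train_slices[[1]]$image)
  if (!all(vapply(train_slices, function(s)
    identical(dim(s$image), shp), logical(1))))
    stopf("all training slices must share one shape")
  model_cfg$dropout_rate <- cfg$dropout
  if (is.null(model)) model <- create_model(model_cfg, seed = cfg$seed)
  with_seed(cfg$seed + 1L, {
    theta <- flatten_params(model$params)
    skel <- model$params
    st <- adam_init(length(theta))
    frozen_mask <- 1 - encoder_mask(model$params)  # 0 on encoder entries
    n <- length(train_slices)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          dice = numeric(0))
    steps <- 0L
    for (ep in seq_len(cfg$epochs)) {
      if (steps >= cfg$max_steps) break
      ord <- sample.int(n)
      mask <- if (ep <= cfg$freeze_epochs) frozen_mask else NULL
      ep_loss <- c(); ep_dice <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        if (steps >= cfg$max_steps) break
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        gacc <- NULL
        for (j in idx) {
          s <- train_slices[[j]]
          f <- net_forward(model, s$image, training = TRUE)
          l <- bce_loss(s$mask, f$prob)
          if (!is.finite(l$mean))
            stopf("non-finite loss in epoch %d (slice %s/%d)", ep,
                  s$patient_id, s$slice_index)
          dlogits <- (f$prob - s$mask) / length(s$mask)
          bw <- net_backward(model, f$cache, dlogits)
          g <- flatten_params(bw$grads)
          gacc <- if (is.null(gacc)) g else gacc + g
          ep_loss <- c(ep_loss, l$mean)
          pred <- f$prob >= cfg$threshold
          ep_dice <- c(ep_dice, dice_from_masks(pred, s$mask))
        }
        gacc <- gacc / length(idx)
        up <- adam_step(theta, gacc, st, cfg$learning_rate, mask = mask)
        theta <- up$theta; st <- up$st
        model$params <- unflatten_like(skel, theta)
        steps <- steps + 1L
      }
      history <- rbind(history, data.frame(epoch = ep,
                                           loss = mean(ep_loss),
                                           dice = mean(ep_dice)))
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  dice %.4f",
                        ep, mean(ep_loss), mean(ep_dice)))
    }
    structure(list(model = model, train_cfg = cfg, history = history,
                   steps = steps, seed = cfg$seed),
              class = "checkpoint")
  })
}

dice_from_masks <- function(pred, gt) {
  tp <- sum(pred & gt == 1)
  denom <- 2 * tp + sum(pred & gt == 0) + sum(!pred & gt == 1)
  if (denom == 0) 1 else 2 * tp / denom
}

#' Predict a batch of slices from a checkpoint
#'
#' Deterministic inference (dropout off) on each slice, thresholded into
#' binary masks.
#'
#' @param checkpoint a `checkpoint` from [train_model()] (or an
#'   `msdasp_model`).
#' @param slices list of `slice_pair`s matching the model's input size.
#' @param threshold probability threshold; defaults to the checkpoint's.
#' @return list of `prediction` objects.
#' @export
predict_batch <- function(checkpoint, slices, threshold = NULL) {
  model <- if (inherits(checkpoint, "checkpoint")) checkpoint$model
           else checkpoint
  if (is.null(threshold))
    threshold <- if (inherits(checkpoint, "checkpoint"))
      checkpoint$train_cfg$threshold else model$cfg$threshold
  lapply(slices, function(s) net_predict(model, s$image, threshold))
}

#' Save / load a checkpoint
#' @param checkpoint a `checkpoint`.
#' @param path file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
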
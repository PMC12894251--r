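#' Pixel confusion counts between two binary masks
#'
#' TP: lesion pixel predicted lesion; TN: background predicted background;
#' FN: lesion predicted background; FP: background predicted lesion.
#'
#' @param pred,gt binary masks of identical shape.
#' @return a `confusion_counts`: list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stopf("prediction/ground-truth shape mismatch")
  if (!is_binary(pred) || !is_binary(gt))
    stopf("confusion requires binary masks")
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

# Ratio with the degenerate-count convention: when the denominator is 0 the
# metric is 1 (the requirement is vacuously met), matching e.g.
# dice = jaccard = sensitivity = 1 for an empty ground truth met by an
# empty prediction.
safe_ratio <- function(num, den) if (den == 0) 1 else num / den

#' Six-metric segmentation panel from confusion counts
#'
#' Precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, Jaccard
#' `TP/(TP+FN+FP)`, Dice `2TP/(2TP+FP+FN)`, specificity `TN/(TN+FP)`, and
#' false positive rate `FP/(FP+TN)`. Zero denominators follow the
#' convention documented in [confusion()]'s panel: the metric is 1 when its
#' requirement is vacuously satisfied (FPR, the complement of specificity,
#' is then 0).
#'
#' @param c a `confusion_counts`.
#' @return a `metric_report`: list with `dice`, `jaccard`, `precision`,
#'   `sensitivity`, `specificity`, `fpr`.
#' @export
metric_panel <- function(c) {
  structure(list(
    dice = safe_ratio(2 * c$TP, 2 * c$TP + c$FP + c$FN),
    jaccard = safe_ratio(c$TP, c$TP + c$FN + c$FP),
    precision = safe_ratio(c$TP, c$TP + c$FP),
    sensitivity = safe_ratio(c$TP, c$TP + c$FN),
    specificity = safe_ratio(c$TN, c$TN + c$FP),
    fpr = if (c$FP + c$TN == 0) 0 else c$FP / (c$FP + c$TN)),
    class = "metric_report")
}

#' Aggregate per-slice evaluations over a test set
#'
#' `"per_slice_mean"` averages each metric across slices (the panel
#' identities, e.g. Jaccard = Dice/(2 - Dice), hold per slice but not for
#' the averages); `"pooled_counts"` sums the confusion counts first and
#' computes one panel.
#'
#' @param counts list of `confusion_counts`, one per slice.
#' @param mode `"per_slice_mean"` or `"pooled_counts"`.
#' @return a `metric_report` with an `aggregation` attribute.
#' @export
aggregate_metrics <- function(counts,
                              mode = c("per_slice_mean", "pooled_counts")) {
  mode <- match.arg(mode)
  if (length(counts) == 0L) stopf("no evaluations to aggregate")
  rep <- if (mode == "pooled_counts") {
    tot <- Reduce(function(a, b) Map(`+`, a, b), lapply(counts, unclass))
    metric_panel(structure(tot, class = "confusion_counts"))
  } else {
    panels <- lapply(counts, metric_panel)
    structure(lapply(setNames(nm = names(panels[[1]])), function(m)
      mean(vapply(panels, `[[`, numeric(1), m))), class = "metric_report")
  }
  attr(rep, "aggregation") <- mode
  rep
}

#' Evaluate a checkpoint on a slice set
#'
#' Predicts every slice and aggregates the confusion counts.
#'
#' @param checkpoint a `checkpoint` or `msdasp_model`.
#' @param slices list of `slice_pair`s.
#' @param mode aggregation mode, see [aggregate_metrics()].
#' @param threshold optional probability threshold.
#' @return a `metric_report`.
#' @export
evaluate_slices <- function(checkpoint, slices,
                            mode = "per_slice_mean", threshold = NULL) {
  preds <- predict_batch(checkpoint, slices, threshold)
  counts <- Map(function(p, s) confusion(p$binary_mask, s$mask),
                preds, slices)
  aggregate_metrics(counts, mode)
}

#' Relative Dice improvement in percent
#'
#' `100 * (new - ref) / ref`, reported at full precision with a 2-decimal
#' rounding alongside, the arithmetic used when comparing Dice scores
#' between architectures.
#'
#' @param new_dice,ref_dice Dice scores; `ref_dice` must be positive.
#' @return list with `percent` (full precision) and `rounded` (2 decimals).
#' @export
relative_improvement <- function(new_dice, ref_dice) {
  if (ref_dice <= 0) stopf("reference Dice must be positive")
  p <- 100 * (new_dice - ref_dice) / ref_dice
  list(percent = p, rounded = round(p, 2))
}

#' Test-split ablation table
#'
#' One six-metric row per test-split fraction, each computed from the
#' checkpoint trained for that fraction on its held-out patients.
#'
#' @param slices full cohort of preprocessed `slice_pair`s.
#' @param checkpoints named list of `checkpoint`s; names are the fractions
#'   (e.g. `"0.1"`), each checkpoint carrying its `split` element (a
#'   `split_plan`) as stored by [run_pipeline()] or supplied by the caller.
#' @param fractions numeric fractions to report (default 0.10/0.15/0.20).
#' @param mode aggregation mode.
#' @param path optional CSV output path.
#' @return data frame with `test_fraction` and the six metric columns.
#' @export
ablation_table <- function(slices, checkpoints,
                           fractions = c(0.10, 0.15, 0.20),
                           mode = "per_slice_mean", path = NULL) {
  rows <- lapply(fractions, function(f) {
    key <- format(f)
    ck <- checkpoints[[key]]
    if (is.null(ck)) stopf("missing checkpoint for test fraction %s", key)
    plan <- ck$split
    if (is.null(plan)) stopf("checkpoint for fraction %s has no split plan", key)
    test <- Filter(function(s) s$patient_id %in% plan$test_patients, slices)
    rep <- evaluate_slices(ck, test, mode)
    cbind(data.frame(test_fraction = f), as.data.frame(unclass(rep)))
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Write a confusion matrix as JSON
#'
#' Four counts plus row-normalised rates (sensitivity/miss rate and
#' FPR/specificity).
#'
#' @param c a `confusion_counts`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
confusion_json <- function(c, path) {
  pos <- c$TP + c$FN; neg <- c$FP + c$TN
  jsonlite::write_json(list(
    counts = unclass(c),
    rates = list(tpr = safe_ratio(c$TP, pos), fnr = if (pos == 0) 0 else c$FN / pos,
                 fpr = if (neg == 0) 0 else c$FP / neg,
                 tnr = safe_ratio(c$TN, neg))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
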
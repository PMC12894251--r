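test_that("confusion counts are exact pixel tallies", {
  gt <- matrix(0L, 4, 4); gt[1, 1:3] <- 1L
  pred <- matrix(0L, 4, 4); pred[1, 2:4] <- 1L
  cc <- confusion(pred, gt)
  expect_equal(unclass(cc), list(TP = 2, FP = 1, FN = 1, TN = 12))
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 16)
  eq <- confusion(gt, gt)
  expect_equal(eq$FP + eq$FN, 0)
  inv <- confusion(1L - gt, gt)
  expect_equal(inv$TP + inv$TN, 0)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
  expect_error(confusion(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("the metric panel reproduces the closed-form values", {
  p <- metric_panel(structure(list(TP = 2, FP = 1, FN = 1, TN = 12),
                              class = "confusion_counts"))
  expect_equal(p$dice, 4 / 6)
  expect_equal(p$jaccard, 0.5)
  expect_equal(p$precision, 2 / 3)
  expect_equal(p$sensitivity, 2 / 3)
  expect_equal(p$specificity, 12 / 13)
  expect_equal(p$fpr, 1 / 13)
  perfect <- metric_panel(confusion(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_equal(unlist(perfect[c("dice", "jaccard", "precision",
                                "sensitivity")]),
               c(dice = 1, jaccard = 1, precision = 1, sensitivity = 1))
  expect_equal(perfect$fpr, 0)
  empty <- metric_panel(confusion(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_equal(empty$dice, 1)
  expect_equal(empty$sensitivity, 1)
})

test_that("panel identities and symmetries hold on random masks", {
  set.seed(77)
  for (i in 1:200) {
    pred <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    gt <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    p <- metric_panel(confusion(pred, gt))
    o <- panel_oracle(pred, gt)
    expect_equal(unclass(p), o, tolerance = 1e-12)
    expect_equal(p$jaccard, p$dice / (2 - p$dice), tolerance = 1e-12)
    expect_equal(p$fpr, 1 - p$specificity, tolerance = 1e-12)
    sw <- metric_panel(confusion(gt, pred))
    expect_equal(sw$dice, p$dice, tolerance = 1e-12)
    expect_equal(sw$jaccard, p$jaccard, tolerance = 1e-12)
    expect_equal(sw$precision, p$sensitivity, tolerance = 1e-12)
    expect_equal(sw$sensitivity, p$precision, tolerance = 1e-12)
  }
})

test_that("aggregation distinguishes slice means from pooled counts", {
  c1 <- confusion(matrix(c(1, 0, 0, 0), 2, 2), matrix(c(1, 1, 1, 1), 2, 2))
  # dice1 = 2/5
  c2 <- confusion(matrix(1, 2, 2), matrix(1, 2, 2))
  # dice2 = 1
  single <- aggregate_metrics(list(c1))
  expect_equal(unclass(single), unclass(metric_panel(c1)),
               ignore_attr = TRUE)
  m <- aggregate_metrics(list(c1, c2), "per_slice_mean")
  expect_equal(m$dice, (2 / 5 + 1) / 2)
  pooled <- aggregate_metrics(list(c1, c2), "pooled_counts")
  # pooled counts: TP = 5, FP = 0, FN = 3 -> dice = 10/13
  expect_equal(pooled$dice, 10 / 13)
  expect_false(isTRUE(all.equal(pooled$dice, m$dice)))
  expect_identical(attr(m, "aggregation"), "per_slice_mean")
  expect_error(aggregate_metrics(list()), "no evaluations")
})

test_that("relative improvement reproduces the printed comparisons", {
  expect_equal(relative_improvement(0.8736, 0.8635)$rounded, 1.17)
  expect_equal(relative_improvement(0.8736, 0.8663)$rounded, 0.84)
  expect_equal(relative_improvement(0.8736, 0.8692)$rounded, 0.51)
  expect_equal(relative_improvement(0.5, 0.5)$rounded, 0)
  expect_error(relative_improvement(0.5, 0), "positive")
})

test_that("the ablation table evaluates one checkpoint per split fraction", {
  sl <- lapply(1:12, function(i) {
    img <- matrix(runif(32 * 32, 0, 0.3), 32, 32)
    m <- matrix(0L, 32, 32); m[10:14, 10:14] <- 1L
    img[m == 1] <- img[m == 1] + 0.6
    slice_pair(img, m, sprintf("p%02d", (i + 2) %/% 3), i, depth = 12L)
  })
  cfg <- tiny_cfg(input_size = c(32L, 32L))
  cks <- list()
  for (f in c(0.10, 0.15, 0.20)) {
    tc <- train_config(epochs = 1L, seed = 11L, test_fraction = f,
                       freeze_epochs = 0)
    plan <- split_patients(unique(vapply(sl, `[[`, character(1),
                                         "patient_id")), f, seed = 11L)
    tr <- Filter(function(s) s$patient_id %in% plan$train_patients, sl)
    ck <- train_model(tr, tc, cfg, test_patients = plan$test_patients)
    ck$split <- plan
    cks[[format(f)]] <- ck
  }
  tab <- ablation_table(sl, cks)
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$test_fraction, c(0.10, 0.15, 0.20))
  expect_true(all(c("dice", "jaccard", "precision", "sensitivity",
                    "specificity", "fpr") %in% names(tab)))
  expect_equal(tab$fpr, 1 - tab$specificity, tolerance = 1e-12)
  # reproducible under identical seeds
  expect_identical(tab, ablation_table(sl, cks))
  expect_error(ablation_table(sl, cks[1:2]), "missing checkpoint")
})
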
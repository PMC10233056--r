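test_that("dice from counts follows the count formula", {
  expect_equal(dice_from_counts(50, 0, 0), 1)
  expect_equal(dice_from_counts(25, 25, 25), 0.5)
  expect_equal(dice_from_counts(0, 0, 10), 0)
  expect_equal(dice_from_counts(0, 0, 0), 0)  # empty-vs-empty convention
})

test_that("local-mean and global DICE separate as the formulas dictate", {
  # two patients: one perfect (TP 50), one all-missed (FN 10)
  cts <- data.frame(TP = c(50, 0), FP = c(0, 0), FN = c(0, 10))
  expect_equal(local_dice_mean(cts), 0.5)
  expect_equal(global_dice(cts), 100 / 110)

  # identical patients: global equals the local mean; single patient too
  same <- data.frame(TP = c(10, 10), FP = c(2, 2), FN = c(3, 3))
  expect_equal(global_dice(same), local_dice_mean(same))
  one <- data.frame(TP = 7, FP = 1, FN = 2)
  expect_equal(global_dice(one), local_dice_mean(one))

  # loop oracle over random count sets
  set.seed(5)
  cts <- data.frame(TP = rpois(100, 20), FP = rpois(100, 5),
                    FN = rpois(100, 5))
  loop_local <- mean(sapply(seq_len(100), function(i)
    2 * cts$TP[i] / (2 * cts$TP[i] + cts$FP[i] + cts$FN[i])))
  expect_equal(local_dice_mean(cts), loop_local, tolerance = 1e-12)
  expect_equal(global_dice(cts),
               2 * sum(cts$TP) / (2 * sum(cts$TP) + sum(cts$FP) + sum(cts$FN)))
  expect_error(local_dice_mean(cts[0, ]), "no patients")
})

test_that("pixel sweep: perfect predictor, class imbalance, monotone recall", {
  set.seed(6)
  truth <- array(rbinom(4000, 1, 0.01), c(20, 20, 10))  # 1% foreground
  thr <- seq(0.2, 0.8, by = 0.1)

  perfect <- pixel_metric_sweep(truth + 0, truth, thr)
  expect_true(all(perfect$precision == 1))
  expect_true(all(perfect$recall == 1))

  # mediocre predictor on background-dominant data: misses foreground but
  # rarely fires on background, so TN dominates and specificity stays high
  noisy <- array(runif(4000) * 0.15, dim(truth))        # low bg scores
  conf <- sample(which(truth == 0), 60)                 # 1.5% confusers
  noisy[conf] <- runif(60, 0.2, 0.9)
  noisy[truth == 1] <- runif(sum(truth == 1), 0.3, 0.8) # imperfect fg
  med <- pixel_metric_sweep(noisy, truth, thr)
  expect_true(all(med$specificity > 0.98))
  # recall non-increasing as the threshold rises
  expect_true(all(diff(med$recall) <= 1e-12))
  expect_error(pixel_metric_sweep(noisy, truth, numeric(0)), "empty")
})

test_that("lesion-level matching counts TP/FP/FN on enumerated toys", {
  truth <- array(0L, c(12, 12, 1))
  truth[2:4, 2:4, 1] <- 1L     # lesion A
  truth[8:10, 8:10, 1] <- 2L   # lesion B
  pred <- array(0L, c(12, 12, 1))
  pred[3:5, 3:5, 1] <- 1L      # overlaps A
  pred[8:9, 8:9, 1] <- 2L      # overlaps B
  pred[1:2, 10:12, 1] <- 3L    # spurious blob
  r <- lesion_level_metrics(pred, truth)
  expect_equal(r$TP, 2); expect_equal(r$FN, 0); expect_equal(r$FP, 1)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 1)
  expect_true(is.na(r$TN))

  # empty prediction: recall 0, precision reported 1 with a degenerate flag
  none <- array(0L, dim(truth))
  r0 <- lesion_level_metrics(none, truth)
  expect_equal(r0$recall, 0)
  expect_equal(r0$precision, 1)
  expect_true(r0$degenerate)

  # IoU rule: a 10%-overlap pair no longer counts as a detection
  small <- array(0L, c(12, 12, 1)); small[2, 2:4, 1] <- 1L  # IoU 3/9
  riou <- lesion_level_metrics(small, truth, match_rule = "iou",
                               iou_threshold = 0.5)
  expect_equal(riou$TP, 0)

  # splitting one prediction into two pieces on the same lesion: still 1 TP
  split2 <- array(0L, c(12, 12, 1))
  split2[2, 2:3, 1] <- 1L; split2[4, 2:3, 1] <- 2L
  truthA <- array(0L, c(12, 12, 1)); truthA[2:4, 2:4, 1] <- 1L
  rs <- lesion_level_metrics(split2, truthA)
  expect_equal(rs$TP, 1)
  expect_equal(rs$FP, 0)
})

test_that("patient-level metrics dominate detection semantics", {
  pp <- data.frame(n_true = c(2, 1, 0, 0), n_detected = c(1, 1, 0, 0),
                   n_pred = c(3, 1, 1, 0))
  r <- patient_level_metrics(pp)
  expect_equal(r$TP, 2)       # both lesion-bearing patients detected
  expect_equal(r$FN, 0)
  expect_equal(r$FP, 1)       # lesion-free patient with a predicted blob
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 2 / 3)

  all_hit <- data.frame(n_true = c(1, 2), n_detected = c(1, 1),
                        n_pred = c(1, 1))
  expect_equal(patient_level_metrics(all_hit)$recall, 1)
})

test_that("confusion matrix and accuracy over resolved categories", {
  all_ok <- confusion_and_accuracy(c("LR3", "LR4", "LR5"),
                                   c("LR3", "LR4", "LR5"))
  expect_equal(all_ok$accuracy, 1)
  expect_equal(diag(all_ok$matrix), c(LR3 = 1, LR4 = 2, LR5 = 3) * 0 + 1,
               ignore_attr = TRUE)

  pred <- c(rep("LR5", 3), rep("LR5", 7))
  true <- c(rep("LR4", 3), rep("LR5", 7))
  cm <- confusion_and_accuracy(pred, true)
  expect_equal(cm$accuracy, 0.7)
  expect_equal(cm$matrix["LR4", "LR5"], 3, ignore_attr = TRUE)
  expect_equal(cm$over, 3)
  expect_equal(cm$under, 0)
  # row sums equal per-class ground-truth counts
  expect_equal(rowSums(cm$matrix), c(LR3 = 0, LR4 = 3, LR5 = 7))

  # order invariance
  perm <- sample(seq_along(pred))
  expect_equal(confusion_and_accuracy(pred[perm], true[perm])$matrix,
               cm$matrix)
  expect_error(confusion_and_accuracy("LR2", "LR3"), "LR3")
})

test_that("patient dice conventions for empty masks", {
  e <- array(0, c(4, 4, 2))
  f <- e; f[1, 1, 1] <- 1
  expect_equal(patient_dice(e, e), 1)
  expect_equal(patient_dice(e, e, empty_value = 0), 0)
  expect_equal(patient_dice(e, f), 0)
  expect_equal(patient_dice(f, f), 1)
})
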
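# Evaluation suite: local and global DICE, pixel/lesion/patient-level
# precision-recall sweeps over binarization thresholds, and the LI-RADS
# category confusion matrix.

#' DICE from pixel counts
#'
#' `2 TP / (2 TP + FP + FN)`; defined as 0 when the denominator is 0
#' (empty prediction against empty truth at this granularity).
#'
#' @param TP,FP,FN Nonnegative counts (vectorized).
#' @return Dice value(s) in \[0, 1\].
#' @export
dice_from_counts <- function(TP, FP, FN) {
  den <- 2 * TP + FP + FN
  ifelse(den > 0, 2 * TP / den, 0)
}

#' Average local DICE
#'
#' Unweighted mean of per-patient DICE values: each patient's counts give one
#' DICE, and the values are averaged. Patients with small or missed lesions
#' weigh as much as large ones, so many near-zero patients drag this mean
#' below the pooled (global) DICE.
#'
#' @param counts Data frame with columns `TP`, `FP`, `FN` (one row per
#'   patient).
#' @return Scalar in \[0, 1\].
#' @export
local_dice_mean <- function(counts) {
  if (nrow(counts) == 0) stop("no patients: cannot average local DICE")
  mean(dice_from_counts(counts$TP, counts$FP, counts$FN))
}

#' Global (pooled) DICE
#'
#' Pools TP/FP/FN over patients first, then computes one DICE:
#' `2 sum(TP) / (2 sum(TP) + sum(FP) + sum(FN))`.
#'
#' @inheritParams local_dice_mean
#' @return Scalar in \[0, 1\].
#' @export
global_dice <- function(counts) {
  if (nrow(counts) == 0) stop("no patients: cannot pool counts")
  dice_from_counts(sum(counts$TP), sum(counts$FP), sum(counts$FN))
}

.pixel_counts <- function(pred, truth) {
  p <- as.logical(pred != 0); t <- as.logical(truth != 0)
  c(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Pixel-level metric sweep over thresholds
#'
#' Pools pixel counts over all volumes at each threshold and reports
#' precision, recall (= sensitivity = TPR), specificity and FPR. Precision
#' with zero predicted pixels is reported as 1 with `degenerate = TRUE`.
#'
#' @param probs List of probability arrays (or a single array).
#' @param truths List of binary arrays aligned with `probs`.
#' @param thresholds Numeric vector of thresholds in (0, 1).
#' @return Data frame: threshold, TP, FP, FN, TN, precision, recall,
#'   specificity, fpr, degenerate.
#' @export
pixel_metric_sweep <- function(probs, truths, thresholds) {
  if (length(thresholds) == 0) stop("threshold list is empty")
  if (!is.list(probs)) probs <- list(probs)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(probs) == length(truths))
  out <- lapply(thresholds, function(thr) {
    cts <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (i in seq_along(probs)) {
      if (!identical(dim(probs[[i]]), dim(truths[[i]])))
        stop("probability map and truth mask are not aligned")
      cts <- cts + .pixel_counts(probs[[i]] >= thr, truths[[i]])
    }
    degen <- (cts["TP"] + cts["FP"]) == 0
    data.frame(threshold = thr, TP = cts[["TP"]], FP = cts[["FP"]],
               FN = cts[["FN"]], TN = cts[["TN"]],
               precision = if (degen) 1 else
                 cts[["TP"]] / (cts[["TP"]] + cts[["FP"]]),
               recall = if (cts[["TP"]] + cts[["FN"]] == 0) 1 else
                 cts[["TP"]] / (cts[["TP"]] + cts[["FN"]]),
               specificity = if (cts[["TN"]] + cts[["FP"]] == 0) 1 else
                 cts[["TN"]] / (cts[["TN"]] + cts[["FP"]]),
               fpr = if (cts[["TN"]] + cts[["FP"]] == 0) 0 else
                 cts[["FP"]] / (cts[["TN"]] + cts[["FP"]]),
               degenerate = as.logical(degen))
  })
  do.call(rbind, out)
}

#' Lesion-level detection metrics
#'
#' A true lesion counts as detected (TP) if it overlaps any predicted
#' component under the match rule; predicted components overlapping no true
#' lesion are FP; undetected true lesions are FN. True negatives are
#' undefined at lesion granularity and reported as `NA`. Splitting one
#' predicted component into several pieces overlapping the same true lesion
#' still yields one TP and no FP.
#'
#' @param pred_labels Integer label array of predicted components (0 =
#'   background), as from [extract_components()].
#' @param true_labels Integer label array of true lesion components on the
#'   same grid.
#' @param match_rule `"overlap"` (>= 1 shared voxel, default) or `"iou"`
#'   (pairwise IoU must reach `iou_threshold`).
#' @param iou_threshold Minimum IoU for the `"iou"` rule.
#' @return `list(TP, FP, FN, TN = NA, precision, recall, degenerate)`;
#'   precision with zero predicted components is 1 with `degenerate = TRUE`.
#' @export
lesion_level_metrics <- function(pred_labels, true_labels,
                                 match_rule = c("overlap", "iou"),
                                 iou_threshold = 0.5) {
  match_rule <- match.arg(match_rule)
  if (!identical(dim(pred_labels), dim(true_labels)))
    stop("component label arrays are not on the same grid")
  pids <- setdiff(unique(as.vector(pred_labels)), 0)
  tids <- setdiff(unique(as.vector(true_labels)), 0)
  matched_true <- logical(length(tids))
  matched_pred <- logical(length(pids))
  for (i in seq_along(tids)) {
    tmask <- true_labels == tids[i]
    for (j in seq_along(pids)) {
      pmask <- pred_labels == pids[j]
      inter <- sum(tmask & pmask)
      if (inter == 0) next
      hit <- if (match_rule == "overlap") TRUE else
        inter / sum(tmask | pmask) >= iou_threshold
      if (hit) {
        matched_true[i] <- TRUE
        matched_pred[j] <- TRUE
      }
    }
  }
  TP <- sum(matched_true)
  FN <- sum(!matched_true)
  FP <- sum(!matched_pred)
  degen <- length(pids) == 0
  list(TP = TP, FP = FP, FN = FN, TN = NA,
       precision = if (degen) 1 else TP / (TP + FP),
       recall = if (length(tids) == 0) 1 else TP / (TP + FN),
       degenerate = degen)
}

#' Patient-level detection metrics
#'
#' A patient with lesions counts as detected if at least one of their true
#' lesions is detected; a lesion-free patient with any predicted component
#' counts as a patient-level false positive.
#'
#' @param per_patient Data frame with one row per patient and columns
#'   `n_true` (true lesions), `n_detected` (true lesions detected) and
#'   `n_pred` (predicted components).
#' @return `list(TP, FP, FN, precision, recall, degenerate)`.
#' @export
patient_level_metrics <- function(per_patient) {
  pos <- per_patient$n_true > 0
  TP <- sum(pos & per_patient$n_detected > 0)
  FN <- sum(pos & per_patient$n_detected == 0)
  FP <- sum(!pos & per_patient$n_pred > 0)
  degen <- (TP + FP) == 0
  list(TP = TP, FP = FP, FN = FN,
       precision = if (degen) 1 else TP / (TP + FP),
       recall = if (sum(pos) == 0) 1 else TP / (TP + FN),
       degenerate = degen)
}

#' LI-RADS confusion matrix and overall accuracy
#'
#' 3 x 3 matrix indexed true x predicted over `{LR3, LR4, LR5}` (ambiguous
#' categories must be resolved first), overall accuracy `trace / total`, and
#' the over/under-categorization counts (upper and lower off-diagonal
#' triangles).
#'
#' @param predicted,true Character vectors of categories.
#' @return An object of class `lirads_confusion`: `list(matrix, accuracy,
#'   over, under, n)`.
#' @export
confusion_and_accuracy <- function(predicted, true) {
  lv <- c("LR3", "LR4", "LR5")
  if (!all(predicted %in% lv) || !all(true %in% lv))
    stop("categories must be in {LR3, LR4, LR5}; resolve ambiguity first")
  stopifnot(length(predicted) == length(true))
  m <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  m <- unclass(m)
  dimnames(m) <- list(true = lv, predicted = lv)
  n <- sum(m)
  structure(list(matrix = m,
                 accuracy = if (n > 0) sum(diag(m)) / n else NA_real_,
                 over = sum(m[upper.tri(m)]),
                 under = sum(m[lower.tri(m)]),
                 n = n),
            class = "lirads_confusion")
}

#' @export
print.lirads_confusion <- function(x, ...) {
  cat("LI-RADS category confusion matrix (true x predicted)\n")
  print(x$matrix)
  cat(sprintf("overall accuracy: %.3f (n = %d)\n", x$accuracy, x$n))
  cat(sprintf("over-categorized: %d, under-categorized: %d\n",
              x$over, x$under))
  invisible(x)
}

#' Per-patient segmentation DICE
#'
#' DICE of a binary prediction against the truth mask for one patient. When
#' both masks are empty the value is 1 by default (no lesion, none
#' predicted); configurable to 0 for strict conventions.
#'
#' @param pred,truth Binary arrays on the same grid.
#' @param empty_value DICE value when both masks are empty.
#' @return Scalar in \[0, 1\].
#' @export
patient_dice <- function(pred, truth, empty_value = 1) {
  cts <- .pixel_counts(pred, truth)
  if (2 * cts[["TP"]] + cts[["FP"]] + cts[["FN"]] == 0) return(empty_value)
  dice_from_counts(cts[["TP"]], cts[["FP"]], cts[["FN"]])
}

#' Plot a precision-recall sweep
#'
#' @param x Data frame from [pixel_metric_sweep()] (or any frame with
#'   `recall` and `precision` columns).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_pr_curve <- function(x, ...) {
  graphics::plot(x$recall, x$precision, type = "b", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "recall", ylab = "precision", ...)
}
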
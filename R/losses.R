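#' Loss configuration for segmentation training
#'
#' Bundles the tunable constants of the hybrid segmentation loss: the focal
#' class-balance factor `alpha` (weight of the lesion class; background gets
#' `1 - alpha`), the focusing parameter `gamma`, the dice smoothing constant
#' `epsilon`, and the training-loss threshold `lovasz_trigger` below which the
#' Lovasz-Softmax term is switched on (latched) for fine-tuning.
#'
#' @param alpha Focal weighting factor for the lesion class, in \[0, 1\].
#' @param gamma Focal focusing parameter, >= 0. `gamma = 0` reduces the focal
#'   term to (alpha-weighted) cross-entropy.
#' @param epsilon Smoothing constant added to the soft-dice numerator and
#'   denominator so empty classes do not produce 0/0.
#' @param lovasz_trigger Training-loss value below which the Lovasz term is
#'   added to the hybrid loss. Use `Inf` to enable it from step 0, `-Inf` to
#'   disable it.
#' @param n_classes Number of classes (2: lesion vs. non-lesion).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.25, gamma = 2, epsilon = 1,
                        lovasz_trigger = 0.3, n_classes = 2L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1,
            is.numeric(gamma), length(gamma) == 1, gamma >= 0,
            is.numeric(epsilon), length(epsilon) == 1, epsilon > 0,
            is.numeric(lovasz_trigger), length(lovasz_trigger) == 1)
  structure(list(alpha = alpha, gamma = gamma, epsilon = epsilon,
                 lovasz_trigger = lovasz_trigger,
                 n_classes = as.integer(n_classes)),
            class = "loss_config")
}

.check_batch <- function(targets, probs) {
  if (!identical(dim(targets), dim(probs)))
    stop("targets and probs must have identical dimensions (pixels x classes)")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  invisible(TRUE)
}

#' Per-class soft dice score
#'
#' Aggregated soft dice per class over a batch:
#' `(2 * sum(y*p) + eps) / (sum(y^2) + sum(p^2) + eps)`. Equals 1 for a
#' perfect one-hot prediction as `eps -> 0` and is symmetric in `(y, p)`.
#'
#' @param targets One-hot target matrix, pixels x classes.
#' @param probs Predicted probability matrix, same shape, rows summing to 1.
#' @param epsilon Smoothing constant (> 0).
#' @return Numeric vector of per-class dice scores in \[0, 1\].
#' @export
soft_dice_term <- function(targets, probs, epsilon = 1) {
  .check_batch(targets, probs)
  num <- 2 * colSums(targets * probs) + epsilon
  den <- colSums(targets^2) + colSums(probs^2) + epsilon
  as.numeric(num / den)
}

#' Focal loss term
#'
#' `-(1/N) * sum_c sum_n alpha_c (1 - p)^gamma y log(p)` with per-class
#' weights `(1 - alpha)` for the background class and `alpha` for the lesion
#' class (the class-balance convention of the originating focal-loss
#' formulation). Probabilities are clipped to `[1e-7, 1 - 1e-7]` before the
#' logarithm. The modulating factor drives the contribution of confidently
#' correct pixels to zero.
#'
#' @inheritParams soft_dice_term
#' @param alpha Scalar lesion-class weight in \[0,1\], or a length-C vector of
#'   explicit per-class weights.
#' @param gamma Focusing parameter >= 0.
#' @return Nonnegative scalar.
#' @export
focal_term <- function(targets, probs, alpha = 0.25, gamma = 2) {
  .check_batch(targets, probs)
  C <- ncol(targets)
  w <- .focal_weights(alpha, C)
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  n <- nrow(targets)
  mod <- (1 - p)^gamma
  per_class <- colSums(targets * mod * log(p))
  -sum(w * per_class) / n
}

.focal_weights <- function(alpha, C) {
  if (length(alpha) == C) return(alpha)
  if (length(alpha) != 1) stop("alpha must be scalar or one weight per class")
  if (C == 2) c(1 - alpha, alpha) else rep(alpha, C)
}

#' Hybrid soft-dice + focal segmentation loss
#'
#' `mean_c(1 - dice_c) + focal`. The dice part is written as `1 - dice` so
#' the loss is nonnegative and minimized (at ~0, up to `epsilon` smoothing)
#' by a perfect prediction; its gradients are identical to the negated-dice
#' form.
#'
#' @inheritParams soft_dice_term
#' @param config A [loss_config()].
#' @return Scalar loss >= 0.
#' @export
hybrid_loss <- function(targets, probs, config = loss_config()) {
  .check_batch(targets, probs)
  d <- soft_dice_term(targets, probs, config$epsilon)
  mean(1 - d) + focal_term(targets, probs, config$alpha, config$gamma)
}

#' Gradient of the Jaccard-loss Lovasz extension
#'
#' Given ground-truth labels sorted by decreasing error, returns the vector of
#' discrete gradients of the Lovasz extension of `1 - IoU`.
#'
#' @param gt_sorted 0/1 vector of ground-truth labels in decreasing-error order.
#' @return Numeric vector of the same length.
#' @keywords internal
lovasz_grad <- function(gt_sorted) {
  n <- length(gt_sorted)
  gts <- sum(gt_sorted)
  intersection <- gts - cumsum(gt_sorted)
  union <- gts + cumsum(1 - gt_sorted)
  jaccard <- 1 - intersection / union
  if (n > 1) jaccard[2:n] <- jaccard[2:n] - jaccard[1:(n - 1)]
  jaccard
}

#' Lovasz-Softmax loss
#'
#' Convex surrogate for the Jaccard (IoU) loss. Per class, the per-pixel
#' errors `m = |y - p|` are sorted in decreasing order and dotted with the
#' discrete gradient of the Lovasz extension of the Jaccard loss; the result
#' is averaged over classes present (a class absent from both the target and
#' the hard prediction is skipped). For hard 0/1 predictions the per-class
#' value equals `1 - IoU` exactly.
#'
#' @inheritParams soft_dice_term
#' @return Scalar loss in \[0, 1\].
#' @export
lovasz_softmax <- function(targets, probs) {
  .check_batch(targets, probs)
  C <- ncol(targets)
  vals <- numeric(0)
  for (c in seq_len(C)) {
    y <- targets[, c]; p <- probs[, c]
    if (sum(y) == 0 && sum(p >= 0.5) == 0) next  # class absent everywhere
    m <- abs(y - p)
    ord <- order(m, decreasing = TRUE)
    vals <- c(vals, sum(m[ord] * lovasz_grad(y[ord])))
  }
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' Scheduled segmentation loss with latched Lovasz fine-tuning
#'
#' Returns the hybrid dice+focal loss, plus the Lovasz-Softmax term once the
#' running training loss has fallen below `config$lovasz_trigger`. The switch
#' is latched by the caller: pass `lovasz_active = TRUE` once triggered and
#' keep it on (see [update_lovasz_latch()]).
#'
#' @inheritParams hybrid_loss
#' @param current_train_loss The running training-loss value used to decide
#'   whether the Lovasz term switches on at this step.
#' @param lovasz_active Latched state from previous steps.
#' @return Scalar loss, with attribute `"lovasz_active"` giving the updated
#'   latch state.
#' @export
scheduled_loss <- function(targets, probs, config = loss_config(),
                           current_train_loss = Inf, lovasz_active = FALSE) {
  active <- update_lovasz_latch(lovasz_active, current_train_loss,
                                config$lovasz_trigger)
  val <- hybrid_loss(targets, probs, config)
  if (active) val <- val + lovasz_softmax(targets, probs)
  structure(val, lovasz_active = active)
}

#' Update the Lovasz latch state
#'
#' Once the training loss has dipped below the trigger the Lovasz term stays
#' on for all subsequent steps.
#'
#' @param active Current latch state.
#' @param current_train_loss Running training loss.
#' @param trigger Threshold from [loss_config()].
#' @return Logical latch state.
#' @export
update_lovasz_latch <- function(active, current_train_loss, trigger) {
  # <= so that trigger = +Inf means "active from step 0"
  isTRUE(active) || current_train_loss <= trigger
}

#' Phase-adaptive multi-task loss
#'
#' Routes per-head losses by the phase indicator `x`: `x = 0` (arterial
#' phase) selects only the APHE head loss, `x = 1` (portal-venous or delayed
#' phase) selects the washout and capsule head losses:
#' `L_all = (1 - x) * L_aphe + x * L_washout + x * L_capsule`.
#' Vectorized over samples; a batch total is the sum of per-sample values.
#'
#' @param l_aphe,l_washout,l_capsule Per-sample head losses (finite numerics).
#' @param x Phase indicator(s), each 0 or 1.
#' @return Scalar (or vector, if inputs are vectors and `reduce = "none"`)
#'   combined loss; default reduces by summation over samples.
#' @param reduce `"sum"` (default) or `"none"`.
#' @export
adaptive_multitask_loss <- function(l_aphe, l_washout, l_capsule, x,
                                    reduce = c("sum", "none")) {
  reduce <- match.arg(reduce)
  if (!all(x %in% c(0, 1))) stop("phase indicator x must be 0 or 1")
  stopifnot(all(is.finite(l_aphe)), all(is.finite(l_washout)),
            all(is.finite(l_capsule)))
  per <- (1 - x) * l_aphe + x * l_washout + x * l_capsule
  if (reduce == "sum") sum(per) else per
}

# ---- analytic gradients (internal, used by the trainers) --------------------

# Gradient of mean_c(1 - dice_c) w.r.t. probs.
.grad_dice <- function(targets, probs, epsilon) {
  C <- ncol(targets)
  num <- 2 * colSums(targets * probs) + epsilon
  den <- colSums(targets^2) + colSums(probs^2) + epsilon
  # dD_c/dp_ic = (2*y_ic*den - num*2*p_ic) / den^2 ; dloss/dp = -dD/dp / C
  g <- matrix(0, nrow(targets), C)
  for (c in seq_len(C)) {
    g[, c] <- -(2 * targets[, c] * den[c] - num[c] * 2 * probs[, c]) /
      (den[c]^2 * C)
  }
  g
}

# Gradient of the focal term w.r.t. probs (using clipped probabilities).
.grad_focal <- function(targets, probs, alpha, gamma) {
  C <- ncol(targets)
  w <- .focal_weights(alpha, C)
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  n <- nrow(targets)
  inner <- if (gamma == 0) 1 / p else
    -gamma * (1 - p)^(gamma - 1) * log(p) + (1 - p)^gamma / p
  g <- -targets * inner / n
  sweep(g, 2, w, `*`)
}

# Gradient of lovasz_softmax w.r.t. probs (sort order treated as fixed).
.grad_lovasz <- function(targets, probs) {
  C <- ncol(targets)
  g <- matrix(0, nrow(targets), C)
  n_present <- 0L
  for (c in seq_len(C)) {
    y <- targets[, c]; p <- probs[, c]
    if (sum(y) == 0 && sum(p >= 0.5) == 0) next
    n_present <- n_present + 1L
    m <- abs(y - p)
    ord <- order(m, decreasing = TRUE)
    gv <- lovasz_grad(y[ord])
    dm <- numeric(length(y)); dm[ord] <- gv
    g[, c] <- dm * ifelse(y == 1, -1, 1)
  }
  if (n_present > 0) g / n_present else g
}

# Combined loss value and gradient w.r.t. softmax logits for a 2-class batch.
# targets/probs: (pixels x 2); returns list(loss, dlogits). `groups` (one id
# per pixel) computes the dice and Lovasz terms per window and averages them,
# so one badly-predicted lesion is not drowned by well-predicted ones pooled
# in the same mini-batch; the focal term is per-pixel and needs no grouping.
.seg_loss_and_grad <- function(targets, logits, config, lovasz_active = FALSE,
                               groups = NULL) {
  z <- logits - do.call(pmax, lapply(asplit(logits, 2), as.numeric))
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  probs <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  probs <- probs / rowSums(probs)
  gidx <- if (is.null(groups)) list(seq_len(nrow(targets))) else
    split(seq_len(nrow(targets)), factor(groups, levels = unique(groups)))
  per_group <- vapply(gidx, function(ix) {
    tg <- targets[ix, , drop = FALSE]
    pp <- probs[ix, , drop = FALSE]
    v <- mean(1 - soft_dice_term(tg, pp, config$epsilon)) +
      focal_term(tg, pp, config$alpha, config$gamma)
    if (lovasz_active) v <- v + lovasz_softmax(tg, pp)
    v
  }, 0)
  loss <- mean(per_group)
  # Gradients use floored probabilities, but only on pixels whose TRUE
  # class has been suppressed below 1%. The softmax jacobian multiplies
  # every upstream derivative by p*(1-p); at saturation that factor kills
  # the dice term's restoring force on wrongly-suppressed regions (the
  # focal term's limit is only alpha/N per pixel), so a saturated minority
  # mode could never recover. Flooring only the wrongly-suppressed rows
  # restores that force without adding spurious pressure on confidently
  # correct pixels.
  pg <- probs
  suppressed <- rowSums(targets * (probs < 1e-2)) > 0
  if (any(suppressed)) {
    pf <- pmin(pmax(probs[suppressed, , drop = FALSE], 1e-2), 1 - 1e-2)
    pg[suppressed, ] <- pf / rowSums(pf)
  }
  dp <- .grad_focal(targets, pg, config$alpha, config$gamma)
  ngr <- length(gidx)
  for (ix in gidx) {
    tg <- targets[ix, , drop = FALSE]
    pgx <- pg[ix, , drop = FALSE]
    dgx <- .grad_dice(tg, pgx, config$epsilon) / ngr
    if (lovasz_active) dgx <- dgx + .grad_lovasz(tg, pgx) / ngr
    dp[ix, ] <- dp[ix, ] + dgx
  }
  # softmax jacobian: dz_c = p_c * (dp_c - sum_k p_k dp_k)
  s <- rowSums(pg * dp)
  dlogits <- pg * (dp - s)
  list(loss = loss, probs = probs, dlogits = dlogits,
       per_group = unname(per_group))
}
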
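# Attention-augmented nested encoder-decoder lesion segmentation on 2.5D
# windows. The network is a UNet++-style nested decoder over a residual
# encoder, with channel+spatial attention (CBAM) on each encoder residual
# block; it maps a 3-channel window to a per-pixel 2-class softmax and is
# trained with the scheduled hybrid dice+focal(+Lovasz) loss.

#' Segmentation model configuration
#'
#' @param n_down Encoder (= decoder) stages; the input size must be
#'   divisible by `2^n_down`.
#' @param base_width Channels at the first stage; stage i has
#'   `base_width * 2^i`.
#' @param attention Apply channel+spatial attention on each encoder residual
#'   block.
#' @param input_size `c(rows, cols)` of the window.
#' @param in_channels Input channels (3 for 2.5D windows).
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(n_down = 4L, base_width = 16L, attention = TRUE,
                       input_size = c(512L, 512L), in_channels = 3L) {
  stopifnot(n_down >= 1, base_width >= 4, length(input_size) == 2)
  div <- 2^n_down
  if (any(input_size %% div != 0))
    stop(sprintf("input size must be divisible by 2^n_down = %d", div))
  structure(list(n_down = as.integer(n_down),
                 base_width = as.integer(base_width),
                 attention = isTRUE(attention),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels)),
            class = "seg_config")
}

# ---- shared blocks ----------------------------------------------------------

.resblock_params <- function(params, prefix, cin, cout, attention) {
  params[[paste0(prefix, ".c1.W")]] <- he_init(NULL, 9 * cin, cout)
  params[[paste0(prefix, ".c1.b")]] <- numeric(cout)
  params[[paste0(prefix, ".c2.W")]] <- he_init(NULL, 9 * cout, cout)
  params[[paste0(prefix, ".c2.b")]] <- numeric(cout)
  if (cin != cout) {
    params[[paste0(prefix, ".sk.W")]] <- he_init(NULL, cin, cout)
    params[[paste0(prefix, ".sk.b")]] <- numeric(cout)
  }
  if (attention) {
    cr <- max(2L, cout %/% 4L)
    params[[paste0(prefix, ".ca.f1.W")]] <- he_init(NULL, cout, cr)
    params[[paste0(prefix, ".ca.f1.b")]] <- numeric(cr)
    params[[paste0(prefix, ".ca.f2.W")]] <- he_init(NULL, cr, cout)
    params[[paste0(prefix, ".ca.f2.b")]] <- numeric(cout)
    params[[paste0(prefix, ".sa.W")]] <- he_init(NULL, 49 * 2, 1)
    params[[paste0(prefix, ".sa.b")]] <- numeric(1)
  }
  params
}

.cbam_fwd <- function(tp, x, prefix) {
  a <- op_gap(tp, x); m <- op_gmp(tp, x)
  f1w <- paste0(prefix, ".ca.f1.W"); f1b <- paste0(prefix, ".ca.f1.b")
  f2w <- paste0(prefix, ".ca.f2.W"); f2b <- paste0(prefix, ".ca.f2.b")
  h1 <- op_relu(tp, op_dense(tp, a, f1w, f1b))
  h2 <- op_relu(tp, op_dense(tp, m, f1w, f1b))
  s <- op_sigmoid(tp, op_add(tp, op_dense(tp, h1, f2w, f2b),
                             op_dense(tp, h2, f2w, f2b)))
  x2 <- op_scale_chan(tp, x, s)
  sm <- op_concat(tp, list(op_chan_mean(tp, x2), op_chan_max(tp, x2)))
  m2 <- op_sigmoid(tp, op_conv(tp, sm, paste0(prefix, ".sa.W"),
                               paste0(prefix, ".sa.b"), 7))
  op_scale_pix(tp, x2, m2)
}

.resblock_fwd <- function(tp, x, prefix, cin, cout, attention) {
  y1 <- op_relu(tp, op_conv(tp, x, paste0(prefix, ".c1.W"),
                            paste0(prefix, ".c1.b"), 3))
  y2 <- op_conv(tp, y1, paste0(prefix, ".c2.W"), paste0(prefix, ".c2.b"), 3)
  skip <- if (cin == cout) x else
    op_conv(tp, x, paste0(prefix, ".sk.W"), paste0(prefix, ".sk.b"), 1)
  out <- op_relu(tp, op_add(tp, y2, skip))
  if (attention) out <- .cbam_fwd(tp, out, prefix)
  out
}

# ---- model ------------------------------------------------------------------

#' Build the segmentation model
#'
#' Residual encoder with optional attention; nested decoder in which node
#' (i, j) convolves the concatenation of all same-level predecessors with the
#' upsampled node one level deeper; 1x1 output convolution to 2-class logits
#' (final nested output only).
#'
#' @param config A [seg_config()].
#' @param seed Weight-initialization seed.
#' @return An object of class `lirads_seg` (untrained).
#' @export
build_seg_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "seg_config"))
  set.seed(seed)
  L <- config$n_down
  wd <- config$base_width * 2^(0:L)
  params <- list()
  for (i in 0:L) {
    cin <- if (i == 0) config$in_channels else wd[i]
    params <- .resblock_params(params, sprintf("enc%d", i), cin, wd[i + 1],
                               config$attention)
  }
  for (j in 1:L) for (i in 0:(L - j)) {
    cin <- j * wd[i + 1] + wd[i + 2]
    params[[sprintf("dec%d_%d.W", i, j)]] <- he_init(NULL, 9 * cin, wd[i + 1])
    params[[sprintf("dec%d_%d.b", i, j)]] <- numeric(wd[i + 1])
  }
  # zero-initialized output head: training starts from p = 0.5 everywhere,
  # keeping the first steps out of the softmax saturation region
  params[["out.W"]] <- matrix(0, wd[1], 2)
  params[["out.b"]] <- numeric(2)
  structure(list(params = params, config = config, log = NULL,
                 trained = FALSE, seed = seed),
            class = "lirads_seg")
}

.seg_forward <- function(params, config, x_fmap) {
  tp <- nn_tape(params)
  L <- config$n_down
  wd <- config$base_width * 2^(0:L)
  X <- vector("list", L + 1)
  for (i in 0:L) X[[i + 1]] <- vector("list", L + 1 - i)
  inp <- t_in(tp, x_fmap)
  X[[1]][[1]] <- .resblock_fwd(tp, inp, "enc0", config$in_channels, wd[1],
                               config$attention)
  for (i in 1:L) {
    X[[i + 1]][[1]] <- .resblock_fwd(tp, op_maxpool(tp, X[[i]][[1]]),
                                     sprintf("enc%d", i), wd[i], wd[i + 1],
                                     config$attention)
  }
  for (j in 1:L) for (i in 0:(L - j)) {
    ins <- c(X[[i + 1]][seq_len(j)], list(op_upsample(tp, X[[i + 2]][[j]])))
    cc <- op_concat(tp, ins)
    X[[i + 1]][[j + 1]] <- op_relu(tp, op_conv(tp, cc,
                                               sprintf("dec%d_%d.W", i, j),
                                               sprintf("dec%d_%d.b", i, j), 3))
  }
  logits <- op_conv(tp, X[[1]][[L + 1]], "out.W", "out.b", 1)
  list(tape = tp, logits = logits)
}

.window_to_fmap <- function(win) {
  d <- dim(win)
  .as_fmap(matrix(as.vector(win), d[1] * d[2], d[3]), d[1], d[2])
}

# stack windows into one batched feature map (B*HW x channels)
.windows_to_batch <- function(wins) {
  d <- dim(wins[[1]])
  m <- do.call(rbind, lapply(wins, function(w)
    matrix(as.vector(w), d[1] * d[2], d[3])))
  .as_fmap(m, d[1], d[2], length(wins))
}

#' Number of trainable parameters
#'
#' @param model A `lirads_seg` or `lirads_char` model.
#' @return Integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 0L))

#' Predict the foreground probability map of one window
#'
#' @param model A `lirads_seg` model.
#' @param window `rows x cols x 3` array (preprocessed).
#' @return Matrix of foreground probabilities in \[0, 1\].
#' @export
seg_predict_window <- function(model, window) {
  fw <- .seg_forward(model$params, model$config, .window_to_fmap(window))
  z <- fw$tape$vals[[fw$logits]]
  z <- z - do.call(pmax, lapply(asplit(z, 2), as.numeric))
  ez <- exp(z)
  p <- ez[, 2] / rowSums(ez)
  matrix(p, dim(window)[1], dim(window)[2])
}

#' Fit the segmentation network on labeled 2.5D windows
#'
#' Adam steps on mini-batches under the scheduled hybrid loss; the Lovasz
#' term latches on once the smoothed training loss drops below the trigger.
#'
#' @param windows List of `rows x cols x 3` arrays.
#' @param labels List of binary center-slice masks (matrices).
#' @param config A [seg_config()].
#' @param loss_cfg A [loss_config()].
#' @param steps Number of optimization steps.
#' @param batch_size Windows per step.
#' @param lr Adam learning rate.
#' @param finetune_lr_factor Learning-rate multiplier applied once the
#'   Lovasz term latches on (the fine-tuning stage).
#' @param seed Seed for init and batch sampling.
#' @param model Optional pre-built/pre-trained `lirads_seg` to continue from.
#' @param balance Oversample lesion-containing windows to this fraction of
#'   each batch (`NULL` to disable).
#' @param augment_prob Probability that a sampled window is replaced by a
#'   random rotation/shift/flip of itself (applied jointly to all three
#'   channels and the label); counters memorization of the few lesions.
#' @param hard_mining Sample lesion-containing windows proportionally to a
#'   running estimate of their per-window loss, so lesions the net currently
#'   misses keep receiving gradient pressure instead of being extinguished
#'   by the well-learned majority (window-level analogue of the focal
#'   principle).
#' @return A trained `lirads_seg`; `$log` holds the per-step scheduled loss.
#' @export
fit_segmentation <- function(windows, labels, config, loss_cfg = loss_config(),
                             steps = 200L, batch_size = 8L, lr = 1e-3,
                             finetune_lr_factor = 0.2, seed = 1L,
                             model = NULL, balance = 0.5,
                             augment_prob = 0.5, hard_mining = TRUE) {
  if (length(windows) == 0) stop("empty training set")
  stopifnot(length(windows) == length(labels))
  if (is.null(model)) model <- build_seg_model(config, seed = seed)
  params <- model$params
  state <- adam_init(params)
  set.seed(derive_seed(seed, 1L, salt = 5L))
  has_fg <- vapply(labels, function(l) any(l != 0), TRUE)
  wloss <- rep(1, length(windows))   # pessimistic prior per-window loss
  loss_log <- numeric(steps)
  lovasz_log <- logical(steps)
  ema <- Inf
  lovasz_on <- FALSE
  n <- length(windows)
  for (step in seq_len(steps)) {
    bs <- min(batch_size, n)
    if (!is.null(balance) && any(has_fg) && any(!has_fg)) {
      nfg <- max(1L, round(bs * balance))
      fg_ids <- which(has_fg)
      fg_prob <- if (hard_mining) wloss[fg_ids] + 0.1 else NULL
      idx <- c(sample(fg_ids, min(nfg, length(fg_ids)), replace = TRUE,
                      prob = fg_prob),
               sample(which(!has_fg), bs - min(nfg, length(fg_ids)),
                      replace = TRUE))
    } else idx <- sample.int(n, bs, replace = bs > n)
    gsum <- NULL
    batch_loss <- 0
    lovasz_on <- update_lovasz_latch(lovasz_on, ema, loss_cfg$lovasz_trigger)
    aug_draw <- stats::runif(length(idx))
    aug_seed <- sample.int(2^30, length(idx))
    wins <- vector("list", length(idx))
    labs <- vector("list", length(idx))
    for (bi in seq_along(idx)) {
      i <- idx[bi]
      win <- windows[[i]]
      lab <- labels[[i]]
      if (aug_draw[bi] < augment_prob) {
        for (ch in 1:3) {
          a <- augment(win[, , ch], lab, seed = aug_seed[bi])
          win[, , ch] <- a$image
          if (ch == 3) lab <- a$label
        }
      }
      wins[[bi]] <- win
      labs[[bi]] <- lab
    }
    fw <- .seg_forward(params, config, .windows_to_batch(wins))
    z <- fw$tape$vals[[fw$logits]]
    v <- unlist(lapply(labs, as.vector))
    targets <- cbind(1 - v, v)
    hw <- nrow(targets) %/% length(wins)
    lg <- .seg_loss_and_grad(targets, z, loss_cfg, lovasz_active = lovasz_on,
                             groups = rep(seq_along(wins), each = hw))
    batch_loss <- lg$loss
    wloss[idx] <- 0.5 * wloss[idx] + 0.5 * lg$per_group
    gsum <- nn_backward(fw$tape, fw$logits, lg$dlogits)
    upd <- adam_step(params, gsum, state,
                     lr = if (lovasz_on) lr * finetune_lr_factor else lr)
    params <- upd$params; state <- upd$state
    loss_log[step] <- batch_loss
    lovasz_log[step] <- lovasz_on
    ema <- if (!is.finite(ema)) batch_loss else 0.9 * ema + 0.1 * batch_loss
  }
  model$params <- params
  model$trained <- TRUE
  model$log <- data.frame(step = seq_len(steps), loss = loss_log,
                          lovasz_active = lovasz_log)
  model$lovasz_on <- lovasz_on
  model
}

#' Patient-wise cross-validated segmentation training
#'
#' For each fold iteration, trains on the complement and predicts the held
#' out patients, so every patient is tested exactly once.
#'
#' @param dataset List with elements `windows`, `labels`, `patient` (window
#'   provenance) — see [build_window_dataset()].
#' @param fold_split A [split_folds()] result over the dataset's patients.
#' @param config,loss_cfg,steps,batch_size,lr,seed As in
#'   [fit_segmentation()].
#' @return List with `models` (per fold) and `test_patients` (per fold).
#' @export
train_segmentation <- function(dataset, fold_split, config,
                               loss_cfg = loss_config(), steps = 200L,
                               batch_size = 8L, lr = 1e-3, seed = 1L) {
  out <- list(models = list(), test_patients = list())
  for (k in seq_len(fold_split$n_folds)) {
    fp <- fold_patients(fold_split, k)
    tr <- dataset$patient %in% fp$train
    if (!any(tr)) stop("empty training fold ", k)
    out$models[[k]] <- fit_segmentation(dataset$windows[tr],
                                        dataset$labels[tr], config, loss_cfg,
                                        steps = steps,
                                        batch_size = batch_size, lr = lr,
                                        seed = derive_seed(seed, k))
    out$test_patients[[k]] <- fp$test
  }
  out
}

#' Build a 2.5D window training set from studies
#'
#' Preprocesses the chosen phase of each study (normalization +
#' standardization) and emits all interior windows with their center-slice
#' labels and patient provenance.
#'
#' @param studies List of study objects ([generate_study()]).
#' @param phase Phase used for segmentation (delayed by default: the phase
#'   the pipeline's ROI extraction runs on).
#' @return `list(windows, labels, patient)`.
#' @export
build_window_dataset <- function(studies, phase = "delayed") {
  windows <- list(); labels <- list(); patient <- integer(0)
  for (st in studies) {
    vol <- preprocess_volume(st$phases[[phase]],
                             name = paste0("patient", st$patient_id))
    ws <- make_windows(vol, st$mask)
    for (w in ws) {
      windows[[length(windows) + 1]] <- w$slices
      labels[[length(labels) + 1]] <- w$label_slice
    }
    patient <- c(patient, rep(st$patient_id, length(ws)))
  }
  list(windows = windows, labels = labels, patient = patient)
}

#' Predict per-slice probability maps for a whole volume
#'
#' One probability map per slice; boundary slices (which have no full 2.5D
#' window) receive the nearest interior window's prediction.
#'
#' @param model A trained `lirads_seg`.
#' @param volume Preprocessed `rows x cols x slices` array.
#' @return Array of foreground probabilities, same shape as `volume`.
#' @export
predict_volume <- function(model, volume) {
  d <- dim(volume)
  if (length(d) != 3 || d[3] < 3) stop("volume must have at least 3 slices")
  S <- d[3]
  probs <- array(0, d)
  interior <- 2:(S - 1)
  hw <- d[1] * d[2]
  for (chunk in split(interior, ceiling(seq_along(interior) / 8))) {
    wins <- lapply(chunk, function(s) volume[, , (s - 1):(s + 1),
                                             drop = FALSE])
    fw <- .seg_forward(model$params, model$config, .windows_to_batch(wins))
    z <- fw$tape$vals[[fw$logits]]
    z <- z - do.call(pmax, lapply(asplit(z, 2), as.numeric))
    ez <- exp(z)
    p <- ez[, 2] / rowSums(ez)
    for (bi in seq_along(chunk))
      probs[, , chunk[bi]] <- matrix(p[((bi - 1) * hw + 1):(bi * hw)],
                                     d[1], d[2])
  }
  probs[, , 1] <- probs[, , 2]
  probs[, , S] <- probs[, , S - 1]
  probs
}

#' Threshold a probability map into a binary mask
#'
#' @param prob_map Probability array/matrix in \[0, 1\].
#' @param threshold Threshold in (0, 1); a pixel is foreground iff its
#'   probability is >= threshold.
#' @return Integer 0/1 array with attribute `threshold_used`.
#' @export
binarize <- function(prob_map, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  m <- (prob_map >= threshold) + 0L
  dim(m) <- dim(prob_map)
  attr(m, "threshold_used") <- threshold
  m
}

#' Connected lesion components under face connectivity
#'
#' Labels connected foreground components (4-connectivity in 2-D,
#' 6-connectivity in 3-D) and removes components smaller than `min_voxels`.
#'
#' @param mask Binary matrix or 3-D array.
#' @param min_voxels Minimum component size kept (set 1 to keep everything).
#' @return `list(labels, ids, sizes)`: integer label array (0 = background),
#'   kept component ids, and their voxel counts.
#' @export
extract_components <- function(mask, min_voxels = 5L) {
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or array")
  if (length(d) == 2) d <- c(d, 1L)
  h <- d[1]; w <- d[2]; s <- d[3]
  lab <- integer(h * w * s)
  fgv <- as.vector(mask != 0)
  neighbors <- function(v) {
    r <- (v - 1L) %% h + 1L
    cc <- ((v - 1L) %/% h) %% w + 1L
    z <- (v - 1L) %/% (h * w) + 1L
    out <- c(v[r > 1] - 1L, v[r < h] + 1L,
             v[cc > 1] - h, v[cc < w] + h,
             v[z > 1] - h * w, v[z < s] + h * w)
    out
  }
  nextid <- 0L
  todo <- which(fgv)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nextid <- nextid + 1L
    lab[seed] <- nextid
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(neighbors(frontier))
      nb <- nb[fgv[nb] & lab[nb] == 0L]
      lab[nb] <- nextid
      frontier <- nb
    }
  }
  sizes <- tabulate(lab, nbins = nextid)
  keep <- which(sizes >= min_voxels)
  relab <- integer(nextid)
  relab[keep] <- seq_along(keep)
  lab[lab != 0L] <- relab[lab[lab != 0L]]
  out <- array(lab, dim(mask))
  list(labels = out, ids = seq_along(keep), sizes = sizes[keep])
}

#' @export
print.lirads_seg <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Nested encoder-decoder segmentation model\n",
                     "  stages: %d down / %d up, base width %d, ",
                     "attention: %s\n  input: %d x %d x %d, parameters: %d\n",
                     "  trained: %s\n"),
              cfg$n_down, cfg$n_down, cfg$base_width,
              ifelse(cfg$attention, "on", "off"),
              cfg$input_size[1], cfg$input_size[2], cfg$in_channels,
              n_parameters(x), ifelse(x$trained, "yes", "no")))
  if (!is.null(x$log))
    cat(sprintf("  final training loss: %.4f (%d steps)\n",
                utils::tail(x$log$loss, 1), nrow(x$log)))
  invisible(x)
}
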
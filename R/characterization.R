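# Per-lesion feature characterization: a shared convolutional backbone with
# three independent sigmoid heads (APHE, washout, capsule), trained with the
# phase-routed adaptive loss so arterial crops drive only the APHE head and
# portal-venous/delayed crops drive only the washout and capsule heads.

#' Characterizer model configuration
#'
#' @param backbone `"vgg"` (plain conv blocks) or `"resnet"` (residual
#'   blocks); both reduced-depth variants suitable for CPU-scale training.
#' @param widths Channel widths of the successive conv blocks.
#' @param fc Width of the fully connected layer before the heads.
#' @param input_size Side length the (square) crop is downscaled to before
#'   entering the network.
#' @return An object of class `char_config`.
#' @export
char_config <- function(backbone = c("vgg", "resnet"), widths = c(8L, 16L),
                        fc = 16L, input_size = 32L) {
  backbone <- match.arg(backbone)
  stopifnot(length(widths) >= 1, all(widths >= 2), fc >= 2,
            input_size %% 2^length(widths) == 0)
  structure(list(backbone = backbone, widths = as.integer(widths),
                 fc = as.integer(fc), input_size = as.integer(input_size)),
            class = "char_config")
}

#' Select the representative slice of a lesion
#'
#' Returns the index of the slice with the largest segmented-lesion area
#' (ties broken toward the lowest index).
#'
#' @param stack A `rows x cols x slices` binary mask or probability stack
#'   (probabilities are hardened at 0.5).
#' @return Integer slice index.
#' @export
select_representative_slice <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3) stop("stack must be a 3-D array")
  areas <- vapply(seq_len(d[3]), function(s) sum(stack[, , s] >= 0.5), 0)
  if (all(areas == 0)) stop("no lesion detected: no foreground in any slice")
  which.max(areas)
}

#' Crop a lesion region and resize to the classifier input
#'
#' Takes the bounding box of the component on the chosen slice, squares it,
#' grows it by `margin` (so capsule rim context survives), clamps to the
#' image, resizes to `out_size` x `out_size` (bilinear) and standardizes.
#' The crop is of the raw slice, not mask-multiplied.
#'
#' @param slice_img Numeric matrix (one axial slice).
#' @param component Binary matrix marking the lesion on this slice, or an
#'   `n x 2` matrix of (row, col) pixel coordinates.
#' @param margin Fractional margin added around the squared bounding box.
#' @param out_size Output side length (224 by convention).
#' @return `out_size x out_size` standardized matrix.
#' @export
crop_resize <- function(slice_img, component, margin = 0.25, out_size = 224L) {
  if (is.matrix(component) && ncol(component) == 2 &&
      !all(component %in% c(0, 1))) {
    coords <- component
  } else {
    coords <- which(component != 0, arr.ind = TRUE)
  }
  if (nrow(coords) == 0) stop("empty component: nothing to crop")
  r0 <- min(coords[, 1]); r1 <- max(coords[, 1])
  c0 <- min(coords[, 2]); c1 <- max(coords[, 2])
  side <- max(r1 - r0 + 1, c1 - c0 + 1, 4)   # degenerate boxes padded
  side <- ceiling(side * (1 + margin))
  rc <- (r0 + r1) / 2; cc <- (c0 + c1) / 2
  half <- side / 2
  rr <- round(c(rc - half, rc + half)); rr <- pmax(1, pmin(nrow(slice_img), rr))
  cl <- round(c(cc - half, cc + half)); cl <- pmax(1, pmin(ncol(slice_img), cl))
  crop <- slice_img[rr[1]:rr[2], cl[1]:cl[2], drop = FALSE]
  out <- as.matrix(EBImage::resize(crop, out_size, out_size))
  dim(out) <- c(out_size, out_size)
  mu <- mean(out)
  sdv <- sqrt(mean((out - mu)^2))
  if (sdv == 0) out - mu else (out - mu) / sdv
}

#' Build the feature characterizer
#'
#' Shared convolutional backbone feeding three parameter-disjoint sigmoid
#' heads for APHE, washout and capsule presence.
#'
#' @param config A [char_config()].
#' @param seed Weight-initialization seed.
#' @return An object of class `lirads_char` (untrained).
#' @export
build_characterizer <- function(config = char_config(), seed = 1L) {
  stopifnot(inherits(config, "char_config"))
  set.seed(seed)
  params <- list()
  cin <- 1L
  for (b in seq_along(config$widths)) {
    cout <- config$widths[b]
    if (config$backbone == "vgg") {
      params[[sprintf("blk%d.W", b)]] <- he_init(NULL, 9 * cin, cout)
      params[[sprintf("blk%d.b", b)]] <- numeric(cout)
    } else {
      params <- .resblock_params(params, sprintf("blk%d", b), cin, cout,
                                 attention = FALSE)
    }
    cin <- cout
  }
  params[["fc.W"]] <- he_init(NULL, cin, config$fc)
  params[["fc.b"]] <- numeric(config$fc)
  for (h in c("aphe", "washout", "capsule")) {
    params[[sprintf("head.%s.W", h)]] <- he_init(NULL, config$fc, 1)
    params[[sprintf("head.%s.b", h)]] <- numeric(1)
  }
  structure(list(params = params, config = config, trained = FALSE,
                 seed = seed, log = NULL),
            class = "lirads_char")
}

.char_forward <- function(params, config, x_fmap) {
  tp <- nn_tape(params)
  x <- t_in(tp, x_fmap)
  cin <- 1L
  for (b in seq_along(config$widths)) {
    cout <- config$widths[b]
    if (config$backbone == "vgg") {
      x <- op_relu(tp, op_conv(tp, x, sprintf("blk%d.W", b),
                               sprintf("blk%d.b", b), 3))
    } else {
      x <- .resblock_fwd(tp, x, sprintf("blk%d", b), cin, cout,
                         attention = FALSE)
    }
    x <- op_maxpool(tp, x)
    cin <- cout
  }
  g <- op_gap(tp, x)
  f <- op_relu(tp, op_dense(tp, g, "fc.W", "fc.b"))
  heads <- lapply(c("aphe", "washout", "capsule"), function(h)
    op_dense(tp, f, sprintf("head.%s.W", h), sprintf("head.%s.b", h)))
  names(heads) <- c("aphe", "washout", "capsule")
  list(tape = tp, heads = heads)
}

.crop_to_input <- function(crop, input_size) {
  if (!all(dim(crop) == input_size)) {
    crop <- as.matrix(EBImage::resize(crop, input_size, input_size))
    dim(crop) <- c(input_size, input_size)
  }
  .as_fmap(matrix(as.vector(crop), ncol = 1), input_size, input_size)
}

#' Head probabilities for one crop
#'
#' @param model A `lirads_char`.
#' @param crop Square matrix (any size; downscaled to the model input).
#' @return Named numeric vector `c(aphe, washout, capsule)` in \[0, 1\].
#' @export
char_predict_crop <- function(model, crop) {
  fw <- .char_forward(model$params, model$config,
                      .crop_to_input(crop, model$config$input_size))
  z <- vapply(fw$heads, function(id) as.numeric(fw$tape$vals[[id]]), 0)
  p <- 1 / (1 + exp(-z))
  names(p) <- names(fw$heads)
  p
}

#' Train the multi-task characterizer with phase-routed loss
#'
#' Per-sample head losses are binary cross-entropy on the sigmoid heads,
#' combined by the adaptive loss: arterial samples (`x = 0`) contribute only
#' the APHE term, portal-venous/delayed samples (`x = 1`) only the washout
#' and capsule terms, so a step on arterial-only batches leaves the washout
#' and capsule heads bit-identical while the shared backbone learns from all
#' samples. With `adaptive = FALSE` every head is trained on every sample
#' (the ablation baseline), using whatever labels are attached.
#'
#' @param crops List of square matrices.
#' @param labels Data frame with logical/0-1 columns `aphe`, `washout`,
#'   `capsule` (NA = no label attached to this crop).
#' @param x Integer vector of phase indicators (0 = arterial, 1 =
#'   portal-venous/delayed).
#' @param config A [char_config()].
#' @param adaptive Use the phase-routed loss (TRUE) or train all heads on
#'   all samples (FALSE).
#' @param steps,batch_size,lr,seed Optimization settings.
#' @param model Optional `lirads_char` to continue training.
#' @return A trained `lirads_char` with a `$log` of per-step losses.
#' @export
fit_characterizer <- function(crops, labels, x, config = char_config(),
                              adaptive = TRUE, steps = 150L, batch_size = 8L,
                              lr = 1e-3, seed = 1L, model = NULL) {
  n <- length(crops)
  stopifnot(n >= 1, nrow(labels) == n, length(x) == n)
  if (!all(x %in% c(0, 1))) stop("phase indicator x must be 0 or 1")
  if (adaptive) {
    bad_art <- x == 0 & (!is.na(labels$washout) | !is.na(labels$capsule))
    bad_late <- x == 1 & !is.na(labels$aphe)
    if (any(bad_art))
      stop("washout/capsule label attached to an arterial crop (sample ",
           which(bad_art)[1], ")")
    if (any(bad_late))
      stop("APHE label attached to a portal-venous/delayed crop (sample ",
           which(bad_late)[1], ")")
    if (any(x == 0 & is.na(labels$aphe)))
      stop("arterial crop without APHE label")
  }
  if (is.null(model)) model <- build_characterizer(config, seed = seed)
  params <- model$params
  state <- adam_init(params)
  set.seed(derive_seed(seed, 2L, salt = 11L))
  inputs <- lapply(crops, .crop_to_input, input_size = config$input_size)
  loss_log <- numeric(steps)
  isz <- config$input_size
  for (step in seq_len(steps)) {
    idx <- sample.int(n, min(batch_size, n), replace = batch_size > n)
    B <- length(idx)
    xb <- .as_fmap(do.call(rbind, inputs[idx]), isz, isz, B)
    fw <- .char_forward(params, config, xb)
    z <- vapply(fw$heads, function(id) as.vector(fw$tape$vals[[id]]),
                numeric(B))
    z <- matrix(z, B, 3)
    p <- 1 / (1 + exp(-z))
    w <- if (adaptive) cbind(1 - x[idx], x[idx], x[idx]) else
      matrix(1, B, 3)
    y <- cbind(labels$aphe[idx], labels$washout[idx], labels$capsule[idx])
    y <- matrix(as.numeric(y), B, 3)
    w[is.na(y)] <- 0
    y[is.na(y)] <- 0
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    bce <- -(y * log(pc) + (1 - y) * log(1 - pc))
    total <- sum(w * bce) / B
    douts <- lapply(1:3, function(h)
      matrix(w[, h] * (p[, h] - y[, h]) / B, B, 1))
    gsum <- nn_backward(fw$tape, unname(fw$heads), douts)
    upd <- adam_step(params, gsum, state, lr = lr)
    params <- upd$params; state <- upd$state
    loss_log[step] <- total
  }
  model$params <- params
  model$trained <- TRUE
  model$adaptive <- adaptive
  model$log <- data.frame(step = seq_len(steps), loss = loss_log)
  model
}

#' Fuse per-phase crops into a lesion feature profile
#'
#' APHE probability comes from the arterial crop(s); washout and capsule
#' probabilities are the maximum of the head outputs over the portal-venous
#' and delayed crops ("present in either"). Boolean calls use
#' `p >= call_threshold`. Invariant to the order of PV/delayed crops.
#'
#' @param model A trained `lirads_char`.
#' @param crops Named list of square matrices; names are phases
#'   (`arterial`, `portal_venous`, `delayed`), repeated names allowed.
#' @param call_threshold Probability threshold for the Boolean calls.
#' @return `list(p_aphe, p_washout, p_capsule, B1, B2, B3)`.
#' @export
predict_features <- function(model, crops, call_threshold = 0.5) {
  phases <- names(crops)
  if (is.null(phases)) stop("crops must be a named list (names = phases)")
  art <- which(phases == "arterial")
  late <- which(phases %in% c("portal_venous", "delayed"))
  if (length(art) == 0) stop("missing phase: arterial")
  if (length(late) == 0) stop("missing phase: portal_venous/delayed")
  pa <- vapply(art, function(i) char_predict_crop(model, crops[[i]])["aphe"], 0)
  pl <- vapply(late, function(i) {
    pr <- char_predict_crop(model, crops[[i]])
    c(pr["washout"], pr["capsule"])
  }, numeric(2))
  p_aphe <- max(pa)
  p_washout <- max(pl[1, ])
  p_capsule <- max(pl[2, ])
  list(p_aphe = p_aphe, p_washout = p_washout, p_capsule = p_capsule,
       B1 = p_aphe >= call_threshold,
       B2 = p_washout >= call_threshold,
       B3 = p_capsule >= call_threshold)
}

#' @export
print.lirads_char <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Shared-backbone feature characterizer (%s)\n",
                     "  blocks: %s, fc %d, input %d x %d, parameters: %d\n",
                     "  trained: %s%s\n"),
              cfg$backbone, paste(cfg$widths, collapse = "-"), cfg$fc,
              cfg$input_size, cfg$input_size, n_parameters(x),
              ifelse(x$trained, "yes", "no"),
              if (isTRUE(x$trained))
                sprintf(" (%s loss)",
                        ifelse(isTRUE(x$adaptive), "adaptive", "uniform"))
              else ""))
  invisible(x)
}
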
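# Intensity normalization, standardization, 2.5D windowing, augmentation and
# patient-level k-fold splitting.

#' Piecewise intensity normalization
#'
#' Maps raw scanner intensities `o` to `[0, 1]`: values below `floor` (80 by
#' default; such pixels are background) become 0, values above the volume's
#' `percentile` threshold (99th by default, robust against the few very
#' bright pixels typical of MR) become 1, and the range in between is scaled
#' linearly by `(o - floor) / (P - floor)`.
#'
#' @param volume Numeric array (any dimensionality) of raw intensities.
#' @param floor Lower cutoff in scanner units.
#' @param percentile Upper-threshold percentile as a fraction (0.99 gives the
#'   99th percentile, computed over the whole volume).
#' @param name Label used in error messages.
#' @return Array of the same shape with values in `[0, 1]`; attributes
#'   `p99` (the threshold used) and `floor`.
#' @export
normalize_intensity <- function(volume, floor = 80, percentile = 0.99,
                                name = "volume") {
  if (length(volume) == 0) stop("empty volume: ", name)
  if (any(!is.finite(volume))) stop("non-finite intensities in ", name)
  p99 <- as.numeric(stats::quantile(volume, percentile, names = FALSE))
  if (p99 <= floor)
    stop(sprintf("%s: percentile threshold (%.3f) does not exceed floor (%g)",
                 name, p99, floor))
  out <- (volume - floor) / (p99 - floor)
  out[volume < floor] <- 0
  out[volume > p99] <- 1
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- dim(volume)
  attr(out, "p99") <- p99
  attr(out, "floor") <- floor
  out
}

#' Per-volume standardization
#'
#' Subtracts the mean and divides by the (population) standard deviation so
#' the result has mean 0 and standard deviation 1. Idempotent to numerical
#' tolerance.
#'
#' @param volume Numeric array.
#' @param name Label used in error messages.
#' @return Standardized array of the same shape.
#' @export
standardize <- function(volume, name = "volume") {
  v <- as.vector(volume)
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) stop("zero variance, cannot standardize: ", name)
  out <- (volume - mu) / sdv
  dim(out) <- dim(volume)
  out
}

#' Build 2.5D windows from a volume
#'
#' Stacks each triplet of neighboring axial slices as a 3-channel image whose
#' label is the center slice's mask; an S-slice volume yields S - 2 windows
#' (strictly interior centers, no padding).
#'
#' @param volume Array `rows x cols x slices`.
#' @param mask Binary array on the same grid (optional).
#' @return List of windows, each `list(slices = rows x cols x 3 array,
#'   center_index, label_slice)`, ordered by center index.
#' @export
make_windows <- function(volume, mask = NULL) {
  d <- dim(volume)
  if (length(d) != 3) stop("volume must be a 3-D array")
  S <- d[3]
  if (S < 3) stop("volume must have at least 3 slices (has ", S, ")")
  if (!is.null(mask) && !identical(dim(mask), d))
    stop("mask must be on the same grid as the volume")
  lapply(2:(S - 1), function(s) {
    list(slices = volume[, , (s - 1):(s + 1), drop = FALSE],
         center_index = s,
         label_slice = if (is.null(mask)) NULL else mask[, , s])
  })
}

#' Random spatial augmentation of an image/label pair
#'
#' Applies one random rotation (within `max_rotation` degrees), shift (within
#' `max_shift` of the side length per axis) and horizontal/vertical flips
#' (each with probability `flip_prob`) identically to the image and its
#' label. The image is interpolated bilinearly, the label with nearest
#' neighbor; both are zero-padded back to the original size.
#'
#' @param image Numeric matrix.
#' @param label Binary matrix on the same grid.
#' @param seed Integer seed making the transform reproducible.
#' @param max_rotation Rotation bound in degrees.
#' @param max_shift Shift bound as a fraction of the side length.
#' @param flip_prob Per-axis flip probability.
#' @return `list(image, label)` with unchanged shapes.
#' @export
augment <- function(image, label, seed, max_rotation = 15, max_shift = 0.10,
                    flip_prob = 0.5) {
  if (!identical(dim(image), dim(label)))
    stop("image and label must share a grid")
  set.seed(seed)
  angle <- stats::runif(1, -max_rotation, max_rotation)
  shift <- round(stats::runif(2, -max_shift, max_shift) * dim(image))
  flips <- stats::runif(2) < flip_prob
  tf <- function(x, filter) {
    if (flips[1]) x <- EBImage::flip(x)
    if (flips[2]) x <- EBImage::flop(x)
    x <- EBImage::rotate(x, angle, filter = filter, output.dim = dim(x),
                         bg.col = 0)
    x <- EBImage::translate(x, shift, filter = filter, bg.col = 0)
    m <- as.matrix(x)
    dim(m) <- dim(image)
    m
  }
  out_label <- tf(label, "none")
  out_label[out_label >= 0.5] <- 1; out_label[out_label < 0.5] <- 0
  list(image = tf(image, "bilinear"), label = out_label)
}

#' Patient-level k-fold split
#'
#' Randomly partitions patients into `n_folds` folds of sizes differing by at
#' most one. Splitting at the patient level (not the window level) keeps
#' neighboring slices of one patient out of both train and test sets.
#'
#' @param patients Vector of patient identifiers.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @param stratify Optional vector (same length) to stratify by: patients are
#'   ordered by this variable before round-robin assignment so each fold gets
#'   a balanced share.
#' @return An object of class `fold_split`: `list(n_folds, assignment)` with
#'   `assignment` a data frame of `patient` and `fold`.
#' @export
split_folds <- function(patients, n_folds = 9, seed = 1L, stratify = NULL) {
  n <- length(patients)
  if (n < n_folds)
    stop(sprintf("need at least %d patients for %d folds (have %d)",
                 n_folds, n_folds, n))
  set.seed(seed)
  ord <- sample.int(n)
  if (!is.null(stratify)) {
    stopifnot(length(stratify) == n)
    ord <- ord[order(stratify[ord])]
  }
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(n_folds), n)
  structure(list(n_folds = as.integer(n_folds),
                 assignment = data.frame(patient = patients, fold = folds)),
            class = "fold_split")
}

#' Train/test patient sets for one fold iteration
#'
#' @param split A [split_folds()] result.
#' @param fold Which fold is held out for testing.
#' @return `list(train, test)` of patient identifiers.
#' @export
fold_patients <- function(split, fold) {
  stopifnot(inherits(split, "fold_split"), fold >= 1, fold <= split$n_folds)
  a <- split$assignment
  list(train = a$patient[a$fold != fold], test = a$patient[a$fold == fold])
}

#' Full preprocessing of a raw phase volume
#'
#' Convenience wrapper: piecewise normalization followed by per-volume
#' standardization.
#'
#' @inheritParams normalize_intensity
#' @return Preprocessed array.
#' @export
preprocess_volume <- function(volume, floor = 80, percentile = 0.99,
                              name = "volume") {
  standardize(normalize_intensity(volume, floor, percentile, name), name)
}
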
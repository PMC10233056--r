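# Shared fixture builders: everything is generated in code at test time.

# A valid random prediction batch (rows sum to 1) with one-hot targets.
random_batch <- function(n, seed = 1) {
  set.seed(seed)
  fg <- rbinom(n, 1, 0.4)
  y <- cbind(1 - fg, fg)
  p0 <- matrix(runif(2 * n, 0.01, 1), n, 2)
  p <- p0 / rowSums(p0)
  list(targets = y, probs = p)
}

# Literal per-pixel oracle for the hybrid dice+focal loss; evaluates both
# terms by explicit loops, independent of the vectorized implementation.
hybrid_loss_oracle <- function(y, p, alpha = 0.25, gamma = 2, eps = 1) {
  C <- ncol(y); n <- nrow(y)
  w <- if (C == 2) c(1 - alpha, alpha) else rep(alpha, C)
  dice <- numeric(C)
  for (c in seq_len(C)) {
    num <- 0; d1 <- 0; d2 <- 0
    for (i in seq_len(n)) {
      num <- num + 2 * y[i, c] * p[i, c]
      d1 <- d1 + y[i, c]^2; d2 <- d2 + p[i, c]^2
    }
    dice[c] <- (num + eps) / (d1 + d2 + eps)
  }
  foc <- 0
  for (c in seq_len(C)) for (i in seq_len(n)) {
    pc <- min(max(p[i, c], 1e-7), 1 - 1e-7)
    foc <- foc - w[c] * (1 - pc)^gamma * y[i, c] * log(pc)
  }
  unname(mean(1 - dice) + foc / n)
}

# Binary IoU of two 0/1 vectors (loop-free reference for Lovasz checks).
iou_binary <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

# Small phantom study collection for training-based tests.
make_easy_studies <- function(n, seed = 11, ...) {
  spec <- phantom_spec_easy(n_patients = n, seed = seed, ...)
  lapply(seq_len(n), function(i)
    generate_study(spec, derive_seed(spec$seed, i), patient_id = i))
}

# Separable feature crops: bright center => positive, dark => negative;
# mimics the phantom's contrast dichotomy at high SNR.
make_feature_crops <- function(n, seed = 5, size = 32L) {
  set.seed(seed)
  crops <- list(); labels <- NULL; x <- integer(0)
  for (i in seq_len(n)) {
    pos <- i %% 2 == 0
    img <- matrix(rnorm(size^2, 0, 0.2), size, size)
    cc <- (size / 2 - 6):(size / 2 + 6)
    img[cc, cc] <- img[cc, cc] + if (pos) 2 else -2
    arterial <- i %% 3 != 0
    crops[[i]] <- img
    if (arterial) {
      labels <- rbind(labels, data.frame(aphe = pos, washout = NA,
                                         capsule = NA))
      x <- c(x, 0L)
    } else {
      labels <- rbind(labels, data.frame(aphe = NA, washout = pos,
                                         capsule = pos))
      x <- c(x, 1L)
    }
  }
  list(crops = crops, labels = labels, x = x)
}
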
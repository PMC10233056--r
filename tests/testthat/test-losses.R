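test_that("soft dice matches pixel-count arithmetic and is symmetric", {
  # 50 true / 50 predicted foreground pixels, 25 overlapping, hard probs
  n <- 200
  y_fg <- c(rep(1, 50), rep(0, 150))
  p_fg <- c(rep(1, 25), rep(0, 25), rep(1, 25), rep(0, 125))
  y <- cbind(1 - y_fg, y_fg)
  p <- cbind(1 - p_fg, p_fg)
  d <- soft_dice_term(y, p, epsilon = 1e-9)
  expect_equal(d[2], 2 * 25 / (50 + 50), tolerance = 1e-6)
  expect_equal(soft_dice_term(y, p, 1e-9), soft_dice_term(p, y, 1e-9))

  # perfect one-hot prediction -> dice 1 per class as epsilon -> 0
  b <- random_batch(30, seed = 2)
  hard <- b$targets
  expect_equal(soft_dice_term(hard, hard, 1e-12), c(1, 1), tolerance = 1e-9)

  # uniform-probability toy agrees with a direct per-pixel summation oracle
  y4 <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  p4 <- matrix(0.5, 4, 2)
  num <- sapply(1:2, function(c) 2 * sum(y4[, c] * p4[, c]) + 1)
  den <- sapply(1:2, function(c) sum(y4[, c]^2) + sum(p4[, c]^2) + 1)
  expect_equal(soft_dice_term(y4, p4, 1), num / den)
})

test_that("focal term reduces to cross-entropy at gamma 0 and vanishes as p -> 1", {
  # all-foreground 3-pixel toy, alpha = 1, gamma = 0: exactly -mean(log p)
  y <- cbind(c(0, 0, 0), c(1, 1, 1))
  p_true <- c(0.9, 0.6, 0.3)
  p <- cbind(1 - p_true, p_true)
  expect_equal(focal_term(y, p, alpha = 1, gamma = 0), -mean(log(p_true)),
               tolerance = 1e-12)

  # confident correct prediction: modulating factor drives the term to ~0
  p_conf <- cbind(rep(1e-7, 3), rep(1 - 1e-7, 3))
  expect_lt(focal_term(y, p_conf, 0.25, 2), 1e-10)

  # increasing gamma never increases the term (brute-force over a p grid)
  for (pt in seq(0.05, 0.95, by = 0.1)) {
    pp <- cbind(1 - pt, pt)
    yy <- cbind(0, 1)
    vals <- sapply(c(0, 0.5, 1, 2, 5), function(g) focal_term(yy, pp, 0.25, g))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("hybrid loss matches the independent per-pixel loop oracle", {
  for (seed in 1:5) {
    b <- random_batch(16, seed = seed)
    expect_equal(hybrid_loss(b$targets, b$probs),
                 hybrid_loss_oracle(b$targets, b$probs), tolerance = 1e-10)
  }
  # minimized at a perfect prediction, monotone in the true-class probability
  y1 <- cbind(0, 1)
  expect_lt(hybrid_loss(y1, cbind(0.1, 0.9)), hybrid_loss(y1, cbind(0.4, 0.6)))
  b <- random_batch(40, seed = 9)
  expect_lt(hybrid_loss(b$targets, b$targets + 0), 0.2)  # near-zero up to eps
  expect_gte(hybrid_loss(b$targets, b$probs), 0)
})

test_that("Lovasz-Softmax equals 1 - IoU on hard predictions", {
  # exhaustive over all hard predictions of a 4-pixel toy
  y_fg <- c(1, 1, 0, 0)
  y <- cbind(1 - y_fg, y_fg)
  for (code in 0:15) {
    p_fg <- as.integer(intToBits(code)[1:4])
    p <- cbind(1 - p_fg, p_fg)
    expected <- mean(c(1 - iou_binary(1 - y_fg == 1, 1 - p_fg == 1),
                       1 - iou_binary(y_fg == 1, p_fg == 1)), na.rm = TRUE)
    expect_equal(lovasz_softmax(y, p), expected, tolerance = 1e-12,
                 label = sprintf("code %d", code))
  }
  # perfect prediction -> 0
  expect_equal(lovasz_softmax(y, y), 0)
})

test_that("Lovasz sorted-gradient algorithm matches direct extension evaluation", {
  # on soft predictions, compare against an independent implementation that
  # evaluates the extension as a sum over sorted prefixes
  direct <- function(y, m) {
    ord <- order(m, decreasing = TRUE)
    ys <- y[ord]; ms <- m[ord]
    gts <- sum(ys)
    jac <- 1 - (gts - cumsum(ys)) / (gts + cumsum(1 - ys))
    g <- diff(c(0, jac))
    sum(ms * g)
  }
  set.seed(4)
  for (rep in 1:20) {
    y_fg <- rbinom(8, 1, 0.5)
    if (sum(y_fg) == 0) y_fg[1] <- 1
    if (sum(y_fg) == 8) y_fg[1] <- 0
    p_fg <- runif(8)
    y <- cbind(1 - y_fg, y_fg); p <- cbind(1 - p_fg, p_fg)
    expected <- mean(c(direct(1 - y_fg, abs((1 - y_fg) - (1 - p_fg))),
                       direct(y_fg, abs(y_fg - p_fg))))
    expect_equal(lovasz_softmax(y, p), expected, tolerance = 1e-12)
  }
})

test_that("scheduled loss latches the Lovasz term on the trigger", {
  b <- random_batch(12, seed = 3)
  cfg <- loss_config(lovasz_trigger = 0.3)
  above <- scheduled_loss(b$targets, b$probs, cfg, current_train_loss = 1)
  expect_equal(as.numeric(above), hybrid_loss(b$targets, b$probs, cfg))
  expect_false(attr(above, "lovasz_active"))

  below <- scheduled_loss(b$targets, b$probs, cfg, current_train_loss = 0.1)
  expect_equal(as.numeric(below),
               hybrid_loss(b$targets, b$probs, cfg) +
                 lovasz_softmax(b$targets, b$probs))
  expect_true(attr(below, "lovasz_active"))

  # latched: active stays on even when the loss rises again
  relatch <- scheduled_loss(b$targets, b$probs, cfg, current_train_loss = 5,
                            lovasz_active = TRUE)
  expect_true(attr(relatch, "lovasz_active"))

  # trigger = +Inf: active from step 0
  cfg_inf <- loss_config(lovasz_trigger = Inf)
  step0 <- scheduled_loss(b$targets, b$probs, cfg_inf,
                          current_train_loss = Inf)
  expect_true(attr(step0, "lovasz_active"))
})

test_that("adaptive multi-task loss routes by the phase indicator", {
  expect_equal(adaptive_multitask_loss(0.3, 0.2, 0.5, x = 0), 0.3)
  expect_equal(adaptive_multitask_loss(0.3, 0.2, 0.5, x = 1), 0.7)
  expect_equal(adaptive_multitask_loss(0, 0, 0, x = 0), 0)
  expect_equal(adaptive_multitask_loss(0, 0, 0, x = 1), 0)
  expect_error(adaptive_multitask_loss(1, 1, 1, x = 0.5), "0 or 1")

  # batch-mixing: vectorized total equals a per-sample loop
  set.seed(8)
  l1 <- runif(20); l2 <- runif(20); l3 <- runif(20)
  x <- rbinom(20, 1, 0.5)
  looped <- 0
  for (i in 1:20)
    looped <- looped + adaptive_multitask_loss(l1[i], l2[i], l3[i], x[i])
  expect_equal(adaptive_multitask_loss(l1, l2, l3, x), looped)
})
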
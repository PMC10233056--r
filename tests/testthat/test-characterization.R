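test_that("representative slice maximizes lesion area with ties to the lowest index", {
  stk <- array(0, c(6, 6, 3))
  stk[1:2, 1:2, 1] <- 1          # area 4... wait areas: 5, 20, 7 analogue
  stk[1:4, 1:5, 2] <- 1
  stk[1:2, 1:3, 3] <- 1
  expect_equal(select_representative_slice(stk), 2)

  tie <- array(0, c(4, 4, 2))
  tie[1:3, 1:3, 1] <- 1; tie[2:4, 2:4, 2] <- 1
  expect_equal(select_representative_slice(tie), 1)

  expect_error(select_representative_slice(array(0, c(4, 4, 2))),
               "no lesion")
})

test_that("crop_resize squares, margins, clamps and standardizes", {
  img <- matrix(rnorm(512 * 512), 512, 512)
  comp <- matrix(0, 512, 512); comp[231:280, 231:280] <- 1  # 50-px blob
  cr <- crop_resize(img, comp, margin = 0.25, out_size = 224)
  expect_equal(dim(cr), c(224, 224))
  expect_equal(mean(cr), 0, tolerance = 1e-8)
  expect_equal(sqrt(mean(cr^2)), 1, tolerance = 1e-8)

  # margin arithmetic: 0.2 on a 100-px box -> 120-px box before clamping
  comp2 <- matrix(0, 512, 512); comp2[201:300, 201:300] <- 1
  cr2 <- crop_resize(img, comp2, margin = 0.2, out_size = 64)
  expect_equal(dim(cr2), c(64, 64))

  # constant image: resize introduces no structure
  const <- crop_resize(matrix(5, 64, 64),
                       {m <- matrix(0, 64, 64); m[30:40, 30:40] <- 1; m},
                       out_size = 32)
  expect_true(all(abs(const) < 1e-12))

  # degenerate single-pixel component still crops
  tiny <- matrix(0, 64, 64); tiny[10, 10] <- 1
  expect_equal(dim(crop_resize(img[1:64, 1:64], tiny, out_size = 32)),
               c(32, 32))
  expect_error(crop_resize(img, matrix(0, 512, 512)), "empty")
})

test_that("characterizer outputs three probabilities with disjoint heads", {
  cc <- char_config(widths = c(4L, 8L), fc = 8L, input_size = 16L)
  m <- build_characterizer(cc, seed = 2)
  crop <- matrix(rnorm(32 * 32), 32, 32)  # downscaled internally
  p <- char_predict_crop(m, crop)
  expect_named(p, c("aphe", "washout", "capsule"))
  expect_true(all(p >= 0 & p <= 1))

  # zeroing one head's weights changes only that head's output
  m2 <- m
  m2$params[["head.washout.W"]][] <- 0
  m2$params[["head.washout.b"]][] <- 0
  p2 <- char_predict_crop(m2, crop)
  expect_equal(p2["aphe"], p["aphe"])
  expect_equal(p2["capsule"], p["capsule"])
  expect_equal(unname(p2["washout"]), 0.5)
})

test_that("phase-routed training leaves inactive heads bit-identical", {
  d <- make_feature_crops(12, seed = 6)
  art <- d$x == 0
  cc <- char_config(widths = c(4L), fc = 6L, input_size = 16L)
  m0 <- build_characterizer(cc, seed = 3)

  # arterial-only batch: washout and capsule heads must not move
  m1 <- fit_characterizer(d$crops[art], d$labels[art, ], d$x[art], cc,
                          steps = 3, batch_size = 4, seed = 9, model = m0)
  for (nm in c("head.washout.W", "head.washout.b", "head.capsule.W",
               "head.capsule.b"))
    expect_identical(m1$params[[nm]], m0$params[[nm]])
  expect_false(identical(m1$params[["head.aphe.W"]],
                         m0$params[["head.aphe.W"]]))
  expect_false(identical(m1$params[["blk1.W"]], m0$params[["blk1.W"]]))

  # symmetric: PV/delayed-only batch leaves the APHE head unchanged
  m2 <- fit_characterizer(d$crops[!art], d$labels[!art, ], d$x[!art], cc,
                          steps = 3, batch_size = 4, seed = 9, model = m0)
  expect_identical(m2$params[["head.aphe.W"]], m0$params[["head.aphe.W"]])
  expect_false(identical(m2$params[["head.washout.W"]],
                         m0$params[["head.washout.W"]]))

  # holds for random mixtures too: inactive-head isolation per composition
  m3 <- fit_characterizer(d$crops, d$labels, d$x, cc, steps = 4,
                          batch_size = 5, seed = 10, model = m0)
  expect_false(identical(m3$params[["head.aphe.W"]],
                         m0$params[["head.aphe.W"]]))

  # contradictory labeling is rejected
  bad <- d$labels; bad$washout[which(art)[1]] <- TRUE
  expect_error(fit_characterizer(d$crops, bad, d$x, cc, steps = 1),
               "arterial")
})

test_that("feature fusion takes the max over late phases and thresholds at >= ", {
  cc <- char_config(widths = c(4L), fc = 6L, input_size = 16L)
  m <- build_characterizer(cc, seed = 4)
  set.seed(12)
  crops <- list(arterial = matrix(rnorm(256), 16, 16),
                portal_venous = matrix(rnorm(256), 16, 16),
                delayed = matrix(rnorm(256), 16, 16))
  f <- predict_features(m, crops)
  ppv <- char_predict_crop(m, crops$portal_venous)
  pdl <- char_predict_crop(m, crops$delayed)
  expect_equal(f$p_washout, max(ppv["washout"], pdl["washout"]),
               ignore_attr = TRUE)
  expect_equal(f$p_capsule, max(ppv["capsule"], pdl["capsule"]),
               ignore_attr = TRUE)
  expect_equal(f$p_aphe, unname(char_predict_crop(m, crops$arterial)["aphe"]))
  expect_equal(f$B1, f$p_aphe >= 0.5)

  # permutation invariance in the PV/delayed order
  f2 <- predict_features(m, crops[c("delayed", "arterial", "portal_venous")])
  expect_equal(f, f2)

  expect_error(predict_features(m, crops[c("portal_venous", "delayed")]),
               "arterial")
  expect_error(predict_features(m, crops["arterial"]), "portal_venous")
})

test_that("the reduced backbone learns separable feature crops to high accuracy", {
  d <- make_feature_crops(60, seed = 15)
  cc <- char_config(widths = c(6L, 12L), fc = 12L, input_size = 16L)
  m <- fit_characterizer(d$crops, d$labels, d$x, cc, steps = 150,
                         batch_size = 8, lr = 3e-3, seed = 5)
  art <- which(d$x == 0)
  acc <- mean(vapply(art, function(i) {
    p <- char_predict_crop(m, d$crops[[i]])
    (p["aphe"] >= 0.5) == d$labels$aphe[i]
  }, TRUE))
  expect_gt(acc, 0.9)
})
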
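test_that("Dice and IoU on hand-countable mask pairs", {
  a <- array(FALSE, c(4, 4, 4)); a[1:4, 1, 1] <- TRUE
  expect_equal(dice_iou(a, a), list(dice = 1, iou = 1))

  b <- array(FALSE, c(4, 4, 4)); b[1:4, 2, 1] <- TRUE
  expect_equal(dice_iou(a, b), list(dice = 0, iou = 0))

  # |A| = |B| = 4, |A & B| = 2
  c <- array(FALSE, c(4, 4, 4)); c[3:4, 1, 1] <- TRUE; c[1:2, 2, 1] <- TRUE
  di <- dice_iou(a, c)
  expect_equal(di$dice, 0.5)
  expect_equal(di$iou, 1 / 3)

  both <- dice_iou(array(FALSE, c(4, 4, 4)), array(FALSE, c(4, 4, 4)))
  expect_equal(both$dice, 1)
  expect_equal(both$flag, "both_empty")
  expect_error(dice_iou(a, array(FALSE, c(5, 4, 4))), "differ")
})

test_that("dice = 2 iou / (1 + iou) on random mask pairs", {
  set.seed(123)
  for (i in 1:1000) {
    a <- array(stats::runif(60) < 0.4, c(5, 4, 3))
    b <- array(stats::runif(60) < 0.4, c(5, 4, 3))
    di <- dice_iou(a, b)
    expect_equal(di$dice, 2 * di$iou / (1 + di$iou), tolerance = 1e-12)
  }
})

test_that("regression agreement matches hand arithmetic and flags zero variance", {
  ra <- regression_agreement(c(1, 2, 3), c(3, 2, 1))
  expect_equal(ra$pearson_r, -1)
  expect_equal(ra$spearman_rho, -1)
  expect_equal(ra$rmse, sqrt(8 / 3))

  id <- regression_agreement(c(1, 2, 5), c(1, 2, 5))
  expect_equal(id$pearson_r, 1)
  expect_equal(id$rmse, 0)

  aff <- regression_agreement(2 * c(1, 2, 5) + 1, c(1, 2, 5))
  expect_equal(aff$pearson_r, 1)
  expect_gt(aff$rmse, 0)

  zv <- regression_agreement(c(2, 2, 2), c(1, 2, 3))
  expect_equal(zv$flag, "zero_variance")
  expect_true(is.na(zv$pearson_r))
  expect_error(regression_agreement(1:2, 1:2), "3 pairs")
})

test_that("soft Dice loss has the closed-form values and matches 1 - dice on hard masks", {
  g <- array(FALSE, c(4, 4, 4)); g[1:2, , ] <- TRUE
  p_perfect <- array(as.numeric(g), dim(g))
  expect_lt(soft_dice_loss(p_perfect, g), 1e-6)
  expect_gt(soft_dice_loss(1 - p_perfect, g), 1 - 1e-6)

  # uniform 0.5 map against a half-full mask
  u <- array(0.5, c(4, 4, 4))
  expect_equal(soft_dice_loss(u, g), 0.5, tolerance = 1e-6)
  expect_error(soft_dice_loss(array(1.5, c(4, 4, 4)), g), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:50) {
    a <- array(stats::runif(64) < 0.5, c(4, 4, 4))
    b <- array(stats::runif(64) < 0.5, c(4, 4, 4))
    expect_equal(soft_dice_loss(array(as.numeric(a), dim(a)), b),
                 1 - dice_iou(a, b)$dice, tolerance = 1e-5)
  }
})

test_that("combined loss reduces to its components and hits zero at the optimum", {
  expect_equal(combined_loss(dice_losses = c(0.2, 0.4), w_reg = 0), 0.3)
  expect_equal(combined_loss(pred = c(1, 2), target = c(0, 0), w_seg = 0), 2.5)
  expect_equal(combined_loss(dice_losses = 0, pred = c(1, 2), target = c(1, 2)), 0)
  expect_error(combined_loss(w_seg = -1), ">= 0")
})

test_that("splits are stratified partitions with the 70/15/15 fractions", {
  sp <- make_splits(1:100, seed = 4)
  expect_equal(sort(sp$item), 1:100)                       # exhaustive, disjoint
  expect_equal(unname(table(sp$split)[c("train", "val", "test")]),
               c(70, 15, 15), ignore_attr = TRUE)

  # 4 strata of 5 with k = 5: every fold holds exactly one item per stratum
  sp2 <- make_splits(1:20, strata = rep(letters[1:4], each = 5), k = 5, seed = 9)
  tab <- table(sp2$stratum, sp2$fold)
  expect_true(all(tab == 1))

  expect_identical(make_splits(1:40, seed = 2), make_splits(1:40, seed = 2))
  expect_false(identical(make_splits(1:40, seed = 2)$item,
                         make_splits(1:40, seed = 3)$item))
  expect_error(make_splits(1:8, strata = rep(c("a", "b"), c(6, 2)), k = 5),
               "stratum smaller")
})

test_that("augmentation with collapsed ranges is the identity", {
  set.seed(11)
  v <- ct_volume(array(stats::rnorm(10^3, -500, 100), c(10, 10, 10)))
  m <- label_mask(array(stats::runif(10^3) < 0.2, c(10, 10, 10)))
  cfg0 <- augment_config(rotation_deg = c(0, 0), flip_horizontal = FALSE,
                         flip_vertical = FALSE, crop_scale = c(1, 1),
                         intensity_amplitude_hu = 0)
  out <- augment(v, m, cfg0, seed = 1)
  expect_identical(out$volume$data, v$data)
  expect_identical(out$mask$data, m$data)
})

test_that("flipping twice recovers the original and transforms stay in range", {
  set.seed(12)
  v <- ct_volume(array(stats::rnorm(8^3), c(8, 8, 8)))
  flipped <- v$data[rev(1:8), , ]
  expect_identical(flipped[rev(1:8), , ], v$data)

  cfg <- augment_config()
  for (s in 1:25) {
    p <- augment(v, label_mask(array(FALSE, c(8, 8, 8))), cfg, seed = s)$params
    expect_true(p$angle_deg >= -10 && p$angle_deg <= 10)
    expect_true(all(p$crop_dim >= floor(0.8 * 8) & p$crop_dim <= 8))
    expect_true(abs(p$shift_hu) <= 10)
  }
  # determinism
  a <- augment(v, label_mask(array(FALSE, c(8, 8, 8))), cfg, seed = 3)
  b <- augment(v, label_mask(array(FALSE, c(8, 8, 8))), cfg, seed = 3)
  expect_identical(a$volume$data, b$volume$data)
})

test_that("rotating a sphere keeps its mask nearly unchanged", {
  d <- c(33, 33, 9)
  g <- grid <- array(FALSE, d)
  for (z in 1:9) {
    rho <- sqrt(outer((1:33 - 17)^2, (1:33 - 17)^2, "+"))
    g[, , z] <- rho <= 10
  }
  v <- ct_volume(array(0, d))
  m <- label_mask(g)
  cfg <- augment_config(rotation_deg = c(7, 7), flip_horizontal = FALSE,
                        flip_vertical = FALSE, crop_scale = c(1, 1),
                        intensity_amplitude_hu = 0)
  out <- augment(v, m, cfg, seed = 2)
  expect_gte(dice_iou(out$mask$data, g)$dice, 0.95)
})

test_that("the same sampled geometric transform is applied to volume and mask", {
  set.seed(20)
  arr <- array(stats::rnorm(12^3), c(12, 12, 12))
  v <- ct_volume(arr)
  m <- label_mask(arr > 0.5)
  out <- augment(v, m, augment_config(rotation_deg = c(0, 0),
                                      intensity_amplitude_hu = 0), seed = 8)
  # mask of thresholded volume transforms exactly like the volume (flip/crop only)
  expect_identical(out$mask$data, out$volume$data > 0.5)
})
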
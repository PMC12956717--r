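make_lesion_volume <- function(lesions, dim = c(32, 32, 8), dz = 3) {
  arr <- array(0, dim)
  roi <- array(TRUE, dim)
  for (L in lesions) arr[L$xs, L$ys, L$z] <- L$hu
  list(v = ct_volume(arr, spacing = c(1, 1, dz)),
       roi = label_mask(roi, spacing = c(1, 1, dz)))
}

test_that("Agatston scoring reproduces hand-computed lesion tables", {
  # one 4 mm2 lesion, peak 250 HU, 3 mm slices -> 4 x 2 x 1 = 8
  lv <- make_lesion_volume(list(list(xs = 10:11, ys = 10:11, z = 3, hu = 250)))
  res <- agatston_score(lv$v, lv$roi)
  expect_equal(res$cacs, 8)
  expect_equal(res$lesion_table$weight, 2L)
  expect_equal(res$lesion_table$area_mm2, 4)

  # nothing above 130 HU -> zero score, empty table
  quiet <- make_lesion_volume(list(list(xs = 5, ys = 5, z = 2, hu = 100)))
  res0 <- agatston_score(quiet$v, quiet$roi)
  expect_equal(res0$cacs, 0)
  expect_equal(nrow(res0$lesion_table), 0L)

  # sub-minimum-area lesion excluded (0.25 mm2 pixels, single voxel)
  arr <- array(0, c(16, 16, 4)); arr[8, 8, 2] <- 300
  v <- ct_volume(arr, spacing = c(0.5, 0.5, 3))
  roi <- label_mask(array(TRUE, c(16, 16, 4)), spacing = c(0.5, 0.5, 3))
  expect_equal(agatston_score(v, roi)$cacs, 0)
})

test_that("density weights follow the 130/200/300/400 classes", {
  expect_equal(agatston_weight(c(130, 199, 200, 299, 300, 399, 400, 900)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # thin slices are rescaled by spacing/3
  lv <- make_lesion_volume(list(list(xs = 10:11, ys = 10:11, z = 3, hu = 450)),
                           dz = 0.75)
  expect_equal(agatston_score(lv$v, lv$roi)$cacs, 4 * 4 * 0.75 / 3)
})

test_that("Agatston is translation-invariant and monotone in area and density", {
  base <- make_lesion_volume(list(list(xs = 5:6, ys = 5:6, z = 2, hu = 250)))
  shifted <- make_lesion_volume(list(list(xs = 15:16, ys = 20:21, z = 6, hu = 250)))
  expect_equal(agatston_score(base$v, base$roi)$cacs,
               agatston_score(shifted$v, shifted$roi)$cacs)
  bigger <- make_lesion_volume(list(list(xs = 5:7, ys = 5:6, z = 2, hu = 250)))
  denser <- make_lesion_volume(list(list(xs = 5:6, ys = 5:6, z = 2, hu = 450)))
  b <- agatston_score(base$v, base$roi)$cacs
  expect_gt(agatston_score(bigger$v, bigger$roi)$cacs, b)
  expect_gt(agatston_score(denser$v, denser$roi)$cacs, b)
})

test_that("8-connectivity merges diagonal voxels into one lesion", {
  arr <- array(0, c(16, 16, 4))
  arr[5, 5, 2] <- 250; arr[6, 6, 2] <- 310   # diagonal neighbours
  v <- ct_volume(arr, spacing = c(1, 1, 3))
  roi <- label_mask(array(TRUE, c(16, 16, 4)), spacing = c(1, 1, 3))
  res <- agatston_score(v, roi)
  expect_equal(nrow(res$lesion_table), 1L)
  expect_equal(res$lesion_table$weight, 3L)   # peak 310 -> class 3
  expect_equal(res$cacs, 2 * 3)
})

test_that("a 400-HU-clamped volume is flagged and loses density class 4", {
  lesions <- list(list(xs = 10:11, ys = 10:11, z = 3, hu = 450))
  lv <- make_lesion_volume(lesions)
  raw <- agatston_score(lv$v, lv$roi)$cacs
  clamped <- ct_volume(pmin(lv$v$data, 400), spacing = lv$v$spacing)
  expect_warning(res <- agatston_score(clamped, lv$roi), "truncated")
  expect_equal(raw, 4 * 4)
  expect_equal(res$cacs, 4 * 4)   # 400 still maps to class 4...
  harder <- ct_volume(pmin(lv$v$data, 399), spacing = lv$v$spacing)
  expect_lt(suppressWarnings(agatston_score(harder, lv$roi))$cacs, raw)
})

test_that("LV mass is count x volume x density with scaling and empty-mask flag", {
  m <- label_mask(array(TRUE, c(100, 100, 10)))  # 100,000 voxels at 1 mm3
  expect_equal(lv_mass(m), 105)
  m2 <- label_mask(array(TRUE, c(100, 100, 10)), spacing = c(2, 2, 2))
  expect_equal(lv_mass(m2), 8 * 105)
  expect_warning(z <- lv_mass(label_mask(array(FALSE, c(4, 4, 4)))), "empty")
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "flag"), "empty_mask")
})

test_that("LV function arithmetic and phase consistency checks", {
  ed <- label_mask(array(seq_len(8^3) <= 120, c(8, 8, 8)), spacing = c(10, 10, 10))
  es <- label_mask(array(seq_len(8^3) <= 48, c(8, 8, 8)), spacing = c(10, 10, 10))
  lf <- lv_function(ed, es)
  expect_equal(lf$edv_ml, 120)
  expect_equal(lf$sv_ml, 72)
  expect_equal(lf$ef_percent, 60)
  expect_error(lv_function(ed, ed), "inconsistent")
  # ef is scale-free; volumes scale with voxel volume
  ed2 <- label_mask(ed$data, spacing = c(20, 20, 20))
  es2 <- label_mask(es$data, spacing = c(20, 20, 20))
  lf2 <- lv_function(ed2, es2)
  expect_equal(lf2$ef_percent, lf$ef_percent)
  expect_equal(lf2$sv_ml, 8 * lf$sv_ml)
})

test_that("phantom cardiac truth is recovered exactly end to end", {
  ph <- small_phantom()
  tr <- ph$truth
  cm <- cardiac_metrics(ph$volume, tr$masks$roi, tr$masks$myocardium,
                        tr$masks$blood_ed, tr$masks$blood_es)
  expect_equal(cm$cacs, tr$expected$cardiac$cacs)
  expect_equal(cm$ef_percent, tr$expected$cardiac$ef_percent)
  expect_equal(cm$sv_ml, tr$expected$cardiac$sv_ml)
  expect_equal(cm$lvm_g, tr$expected$cardiac$lvm_g)
  got <- cm$lesion_table[order(cm$lesion_table$slice), ]
  exp <- tr$expected$cardiac$lesion_table[order(tr$expected$cardiac$lesion_table$slice), ]
  expect_equal(got$score, exp$score)
  expect_equal(got$weight, exp$weight)
})
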
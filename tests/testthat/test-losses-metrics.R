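test_that("soft Dice loss matches hand-evaluated overlap", {
  # 2^3 grid: 4 true foreground voxels, prediction hits exactly 2 of them
  tgt <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  pfg <- array(c(1, 1, 0, 0, 0, 0, 0, 0), c(2, 2, 2))
  pred <- array(0, c(2, 2, 2, 2))
  pred[, , , 1] <- 1 - pfg
  pred[, , , 2] <- pfg
  expect_equal(soft_dice_loss(pred, tgt, smooth_eps = 0), 1 / 3)

  # perfect one-hot prediction -> loss 0 (up to the stabilizer)
  perf <- array(0, c(2, 2, 2, 2))
  perf[, , , 1] <- 1 - tgt
  perf[, , , 2] <- tgt
  expect_lt(soft_dice_loss(perf, tgt), 1e-5)

  # disjoint foreground mass -> loss ~ 1
  expect_gt(soft_dice_loss(pred, array(c(0, 0, 0, 0, 1, 1, 1, 1), c(2, 2, 2))),
            0.999)
  expect_error(soft_dice_loss(pred, array(0L, c(3, 3, 3))), "mismatch")
})

test_that("soft Dice of a one-hot prediction is 1 - DSC as eps -> 0", {
  set.seed(3)
  for (i in 1:20) {
    tgt <- rand_mask(c(6, 6, 6), p = runif(1, 0.05, 0.6))
    pm <- rand_mask(c(6, 6, 6), p = runif(1, 0.05, 0.6))
    pred <- array(0, c(6, 6, 6, 2))
    pred[, , , 1] <- 1 - pm
    pred[, , , 2] <- pm
    dsc <- segmentation_metrics(pm, tgt)$dsc
    expect_equal(soft_dice_loss(pred, tgt, smooth_eps = 1e-12), 1 - dsc,
                 tolerance = 1e-8)
  }
})

test_that("composite loss reduces, scales and is monotone in the aux heads", {
  set.seed(4)
  tgt <- rand_mask(c(4, 4, 4), 0.3)
  lg <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  outs <- list(main = lg, aux_semantic = lg, aux_detail = lg)
  single <- soft_dice_loss(dpfnet:::softmax_channels(lg), tgt)
  expect_equal(composite_loss(outs, tgt, train_loss_config(0, 0)), single)
  # three identical heads at beta1 = beta2 = 1 -> exactly 3x one head
  expect_equal(composite_loss(outs, tgt, train_loss_config(1, 1)), 3 * single)
  # deep supervision off: only the main term
  expect_equal(composite_loss(list(main = lg), tgt), single)
  # worsening only the detail head never decreases the composite
  worse <- outs
  worse$aux_detail[, , , 2] <- worse$aux_detail[, , , 2] -
    2 * (tgt > 0) + 2 * (tgt == 0)
  expect_gte(composite_loss(worse, tgt), composite_loss(outs, tgt))
})

test_that("segmentation metrics match hand counts and identities", {
  # |y| = 10, |yhat| = 10, |intersection| = 6
  y <- array(0L, c(5, 5, 5)); y[1:10] <- 1L
  p <- array(0L, c(5, 5, 5)); p[5:14] <- 1L
  m <- segmentation_metrics(p, y)
  expect_equal(m$dsc, 0.6)
  expect_equal(m$precision, 0.6)
  expect_equal(m$recall, 0.6)
  expect_equal(m$iou, 6 / 14)

  ident <- segmentation_metrics(y, y)
  expect_equal(unlist(ident), c(dsc = 1, precision = 1, recall = 1, iou = 1))

  # empty-mask conventions
  e <- array(0L, c(3, 3, 3))
  expect_equal(unlist(segmentation_metrics(e, e)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unlist(segmentation_metrics(e, y[1:3, 1:3, 1:3])), rep(0, 4),
               ignore_attr = TRUE)

  set.seed(5)
  for (i in 1:100) {
    a <- rand_mask(c(5, 5, 5), runif(1, 0.1, 0.9))
    b <- rand_mask(c(5, 5, 5), runif(1, 0.1, 0.9))
    mm <- segmentation_metrics(a, b)
    if (mm$dsc > 0) {
      expect_equal(mm$dsc, 2 * mm$iou / (1 + mm$iou), tolerance = 1e-9)
      expect_equal(mm$dsc, 2 * mm$precision * mm$recall /
                     (mm$precision + mm$recall), tolerance = 1e-9)
    }
  }
})

test_that("relative improvement reproduces the reporting convention", {
  expect_equal(relative_improvement(0.8967, 0.8038), 11.56)
  expect_equal(relative_improvement(0.8967, 0.8861), 1.20)
  expect_equal(relative_improvement(0.9007, 0.8576), 5.03)
  expect_equal(relative_improvement(0.9007, 0.8849), 1.79)
  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_error(relative_improvement(0.9, 0), "positive")
})

test_that("size stratification uses the largest lesion's equivalent diameter", {
  sp <- c(0.5, 0.5, 0.5)
  vox <- prod(sp)
  ball_mask <- function(dm, centre, r_vox) {
    g <- expand.grid(x = 1:dm[1], y = 1:dm[2], z = 1:dm[3])
    inside <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2 <=
      r_vox^2
    array(as.integer(inside), dm)
  }
  # rasterized 4 mm sphere (radius 4 voxels at 0.5 mm) -> Small
  m4 <- ball_mask(c(24, 24, 24), c(12, 12, 12), 4)
  expect_identical(stratify_by_diameter(m4, sp), "Small")

  # boundary: smallest voxel count whose equivalent diameter reaches 5 mm
  n5 <- ceiling(4 / 3 * pi * 2.5^3 / vox)
  m <- array(0L, c(40, 40, 40)); m[seq_len(n5)] <- 1L
  expect_identical(stratify_by_diameter(m, sp), "Medium")  # 5 mm inclusive
  m[n5] <- 0L
  d_below <- 2 * (3 * (n5 - 1) * vox / (4 * pi))^(1 / 3)
  expect_lt(d_below, 5)
  expect_identical(stratify_by_diameter(m, sp), "Small")

  # two lesions, ~3 mm and ~16 mm -> the largest governs
  big <- ball_mask(c(80, 48, 48), c(55, 24, 24), 16)  # 16 mm diameter
  big[ball_mask(c(80, 48, 48), c(8, 8, 8), 3) == 1L] <- 1L
  expect_identical(stratify_by_diameter(big, sp), "Large")
  expect_error(stratify_by_diameter(array(0L, c(4, 4, 4)), sp), "empty")
})

test_that("tumor-region compositing is nested and label-exact", {
  dm <- c(4, 4, 4)
  lab <- array(0L, dm)
  lab[1] <- 1L; lab[2] <- 2L; lab[3] <- 4L
  r <- brats_regions(lab)
  expect_equal(sum(r$WT), 3)
  expect_equal(sum(r$TC), 2)
  expect_equal(sum(r$ET), 1)
  # an edema voxel belongs to WT only
  expect_equal(r$WT[2], 1L)
  expect_equal(r$TC[2], 0L)
  expect_equal(r$ET[2], 0L)
  # all-background input -> three empty masks
  r0 <- brats_regions(array(0L, dm))
  expect_true(all(unlist(r0) == 0L))
  # nesting WT >= TC >= ET on random label fields
  set.seed(6)
  for (i in 1:20) {
    lf <- array(sample(c(0L, 1L, 2L, 4L), 64, TRUE), dm)
    rr <- brats_regions(lf)
    expect_true(all(rr$WT >= rr$TC))
    expect_true(all(rr$TC >= rr$ET))
  }
  expect_error(brats_regions(array(3L, dm)), "unknown label")
})
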
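test_that("view permutations reorder and round-trip bit-exactly", {
  x <- array(rnorm(30 * 40 * 50), c(30, 40, 50))
  expect_identical(permute_view(x, "axial"), x)
  expect_equal(dim(permute_view(x, "coronal")), c(40, 30, 50))
  expect_equal(dim(permute_view(x, "sagittal")), c(50, 40, 30))
  for (vw in c("axial", "coronal", "sagittal"))
    expect_identical(inverse_view(permute_view(x, vw), vw), x)
  expect_error(permute_view(x, "oblique"))
})

test_that("patch grids tile and cover the volume", {
  g1 <- make_patch_grid(c(64, 64, 64), 64L, 64L)
  expect_equal(nrow(g1$origins), 1L)
  g2 <- make_patch_grid(c(96, 96, 96), 64L, 32L)
  expect_equal(nrow(g2$origins), 27L)
  expect_equal(g2$padded_shape, c(128L, 128L, 128L))
  # every voxel covered by at least one window, random shapes
  set.seed(31)
  for (i in 1:10) {
    sh <- sample(16:50, 3, replace = TRUE)
    ps <- sample(c(8L, 12L, 16L), 1)
    st <- sample(seq_len(ps), 1)
    g <- make_patch_grid(sh, ps, st)
    cov <- array(0L, g$padded_shape)
    for (r in seq_len(nrow(g$origins))) {
      o <- g$origins[r, ]
      idx <- lapply(1:3, function(a) o[a] + seq_len(ps))
      cov[idx[[1]], idx[[2]], idx[[3]]] <- 1L
    }
    expect_true(all(cov[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])] == 1L))
  }
  expect_error(make_patch_grid(c(32, 32, 32), 16L, 0L), "positive")
  expect_error(make_patch_grid(c(32, 32, 32), 16L, 20L), "exceed")
})

test_that("reconstruction averages overlaps exactly", {
  # constant field survives any overlap pattern (dyadic constant, so the
  # overlap average is exact in floating point)
  g <- make_patch_grid(c(20, 20, 20), 8L, 4L)
  patches <- replicate(nrow(g$origins), array(0.375, c(8, 8, 8)),
                       simplify = FALSE)
  rec <- reconstruct(patches, g)
  expect_true(all(rec$prob == 0.375))
  expect_true(all(rec$weights >= 1))

  # non-overlapping grid is bit-exact
  x <- array(rnorm(16^3), c(16, 16, 16))
  gn <- make_patch_grid(dim(x), 8L, 8L)
  rec2 <- reconstruct(extract_patches(x, gn), gn)
  expect_identical(rec2$prob, x)

  # overlap weighting agrees with a brute-force accumulate/count oracle,
  # including the (a + b) / 2 value where exactly two windows meet
  set.seed(38)
  gz <- make_patch_grid(c(10, 10, 10), 8L, 4L)
  vals <- lapply(seq_len(nrow(gz$origins)), function(i) array(i, c(8, 8, 8)))
  rec3 <- reconstruct(vals, gz)
  acc <- array(0, gz$padded_shape); cnt <- array(0, gz$padded_shape)
  for (i in seq_len(nrow(gz$origins))) {
    o <- gz$origins[i, ]
    id <- o[1] + 1:8; ih <- o[2] + 1:8; iw <- o[3] + 1:8
    acc[id, ih, iw] <- acc[id, ih, iw] + vals[[i]]
    cnt[id, ih, iw] <- cnt[id, ih, iw] + 1
  }
  oracle <- (acc / cnt)[1:10, 1:10, 1:10]
  expect_equal(rec3$prob, oracle)
  # a voxel covered by exactly windows a and b holds their midpoint
  two <- which(rec3$weights == 2)
  expect_true(length(two) > 0 && all(rec3$prob[two] == oracle[two]))
  expect_error(reconstruct(vals[1:2], gz), "expected")
})

test_that("training batches are reproducible, view-balanced and congruent", {
  set.seed(32)
  cases <- lapply(1:2, function(i)
    list(image = array(runif(12^3), c(12, 12, 12)),
         mask = rand_mask(c(12, 12, 12), 0.01)))
  set.seed(99)
  b1 <- sample_training_batch(cases, 6L, 8L, augment = FALSE)
  set.seed(99)
  b2 <- sample_training_batch(cases, 6L, 8L, augment = FALSE)
  expect_identical(lapply(b1, `[[`, "origin"), lapply(b2, `[[`, "origin"))
  expect_identical(lapply(b1, `[[`, "view"), lapply(b2, `[[`, "view"))
  for (s in b1) {
    expect_equal(dim(s$image), c(8, 8, 8))
    expect_equal(dim(s$image), dim(s$mask))
  }
  # view frequencies ~ 1/3 over 3000 draws
  set.seed(33)
  big <- sample_training_batch(cases, 3000L, 8L, fg_bias = 0, augment = FALSE)
  freq <- table(vapply(big, `[[`, "", "view")) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
  expect_error(sample_training_batch(list(), 2L, 8L), "no cases")
})

test_that("augmentation keeps masks crisp and foreground-invariant", {
  set.seed(34)
  img <- array(runif(8^3), c(8, 8, 8))
  msk <- rand_mask(c(8, 8, 8), 0.2)
  nfg <- sum(msk)
  for (i in 1:50) {
    a <- augment_patch(img, msk)
    expect_true(all(a$mask %in% c(0L, 1L)))       # no interpolation
    expect_equal(sum(a$mask), nfg)                # geometric invariance
    expect_equal(dim(a$image), dim(img))
  }
  # double flip along one axis is the identity
  ns <- asNamespace("dpfnet")
  idx <- rev(seq_len(8))
  expect_identical(ns$flip_axis(ns$flip_axis(img, 2L, idx), 2L, idx), img)
  # four quarter-turns are the identity
  expect_identical(ns$rot90_inplane(img, 4L), img)
})

test_that("majority voting matches the 8-row truth table", {
  dm <- c(2, 2, 2)
  pats <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  for (r in seq_len(nrow(pats))) {
    ms <- lapply(pats[r, ], function(v) array(v, dm))
    fused <- fuse_views_majority(ms)
    expect_true(all(fused == as.integer(sum(pats[r, ]) >= 2)))
  }
  # permutation invariance and idempotence
  set.seed(35)
  ms <- lapply(1:3, function(i) rand_mask(c(5, 5, 5), 0.4))
  f <- fuse_views_majority(ms)
  expect_identical(fuse_views_majority(ms[c(3, 1, 2)]), f)
  expect_identical(fuse_views_majority(list(f, f, f)), f)
  # never invents voxels
  expect_true(all(f <= pmin(ms[[1]] + ms[[2]] + ms[[3]], 1L)))
  expect_error(fuse_views_majority(ms[1:2]), "three")
})

test_that("summation fusion thresholds the mean probability", {
  dm <- c(2, 2, 2)
  p1 <- array(0.9, dm); p2 <- array(0.9, dm); p3 <- array(0, dm)
  expect_true(all(fuse_views_sum(list(p1, p2, p3)) == 1L))  # mean 0.6
  q <- list(array(0.6, dm), array(0.3, dm), array(0.3, dm))
  expect_true(all(fuse_views_sum(q) == 0L))                 # mean 0.4
  # identical maps reduce to single-view thresholding
  set.seed(36)
  pm <- array(runif(5^3), c(5, 5, 5))
  expect_identical(fuse_views_sum(list(pm, pm, pm)),
                   array(as.integer(pm >= 0.5), dim(pm)))
  # agreement case: thresholded majority also marks the (0.9, 0.9, 0) voxel
  thr <- lapply(list(p1, p2, p3), function(p) (p >= 0.5) * 1L)
  expect_true(all(fuse_views_majority(thr) == 1L))
})

test_that("component filtering enforces the 10-voxel threshold exactly", {
  dm <- c(20, 20, 20)
  m <- array(0L, dm)
  m[1:9] <- 1L                 # 9-voxel line component -> removed
  m[1:10 + 200L] <- 1L         # 10-voxel line component -> kept
  f <- filter_small_components(m, 10L)
  expect_equal(sum(f[1:9]), 0)
  expect_equal(sum(f[1:10 + 200L]), 10)
  expect_identical(filter_small_components(array(0L, dm)), array(0L, dm))
  # idempotent, never adds voxels
  expect_identical(filter_small_components(f, 10L), f)
  expect_true(all(f <= m))
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(37)
  for (i in 1:100) {
    m <- rand_mask(c(20, 20, 20), runif(1, 0.05, 0.3))
    lab <- label_components(m, 26L)
    oracle <- flood_fill_labels(m, 26L)
    expect_equal(max(lab), max(oracle))
    expect_equal(component_sizes(lab), component_sizes(oracle))
    # filtering agrees with filtering the oracle's components
    keep <- which(tabulate(oracle[oracle > 0]) >= 10L)
    expect_identical(filter_small_components(m, 10L),
                     array(as.integer(oracle %in% keep & m != 0L), dim(m)))
  }
})
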
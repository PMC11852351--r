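test_that("convolutional block obeys its shape and activation contract", {
  set.seed(21)
  x <- array(rnorm(8^3 * 4), c(8, 8, 8, 4))
  W <- array(rnorm(27 * 4 * 6, sd = 0.2), c(3, 3, 3, 4, 6))
  y1 <- conv_block(x, W, rep(1, 6), rep(0, 6), stride = 1L)
  expect_equal(dim(y1), c(8, 8, 8, 6))
  y2 <- conv_block(x, W, rep(1, 6), rep(0, 6), stride = 2L)
  expect_equal(dim(y2), c(4, 4, 4, 6))
  expect_true(all(y1 >= 0))  # ReLU range
})

test_that("residual block reduces to the identity at zero weights", {
  set.seed(22)
  x <- abs(array(rnorm(6 * 6 * 6 * 3), c(6, 6, 6, 3)))  # post-ReLU regime
  W0 <- array(0, c(3, 3, 3, 3, 3))
  y <- residual_block(x, W0, rep(1, 3), rep(0, 3))
  expect_equal(y, x, tolerance = 1e-6)
  # shape in = shape out, and channel mismatch is rejected
  W <- array(rnorm(27 * 9, sd = 0.2), c(3, 3, 3, 3, 3))
  expect_equal(dim(residual_block(x, W, rep(1, 3), rep(0, 3))), dim(x))
  expect_error(residual_block(x, array(0, c(3, 3, 3, 3, 4)), rep(1, 4),
                              rep(0, 4)), "channels")
})

test_that("gradient reaches the input through the identity shortcut", {
  # even with the conv path zeroed, d residual / d x must be ~1
  set.seed(23)
  x <- abs(array(rnorm(4^3 * 2), c(4, 4, 4, 2))) + 0.1
  W0 <- array(0, c(3, 3, 3, 2, 2))
  f <- function(z) sum(residual_block(z, W0, rep(1, 2), rep(0, 2)))
  i <- sample(length(x), 3)
  for (ii in i) {
    eps <- 1e-4
    x1 <- x; x1[ii] <- x1[ii] + eps
    x2 <- x; x2[ii] <- x2[ii] - eps
    expect_equal((f(x1) - f(x2)) / (2 * eps), 1, tolerance = 1e-2)
  }
})

test_that("network gradients agree with finite differences", {
  set.seed(24)
  ns <- asNamespace("dpfnet")
  cfg <- network_config(semantic_widths = c(2L, 3L, 4L), detail_width = 2L,
                        patch_size = 8L)
  P <- dpfnet_init(cfg, seed = 5)
  xs <- array(runif(8^3), c(8, 8, 8, 1))
  tgt <- array(as.integer(runif(8^3) > 0.7), c(8, 8, 8))
  lossfun <- function(P) {
    tp <- ns$ag_tape(); G <- new.env(parent = emptyenv())
    out <- ns$dpf_forward_nodes(xs, P, cfg, tp, G)
    l <- ns$op_dice_loss(tp, ns$op_softmax(tp, out$main), tgt)
    list(val = l$v, G = G, tape = tp, node = l)
  }
  r <- lossfun(P)
  ns$ag_backward(r$tape, r$node)
  for (nm in c("s1.1.W", "d3.2.g", "dam.k4.W", "cfm3.up.c.W", "dec.out.bias")) {
    i <- sample(length(P[[nm]]), 1)
    eps <- 1e-3
    P1 <- P; P1[[nm]][i] <- P1[[nm]][i] + eps
    P2 <- P; P2[[nm]][i] <- P2[[nm]][i] - eps
    fd <- (lossfun(P1)$val - lossfun(P2)$val) / (2 * eps)
    an <- r$G[[nm]][i]
    # float32 conv arithmetic bounds the attainable agreement
    expect_equal(an, fd, tolerance = 5e-2)
  }
})

test_that("branches produce the contracted resolutions and widths", {
  cfg <- tiny_cfg(patch = 16L)
  P <- dpfnet_init(cfg, 1)
  x <- array(rnorm(16^3), c(16, 16, 16, 1))
  S <- semantic_branch(x, P, cfg)
  expect_equal(dim(S$S1), c(16, 16, 16, 3))
  expect_equal(dim(S$S2), c(8, 8, 8, 4))
  expect_equal(dim(S$S3), c(4, 4, 4, 6))
  D <- detail_branch(x, P, cfg)
  expect_equal(dim(D$D1), c(16, 16, 16, 3))
  expect_equal(dim(D$D2), c(16, 16, 16, 3))
  expect_equal(dim(D$D3), c(16, 16, 16, 3))
  # average pooling of a constant field is the same constant
  ns <- asNamespace("dpfnet")
  cst <- ns$op_avgpool2(NULL, ns$ag_node(array(2.5, c(4, 4, 4, 2))))
  expect_true(all(cst$v == 2.5))
})

test_that("cross-fusion is additive with identity fallbacks", {
  cfg <- tiny_cfg(patch = 16L)
  P <- dpfnet_init(cfg, 2)
  sem <- array(rnorm(8^3 * 4), c(8, 8, 8, 4))
  det <- array(rnorm(16^3 * 3), c(16, 16, 16, 3))
  fz <- cross_fusion(sem, det, 1L, P, cfg)
  expect_equal(dim(fz$sem), dim(sem))
  expect_equal(dim(fz$det), dim(det))
  # zero detail features leave the semantic stream untouched
  f0 <- cross_fusion(sem, array(0, dim(det)), 1L, P, cfg)
  expect_equal(f0$sem, sem, tolerance = 1e-6)
  # zero semantic features + zero up-projection leave the detail stream
  P0 <- P
  P0[["cfm2.up.c.W"]][] <- 0
  f1 <- cross_fusion(array(0, dim(sem)), det, 1L, P0, cfg)
  expect_equal(f1$det, det, tolerance = 1e-6)
  # p = 2 gap from the third stage
  sem3 <- array(rnorm(4^3 * 6), c(4, 4, 4, 6))
  f2 <- cross_fusion(sem3, det, 2L, P, cfg)
  expect_equal(dim(f2$sem), dim(sem3))
  expect_equal(dim(f2$det), dim(det))
  expect_error(cross_fusion(sem, det, 2L, P, cfg), "factor")
})

test_that("detail aggregation preserves shape and sums its pyramid", {
  cfg <- tiny_cfg(patch = 16L)
  P <- dpfnet_init(cfg, 3)
  x <- array(rnorm(16^3 * 3), c(16, 16, 16, 3))
  y <- detail_aggregation(x, P, cfg)
  expect_equal(dim(y), dim(x))
  # element-wise sum contract: four equal branch outputs add to 4f
  ns <- asNamespace("dpfnet")
  f <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  s <- ns$op_scale_add(NULL, list(ns$ag_node(f), ns$ag_node(f),
                                  ns$ag_node(f), ns$ag_node(f)), rep(1, 4))
  expect_equal(s$v, 4 * f)
})

test_that("the kernel pyramid's receptive field is the 7^3 envelope", {
  # impulse response of the raw (normalization-free) pyramid: stimulate one
  # voxel, the response support must fill exactly the 7^3 box around it
  ns <- asNamespace("dpfnet")
  x <- array(0, c(15, 15, 15, 1))
  x[8, 8, 8, 1] <- 1
  resp <- 0
  for (k in c(1, 3, 5, 7)) {
    W <- array(1, c(k, k, k, 1, 1))
    resp <- resp + ns$cpp_conv3d_fw(x, W, 1L, as.integer((k - 1) / 2))
  }
  on <- which(resp != 0, arr.ind = TRUE)
  expect_equal(range(on[, 1]), c(5, 11))
  expect_equal(range(on[, 2]), c(5, 11))
  expect_equal(range(on[, 3]), c(5, 11))
  expect_equal(nrow(on), 7^3)
})

test_that("forward pass emits full-resolution logits for every head", {
  for (ps in c(16L, 32L)) {
    cfg <- tiny_cfg(patch = ps)
    P <- dpfnet_init(cfg, 4)
    x <- array(runif(ps^3), c(ps, ps, ps))
    out <- dpfnet_forward(x, P, cfg)
    expect_named(out, c("main", "aux_semantic", "aux_detail"))
    for (o in out) expect_equal(dim(o), c(ps, ps, ps, 2L))
    # determinism with fixed weights
    expect_identical(dpfnet_forward(x, P, cfg)$main, out$main)
  }
  expect_error(dpfnet_forward(array(0, c(6, 6, 6)), P, tiny_cfg(16L)),
               "divisible")
})

test_that("ablation toggles reproduce the four structural variants", {
  ps <- 16L
  x <- array(runif(ps^3), c(ps, ps, ps))
  variants <- list(
    full = tiny_cfg(ps),
    no_detail = tiny_cfg(ps, enable_detail_branch = FALSE),
    no_dam = tiny_cfg(ps, enable_dam = FALSE),
    no_cfm = tiny_cfg(ps, enable_cfm = FALSE)
  )
  outs <- lapply(variants, function(cf)
    dpfnet_forward(x, dpfnet_init(cf, 5), cf))
  for (o in outs) expect_equal(dim(o$main), c(ps, ps, ps, 2L))
  # no detail branch: no detail aux head, no DAM/CFM parameters
  expect_null(outs$no_detail$aux_detail)
  nm2 <- names(dpfnet_init(variants$no_detail, 1))
  expect_false(any(grepl("^(d[1-3]|dam|cfm|auxd)", nm2)))
  # no DAM: detail features reach the decoder directly (dam.* absent)
  expect_false(any(grepl("^dam", names(dpfnet_init(variants$no_dam, 1)))))
  # no CFM: branches stay independent until the decoder
  expect_false(any(grepl("^cfm", names(dpfnet_init(variants$no_cfm, 1)))))
  # deep supervision off removes every auxiliary output
  cfg_ds <- tiny_cfg(ps, enable_deep_supervision = FALSE)
  out_ds <- dpfnet_forward(x, dpfnet_init(cfg_ds, 6), cfg_ds)
  expect_named(out_ds, "main")
})

test_that("parameter counting equals closed-form and brute-force counts", {
  # single conv block, cin 1 -> cout 8: 27*8 kernel + 2*8 instance norm
  one <- network_config(semantic_widths = c(8L, 8L, 8L), detail_width = 8L,
                        patch_size = 16L)
  shapes <- dpfnet:::dpf_param_shapes(one)
  expect_equal(prod(shapes[["s1.1.W"]]) + sum(shapes[["s1.1.g"]],
                                              shapes[["s1.1.b"]]), 232)
  # reference configuration against the block-by-block closed form
  ref <- network_config()
  cp <- count_parameters(ref)
  expect_equal(cp$count, closed_form_param_count(12, 24, 49, 12))
  # oracle equivalence: count == total length of the instantiated arrays
  P <- dpfnet_init(ref, 1)
  expect_equal(cp$count, sum(vapply(P, length, numeric(1))))
  expect_error(network_config(semantic_widths = c(0L, 8L, 8L)), "positive")
  expect_error(network_config(dam_kernels = c(2L, 3L, 5L, 7L)), "odd")
})

test_that("checkpoints are self-describing round trips", {
  dir <- withr::local_tempdir()
  cfg <- tiny_cfg(16L)
  P <- dpfnet_init(cfg, 9)
  p <- file.path(dir, "model.rds")
  save_model(P, cfg, p, meta = list(iteration = 3L))
  m <- load_model(p)
  expect_identical(m$params, P)
  expect_identical(m$config, cfg)
  expect_equal(m$meta$iteration, 3L)
})
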
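#' Network configuration for the dual-path fusion network
#'
#' Defines the architecture of the two-branch segmentation network: a
#' semantic branch that down-samples twice (2x2x2 average pooling between
#' its three stages) and a detail branch that keeps full resolution, linked
#' by cross-fusion modules (CFM) and closed by a detail aggregation module
#' (DAM) whose kernel pyramid defaults to 1/3/5/7. Each toggle corresponds
#' to one ablation variant of the architecture.
#'
#' The default channel widths are the reference configuration calibrated so
#' that the float32 parameter storage reported by [count_parameters()]
#' rounds to 1.45 MB, the published size of the network.
#'
#' @param in_channels Number of input image channels (1 for DSA volumes, 4
#'   for multi-modal MRI).
#' @param num_classes Number of output classes including background.
#' @param semantic_widths Integer vector `(C1, C2, C3)`: channels of the
#'   three semantic stages.
#' @param detail_width Channels `Cd` of the detail branch (constant across
#'   its stages).
#' @param dam_kernels Four odd kernel sizes of the DAM pyramid.
#' @param enable_detail_branch,enable_cfm,enable_dam,enable_deep_supervision
#'   Ablation toggles. Disabling the detail branch implies no CFM, no DAM
#'   and no detail auxiliary head.
#' @param patch_size Training/inference patch edge length; must be
#'   divisible by 4 (two 2x poolings).
#' @return An object of class `dpf_net_config`.
#' @export
network_config <- function(in_channels = 1L, num_classes = 2L,
                           semantic_widths = c(12L, 24L, 49L),
                           detail_width = 12L,
                           dam_kernels = c(1L, 3L, 5L, 7L),
                           enable_detail_branch = TRUE,
                           enable_cfm = TRUE,
                           enable_dam = TRUE,
                           enable_deep_supervision = TRUE,
                           patch_size = 64L) {
  if (length(semantic_widths) != 3L || any(semantic_widths <= 0))
    stop("semantic_widths must be three positive channel counts")
  if (detail_width <= 0) stop("detail_width must be positive")
  if (length(dam_kernels) != 4L || any(dam_kernels %% 2L == 0L))
    stop("dam_kernels must be four odd kernel sizes")
  if (patch_size %% 4L != 0L) stop("patch_size must be divisible by 4")
  if (in_channels < 1L || num_classes < 2L)
    stop("need at least one input channel and two classes")
  cfg <- list(in_channels = as.integer(in_channels),
              num_classes = as.integer(num_classes),
              semantic_widths = as.integer(semantic_widths),
              detail_width = as.integer(detail_width),
              dam_kernels = as.integer(dam_kernels),
              enable_detail_branch = isTRUE(enable_detail_branch),
              enable_cfm = isTRUE(enable_cfm),
              enable_dam = isTRUE(enable_dam),
              enable_deep_supervision = isTRUE(enable_deep_supervision),
              patch_size = as.integer(patch_size))
  class(cfg) <- "dpf_net_config"
  cfg
}

# One row per learnable block. type: "conv" (conv + IN + ReLU or the conv
# inside a residual block), "tconv" (2x2x2 transposed conv + IN + ReLU),
# "logit" (k^3 conv + bias, no normalization).
dpf_block_defs <- function(cfg) {
  C <- cfg$semantic_widths
  Cd <- cfg$detail_width
  nc <- cfg$num_classes
  ic <- cfg$in_channels
  defs <- list()
  add <- function(name, type, k, cin, cout, stride = 1L) {
    defs[[length(defs) + 1L]] <<- list(name = name, type = type, k = k,
                                       cin = cin, cout = cout, stride = stride)
  }
  stage <- function(pre, cin, cout) {
    add(paste0(pre, ".1"), "conv", 3L, cin, cout)
    add(paste0(pre, ".2"), "conv", 3L, cout, cout)
    add(paste0(pre, ".3"), "conv", 3L, cout, cout)
  }
  stage("s1", ic, C[1])
  stage("s2", C[1], C[2])
  stage("s3", C[2], C[3])
  if (cfg$enable_detail_branch) {
    stage("d1", ic, Cd)
    stage("d2", Cd, Cd)
    stage("d3", Cd, Cd)
    if (cfg$enable_cfm) {
      add("cfm2.down", "conv", 3L, Cd, C[2], 2L)
      add("cfm2.up.c", "conv", 3L, C[2], Cd)
      add("cfm2.up.t1", "tconv", 2L, Cd, Cd)
      add("cfm3.down1", "conv", 3L, Cd, Cd, 2L)
      add("cfm3.down2", "conv", 3L, Cd, C[3], 2L)
      add("cfm3.up.c", "conv", 3L, C[3], Cd)
      add("cfm3.up.t1", "tconv", 2L, Cd, Cd)
      add("cfm3.up.t2", "tconv", 2L, Cd, Cd)
    }
    if (cfg$enable_dam) {
      for (i in 1:4)
        add(paste0("dam.k", i), "conv", cfg$dam_kernels[i], Cd, Cd)
      add("dam.mix", "conv", 1L, Cd, Cd)
    }
  }
  add("dec.t1", "tconv", 2L, C[3], Cd)
  add("dec.t2", "tconv", 2L, Cd, Cd)
  add("dec.out", "logit", 3L, Cd, nc)
  if (cfg$enable_deep_supervision) {
    add("auxs.t1", "tconv", 2L, C[3], Cd)
    add("auxs.t2", "tconv", 2L, Cd, Cd)
    add("auxs.out", "logit", 3L, Cd, nc)
    if (cfg$enable_detail_branch)
      add("auxd.out", "logit", 3L, Cd, nc)
  }
  defs
}

dpf_param_shapes <- function(cfg) {
  shapes <- list()
  for (d in dpf_block_defs(cfg)) {
    shapes[[paste0(d$name, ".W")]] <- c(d$k, d$k, d$k, d$cin, d$cout)
    if (d$type == "logit") {
      shapes[[paste0(d$name, ".bias")]] <- d$cout
    } else {
      shapes[[paste0(d$name, ".g")]] <- d$cout
      shapes[[paste0(d$name, ".b")]] <- d$cout
    }
  }
  shapes
}

#' Count learnable parameters and float32 storage
#'
#' Enumerates every learnable array of the configured network (convolution
#' and transposed-convolution kernels, instance-norm scale/shift pairs and
#' logit-head biases) and reports the exact count plus its float32 storage
#' footprint in MB (2^20 bytes), rounded to two decimals. With the default
#' reference configuration the storage rounds to 1.45 MB.
#'
#' @param cfg A [network_config()].
#' @return A list with elements `count` and `storage_mb`.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "dpf_net_config"))
  n <- sum(vapply(dpf_param_shapes(cfg), prod, numeric(1)))
  list(count = as.integer(n), storage_mb = round(4 * n / 2^20, 2))
}

#' Initialize network weights
#'
#' He-normal initialization for convolution kernels (fan-in = k^3 * cin)
#' and scale 1 / shift 0 for instance norm. The logit-head biases start at
#' a background prior (`-4` on every foreground class, i.e. about 2%
#' initial foreground probability): with foreground below 0.2% of voxels
#' an indifferent start wastes most of the early Dice gradient on pushing
#' down background, so the head starts near the class prior instead.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed pinning the draw.
#' @param fg_prior_logit Initial logit offset of the foreground classes.
#' @return Named list of parameter arrays.
#' @export
dpfnet_init <- function(cfg, seed = 1L, fg_prior_logit = -4) {
  shapes <- dpf_param_shapes(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  P <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    if (endsWith(nm, ".W")) {
      fan_in <- prod(sh[1:4])
      P[[nm]] <- array(rnorm(prod(sh), sd = sqrt(2 / fan_in)), sh)
    } else if (endsWith(nm, ".g")) {
      P[[nm]] <- rep(1, sh)
    } else if (endsWith(nm, ".bias")) {
      P[[nm]] <- c(0, rep(fg_prior_logit, sh - 1L))
    } else {
      P[[nm]] <- rep(0, sh)
    }
  }
  P
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# ---- forward graph ---------------------------------------------------------

# Node-level forward pass. P: parameter list (environment also accepted),
# tp/G: tape and gradient environment (NULL for inference).
dpf_forward_nodes <- function(x, P, cfg, tp = NULL, G = NULL) {
  pget <- if (is.environment(P)) function(n) get(n, envir = P) else function(n) P[[n]]
  Penv <- if (is.environment(P)) P else list2env(P, parent = emptyenv())

  cb <- function(nd, pre, stride = 1L) {
    op_relu(tp, op_instnorm(tp, Penv, G,
      op_conv(tp, Penv, G, nd, paste0(pre, ".W"), stride),
      paste0(pre, ".g"), paste0(pre, ".b")))
  }
  # residual ordering: conv -> IN -> add identity -> ReLU
  rb <- function(nd, pre) {
    op_relu(tp, op_add(tp, op_instnorm(tp, Penv, G,
      op_conv(tp, Penv, G, nd, paste0(pre, ".W")),
      paste0(pre, ".g"), paste0(pre, ".b")), nd))
  }
  tb <- function(nd, pre) {
    op_relu(tp, op_instnorm(tp, Penv, G,
      op_tconv2(tp, Penv, G, nd, paste0(pre, ".W")),
      paste0(pre, ".g"), paste0(pre, ".b")))
  }
  lg <- function(nd, pre) {
    op_bias(tp, Penv, G, op_conv(tp, Penv, G, nd, paste0(pre, ".W")),
            paste0(pre, ".bias"))
  }
  stage <- function(nd, pre) rb(rb(cb(nd, paste0(pre, ".1")), paste0(pre, ".2")),
                                paste0(pre, ".3"))

  xin <- if (inherits(x, "environment")) x else ag_node(x)
  det <- cfg$enable_detail_branch

  s1 <- stage(xin, "s1")
  s2 <- stage(op_avgpool2(tp, s1), "s2")
  if (det) {
    d1 <- stage(xin, "d1")
    d2 <- stage(d1, "d2")
    if (cfg$enable_cfm) {
      s2f <- op_add(tp, s2, cb(d2, "cfm2.down", 2L))
      d2f <- op_add(tp, d2, tb(cb(s2, "cfm2.up.c"), "cfm2.up.t1"))
    } else {
      s2f <- s2; d2f <- d2
    }
  } else {
    s2f <- s2
  }
  s3 <- stage(op_avgpool2(tp, s2f), "s3")
  if (det) {
    d3 <- stage(d2f, "d3")
    if (cfg$enable_cfm) {
      s3f <- op_add(tp, s3, cb(cb(d3, "cfm3.down1", 2L), "cfm3.down2", 2L))
      d3f <- op_add(tp, d3, tb(tb(cb(s3, "cfm3.up.c"), "cfm3.up.t1"), "cfm3.up.t2"))
    } else {
      s3f <- s3; d3f <- d3
    }
    dam <- if (cfg$enable_dam) {
      pyr <- op_scale_add(tp, list(cb(d3f, "dam.k1"), cb(d3f, "dam.k2"),
                                   cb(d3f, "dam.k3"), cb(d3f, "dam.k4")),
                          rep(1, 4))
      cb(pyr, "dam.mix")
    } else {
      d3f
    }
  } else {
    s3f <- s3
  }

  up <- tb(tb(s3f, "dec.t1"), "dec.t2")
  fused <- if (det) op_add(tp, up, dam) else up
  out <- list(main = lg(fused, "dec.out"))
  if (cfg$enable_deep_supervision) {
    out$aux_semantic <- lg(tb(tb(s3f, "auxs.t1"), "auxs.t2"), "auxs.out")
    if (det) out$aux_detail <- lg(d3f, "auxd.out")
  }
  out
}

#' Forward pass of the dual-path network
#'
#' Runs a patch through the network and returns per-head logits at full
#' input resolution. The input spatial extent must be divisible by 4.
#'
#' @param x Numeric array, either `(d, h, w)` single-channel or
#'   `(d, h, w, channels)`.
#' @param params Parameter list from [dpfnet_init()] (or a trained model).
#' @param cfg The [network_config()] the parameters were built for.
#' @return List with `main` logits `(d, h, w, num_classes)` and, when deep
#'   supervision is enabled, `aux_semantic` and (with the detail branch)
#'   `aux_detail` logits of the same shape.
#' @export
dpfnet_forward <- function(x, params, cfg) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[4] != cfg$in_channels)
    stop("input has ", dim(x)[4], " channels; config expects ", cfg$in_channels)
  if (any(dim(x)[1:3] %% 4L != 0L))
    stop("patch extents must be divisible by 4")
  nodes <- dpf_forward_nodes(x, params, cfg, tp = NULL, G = NULL)
  lapply(nodes, function(nd) nd$v)
}

#' Per-class probabilities for one patch
#'
#' [dpfnet_forward()] followed by a channel softmax on the main logits.
#'
#' @inheritParams dpfnet_forward
#' @return Array `(d, h, w, num_classes)` of probabilities summing to 1
#'   over the class axis.
#' @export
dpfnet_predict_patch <- function(x, params, cfg) {
  logits <- dpfnet_forward(x, params, cfg)$main
  softmax_channels(logits)
}

softmax_channels <- function(logits) {
  dm <- dim(logits)
  m <- matrix(logits, prod(dm[1:3]), dm[4])
  m <- exp(m - apply(m, 1, max))
  array(m / rowSums(m), dm)
}

# ---- standalone block operations (exported surface for the architecture) ---

#' Convolutional block: k^3 convolution + instance norm + ReLU
#'
#' @param x Feature array `(d, h, w, cin)`.
#' @param W Kernel `(k, k, k, cin, cout)`.
#' @param gamma,beta Instance-norm scale and shift, length `cout`.
#' @param stride 1 (shape-preserving, same padding) or 2 (ceil-halving).
#' @return Feature array with `cout` channels.
#' @export
conv_block <- function(x, W, gamma, beta, stride = 1L) {
  P <- list2env(list(W = W, g = gamma, b = beta), parent = emptyenv())
  nd <- op_relu(NULL, op_instnorm(NULL, P, NULL,
    op_conv(NULL, P, NULL, ag_node(x), "W", stride), "g", "b"))
  nd$v
}

#' Residual convolutional block
#'
#' conv -> instance norm -> add identity -> ReLU. Input and output channel
#' counts must match for the identity sum.
#'
#' @inheritParams conv_block
#' @export
residual_block <- function(x, W, gamma, beta) {
  if (dim(W)[4] != dim(W)[5] || dim(x)[4] != dim(W)[4])
    stop("residual_block needs matching input/output channels")
  P <- list2env(list(W = W, g = gamma, b = beta), parent = emptyenv())
  xin <- ag_node(x)
  nd <- op_relu(NULL, op_add(NULL, op_instnorm(NULL, P, NULL,
    op_conv(NULL, P, NULL, xin, "W"), "g", "b"), xin))
  nd$v
}

#' Semantic branch features
#'
#' Three stages of (conv block + two residual blocks) with 2x2x2 average
#' pooling between stages: `S1` at full resolution with `C1` channels,
#' `S2` at 1/2 with `C2`, `S3` at 1/4 with `C3`.
#'
#' @param x Input array `(d, h, w, in_channels)`, extents divisible by 4.
#' @param params,cfg Parameters and configuration of the full network.
#' @return List of arrays `S1`, `S2`, `S3`.
#' @export
semantic_branch <- function(x, params, cfg) {
  sub <- run_branch(x, params, cfg, c("s1", "s2", "s3"), pool = TRUE)
  setNames(sub, c("S1", "S2", "S3"))
}

#' Detail branch features
#'
#' Same stage layout as the semantic branch but at constant full resolution
#' with `Cd` channels throughout.
#'
#' @inheritParams semantic_branch
#' @return List of arrays `D1`, `D2`, `D3` (all full resolution).
#' @export
detail_branch <- function(x, params, cfg) {
  if (!cfg$enable_detail_branch) stop("detail branch disabled in this config")
  sub <- run_branch(x, params, cfg, c("d1", "d2", "d3"), pool = FALSE)
  setNames(sub, c("D1", "D2", "D3"))
}

run_branch <- function(x, params, cfg, prefixes, pool) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  P <- list2env(params, parent = emptyenv())
  cb <- function(nd, pre, stride = 1L)
    op_relu(NULL, op_instnorm(NULL, P, NULL,
      op_conv(NULL, P, NULL, nd, paste0(pre, ".W"), stride),
      paste0(pre, ".g"), paste0(pre, ".b")))
  rb <- function(nd, pre)
    op_relu(NULL, op_add(NULL, op_instnorm(NULL, P, NULL,
      op_conv(NULL, P, NULL, nd, paste0(pre, ".W")),
      paste0(pre, ".g"), paste0(pre, ".b")), nd))
  out <- list()
  nd <- ag_node(x)
  for (i in seq_along(prefixes)) {
    if (pool && i > 1L) nd <- op_avgpool2(NULL, nd)
    pre <- prefixes[i]
    nd <- rb(rb(cb(nd, paste0(pre, ".1")), paste0(pre, ".2")), paste0(pre, ".3"))
    out[[i]] <- nd$v
  }
  out
}

#' Cross-fusion module
#'
#' Bidirectional exchange between the branches at a resolution gap of
#' `2^p`: the detail stream receives the semantic features compressed by a
#' 3^3 convolutional block and upsampled through `p` deconvolution blocks;
#' the semantic stream receives the detail features down-sampled through
#' `p` stride-2 3^3 convolutional blocks. Both contributions are added
#' element-wise.
#'
#' @param sem Semantic features at 1/2^p resolution.
#' @param det Detail features at full resolution (`Cd` channels).
#' @param p Pooling depth separating the two streams (1 or 2).
#' @param params,cfg Parameters and configuration of the full network.
#' @return List with fused `sem` and `det` arrays (shapes unchanged).
#' @export
cross_fusion <- function(sem, det, p, params, cfg) {
  if (!cfg$enable_cfm) stop("cross-fusion disabled in this config")
  if (!p %in% c(1L, 2L)) stop("p must be 1 or 2")
  if (any(dim(det)[1:3] != dim(sem)[1:3] * 2L^p))
    stop("detail/semantic extents must differ by a factor 2^p")
  P <- list2env(params, parent = emptyenv())
  cb <- function(nd, pre, stride = 1L)
    op_relu(NULL, op_instnorm(NULL, P, NULL,
      op_conv(NULL, P, NULL, nd, paste0(pre, ".W"), stride),
      paste0(pre, ".g"), paste0(pre, ".b")))
  tb <- function(nd, pre)
    op_relu(NULL, op_instnorm(NULL, P, NULL,
      op_tconv2(NULL, P, NULL, nd, paste0(pre, ".W")),
      paste0(pre, ".g"), paste0(pre, ".b")))
  semn <- ag_node(sem); detn <- ag_node(det)
  if (p == 1L) {
    semf <- op_add(NULL, semn, cb(detn, "cfm2.down", 2L))
    detf <- op_add(NULL, detn, tb(cb(semn, "cfm2.up.c"), "cfm2.up.t1"))
  } else {
    semf <- op_add(NULL, semn, cb(cb(detn, "cfm3.down1", 2L), "cfm3.down2", 2L))
    detf <- op_add(NULL, detn, tb(tb(cb(semn, "cfm3.up.c"), "cfm3.up.t1"), "cfm3.up.t2"))
  }
  list(sem = semf$v, det = detf$v)
}

#' Detail aggregation module
#'
#' Kernel pyramid (defaults 1/3/5/7) of convolutional blocks whose outputs
#' are summed element-wise and mixed by a 1^3 convolutional block; spatial
#' shape is preserved by same-padding.
#'
#' @param x Detail features `(d, h, w, Cd)`.
#' @param params,cfg Parameters and configuration of the full network.
#' @return Aggregated features, same shape as `x`.
#' @export
detail_aggregation <- function(x, params, cfg) {
  if (!cfg$enable_dam) stop("detail aggregation disabled in this config")
  P <- list2env(params, parent = emptyenv())
  cb <- function(nd, pre)
    op_relu(NULL, op_instnorm(NULL, P, NULL,
      op_conv(NULL, P, NULL, nd, paste0(pre, ".W")),
      paste0(pre, ".g"), paste0(pre, ".b")))
  xin <- ag_node(x)
  pyr <- op_scale_add(NULL, list(cb(xin, "dam.k1"), cb(xin, "dam.k2"),
                                 cb(xin, "dam.k3"), cb(xin, "dam.k4")), rep(1, 4))
  cb(pyr, "dam.mix")$v
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the weights together with
#' the exact configuration used to build them (self-describing) plus
#' training metadata.
#'
#' @param params Parameter list.
#' @param cfg The matching [network_config()].
#' @param path Destination file.
#' @param meta Optional list of training metadata (iteration, seed, ...).
#' @return `save_model` returns `path` invisibly; `load_model` returns a
#'   list with `params`, `config` and `meta`.
#' @export
save_model <- function(params, cfg, path, meta = list()) {
  saveRDS(list(params = params, config = cfg, meta = meta), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m$config, "dpf_net_config"))
  m
}
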
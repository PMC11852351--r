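# Minimal reverse-mode autodiff for the fixed dual-path graph.
#
# Values are plain R arrays wrapped in "node" environments ($v value,
# $g accumulated cotangent). Differentiable ops append a backward closure
# to a tape; ag_backward() replays the tape in reverse. Parameters live in
# an environment keyed by name; their gradients are accumulated into a
# second environment so batches can be averaged across successive tapes.
# With tape = NULL every op runs in pure inference mode (no recording).
#
# Feature grids are (d, h, w, channels); kernels (k, k, k, cin, cout).

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$ops <- list()
  tp$k <- 0L
  tp
}

ag_node <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e
}

ag_push <- function(tp, fn) {
  if (!is.null(tp)) {
    tp$k <- tp$k + 1L
    tp$ops[[tp$k]] <- fn
  }
  invisible(NULL)
}

ag_acc <- function(nd, g) {
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

ag_acc_param <- function(gr, name, g) {
  gr[[name]] <- if (is.null(gr[[name]])) g else gr[[name]] + g
  invisible(NULL)
}

# Replay a tape backwards; cotangents must already be seeded on the
# output node(s).
ag_run_backward <- function(tp) {
  if (tp$k > 0L) {
    for (i in tp$k:1L) tp$ops[[i]]()
  }
  invisible(NULL)
}

# Run the tape backwards from a scalar loss node.
ag_backward <- function(tp, loss) {
  loss$g <- 1
  ag_run_backward(tp)
}

# ---- primitive ops ---------------------------------------------------------

# 3^3 (or k^3) convolution, no bias; pad chosen so stride-1 preserves shape
# and stride-2 halves it (ceiling) for odd k.
op_conv <- function(tp, P, G, x, wname, stride = 1L, pad = NULL) {
  W <- P[[wname]]
  k <- dim(W)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  y <- ag_node(cpp_conv3d_fw(x$v, W, as.integer(stride), as.integer(pad)))
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    bw <- cpp_conv3d_bw(x$v, W, y$g, as.integer(stride), as.integer(pad))
    ag_acc(x, bw$gx)
    ag_acc_param(G, wname, bw$gW)
  })
  y
}

# Per-channel bias add (used only by the logit heads).
op_bias <- function(tp, P, G, x, bname) {
  b <- P[[bname]]
  dm <- dim(x$v)
  nsp <- prod(dm[1:3])
  y <- ag_node(x$v + rep(b, each = nsp))
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    ag_acc(x, y$g)
    ag_acc_param(G, bname, colSums(matrix(y$g, nsp, dm[4])))
  })
  y
}

# Instance normalization with learned per-channel scale/shift.
op_instnorm <- function(tp, P, G, x, gname, bname, eps = 1e-5) {
  gam <- P[[gname]]
  fw <- cpp_instnorm_fw(x$v, gam, P[[bname]], eps)
  y <- ag_node(fw$y)
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    bw <- cpp_instnorm_bw(x$v, fw$mu, fw$istd, gam, y$g)
    ag_acc_param(G, gname, bw$ggamma)
    ag_acc_param(G, bname, bw$gbeta)
    ag_acc(x, bw$gx)
  })
  y
}

op_relu <- function(tp, x) {
  y <- ag_node((x$v + abs(x$v)) * 0.5)
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    ag_acc(x, y$g * (y$v > 0))
  })
  y
}

op_add <- function(tp, a, b) {
  y <- ag_node(a$v + b$v)
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    ag_acc(a, y$g)
    ag_acc(b, y$g)
  })
  y
}

# 2x2x2 average pooling, stride 2; spatial extents must be even.
op_avgpool2 <- function(tp, x) {
  dm <- dim(x$v)
  if (any(dm[1:3] %% 2L != 0L)) stop("avgpool2: spatial extents must be even")
  i1 <- seq(1L, dm[1], 2L); i2 <- seq(2L, dm[1], 2L)
  j1 <- seq(1L, dm[2], 2L); j2 <- seq(2L, dm[2], 2L)
  l1 <- seq(1L, dm[3], 2L); l2 <- seq(2L, dm[3], 2L)
  v <- (x$v[i1, j1, l1, , drop = FALSE] + x$v[i2, j1, l1, , drop = FALSE] +
        x$v[i1, j2, l1, , drop = FALSE] + x$v[i2, j2, l1, , drop = FALSE] +
        x$v[i1, j1, l2, , drop = FALSE] + x$v[i2, j1, l2, , drop = FALSE] +
        x$v[i1, j2, l2, , drop = FALSE] + x$v[i2, j2, l2, , drop = FALSE]) / 8
  y <- ag_node(v)
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    gx <- array(0, dm)
    g8 <- y$g / 8
    for (ii in list(i1, i2)) for (jj in list(j1, j2)) for (ll in list(l1, l2))
      gx[ii, jj, ll, ] <- gx[ii, jj, ll, ] + g8
    ag_acc(x, gx)
  })
  y
}

# Transposed convolution, kernel 2, stride 2 (exact x2 upsampling), no bias.
# W: (2, 2, 2, cin, cout). Offsets are non-overlapping, so each of the eight
# output sub-lattices is a plain matrix product.
op_tconv2 <- function(tp, P, G, x, wname) {
  W <- P[[wname]]
  dm <- dim(x$v)
  cin <- dm[4]; cout <- dim(W)[5]
  n <- prod(dm[1:3])
  xm <- matrix(x$v, n, cin)
  od <- dm[1:3] * 2L
  y <- array(0, c(od, cout))
  idx <- list(seq(1L, od[1], 2L), seq(2L, od[1], 2L))
  jdx <- list(seq(1L, od[2], 2L), seq(2L, od[2], 2L))
  ldx <- list(seq(1L, od[3], 2L), seq(2L, od[3], 2L))
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    Wo <- matrix(W[a, b, cc, , ], cin, cout)
    y[idx[[a]], jdx[[b]], ldx[[cc]], ] <- array(xm %*% Wo, c(dm[1:3], cout))
  }
  yn <- ag_node(y)
  ag_push(tp, function() {
    if (is.null(yn$g)) return(invisible(NULL))
    gW <- array(0, dim(W))
    gx <- matrix(0, n, cin)
    for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
      Go <- matrix(yn$g[idx[[a]], jdx[[b]], ldx[[cc]], ], n, cout)
      gW[a, b, cc, , ] <- crossprod(xm, Go)
      gx <- gx + Go %*% t(matrix(W[a, b, cc, , ], cin, cout))
    }
    ag_acc_param(G, wname, gW)
    ag_acc(x, array(gx, dm))
  })
  yn
}

# Channel softmax (last axis).
op_softmax <- function(tp, x) {
  dm <- dim(x$v)
  nsp <- prod(dm[1:3])
  nc <- dm[4]
  xm <- x$v
  dim(xm) <- c(nsp, nc)
  mx <- xm[, 1]
  for (j in seq_len(nc)[-1]) mx <- pmax(mx, xm[, j])
  e <- exp(xm - mx)
  p <- e / .rowSums(e, nsp, nc)
  y <- ag_node(array(p, dm))
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    gy <- y$g
    dim(gy) <- c(nsp, nc)
    dot <- .rowSums(gy * p, nsp, nc)
    gx <- p * (gy - dot)
    dim(gx) <- dm
    ag_acc(x, gx)
  })
  y
}

# Soft Dice loss against a one-hot target, averaged over foreground classes.
# prob: (d,h,w,C) softmax output node; target: integer array of class indices
# (0-based) with the same spatial shape. Returns a scalar node.
op_dice_loss <- function(tp, prob, target, smooth_eps = 1e-5) {
  dm <- dim(prob$v)
  ncl <- dm[4]
  nsp <- prod(dm[1:3])
  pm <- matrix(prob$v, nsp, ncl)
  tvec <- as.integer(target)
  losses <- numeric(ncl - 1L)
  grads <- matrix(0, nsp, ncl)
  for (cl in seq_len(ncl - 1L)) {
    yc <- as.numeric(tvec == cl)
    pc <- pm[, cl + 1L]
    inter <- sum(pc * yc)
    card <- sum(pc) + sum(yc)
    num <- 2 * inter + smooth_eps
    den <- card + smooth_eps
    losses[cl] <- 1 - num / den
    # d loss / d pc = -(2*yc*den - num) / den^2
    grads[, cl + 1L] <- -(2 * yc * den - num) / (den * den)
  }
  y <- ag_node(mean(losses))
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    ag_acc(prob, array(y$g * grads / (ncl - 1L), dm))
  })
  y
}

op_scale_add <- function(tp, nodes, weights) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + weights[i] * nodes[[i]]$v
  y <- ag_node(v)
  ag_push(tp, function() {
    if (is.null(y$g)) return(invisible(NULL))
    for (i in seq_along(nodes)) ag_acc(nodes[[i]], weights[i] * y$g)
  })
  y
}
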
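# Multi-view mechanics: axis permutations, sliding-window patch grids,
# randomized training sampling with foreground bias, augmentation,
# overlap-averaged reconstruction and the two test-time fusion manners.

VIEW_PERMS <- list(axial = c(1L, 2L, 3L),
                   coronal = c(2L, 1L, 3L),   # (d,h,w) -> (h,d,w)
                   sagittal = c(3L, 2L, 1L))  # (d,h,w) -> (w,h,d)

#' Permute a volume into one of the three anatomical views
#'
#' From an axial grid `(d, h, w)` the coronal view is `(h, d, w)` and the
#' sagittal view `(w, h, d)`; the axial permutation is the identity. Both
#' non-trivial permutations are involutions, so [inverse_view()] applies
#' the same transposition back and restores the original grid bit-exactly.
#'
#' @param arr 3-D array in the axial frame.
#' @param view `"axial"`, `"coronal"` or `"sagittal"`.
#' @return The permuted array.
#' @export
permute_view <- function(arr, view) {
  if (length(dim(arr)) != 3L) stop("permute_view expects a 3-D grid")
  perm <- VIEW_PERMS[[match.arg(view, names(VIEW_PERMS))]]
  aperm(arr, perm)
}

#' @rdname permute_view
#' @export
inverse_view <- function(arr, view) {
  # all three permutations are self-inverse transpositions
  permute_view(arr, view)
}

#' Sliding-window patch grid
#'
#' Computes the zero-padded shape and the ordered list of 0-based window
#' origins that tile a volume with `patch_size^3` windows at the given
#' stride, covering every voxel. Windows start at every multiple of the
#' stride below the volume extent (a 96^3 volume with 64^3 patches at
#' stride 32 therefore has 3 origins per axis, 27 windows), and the volume
#' is zero-padded up to the last window's end.
#'
#' @param shape Integer spatial extents `(d, h, w)`.
#' @param patch_size Window edge length (divisible by 4).
#' @param stride Step between windows, `0 < stride <= patch_size`.
#' @return A `dpf_patch_grid`: `patch_size`, `stride`, `padded_shape`, and
#'   `origins` (matrix, one 0-based `(d, h, w)` corner per row, lexicographic
#'   order with the depth axis fastest).
#' @export
make_patch_grid <- function(shape, patch_size = 64L, stride = patch_size) {
  if (stride <= 0L) stop("stride must be positive")
  if (stride > patch_size) stop("stride must not exceed patch_size")
  if (patch_size %% 4L != 0L) stop("patch_size must be divisible by 4")
  shape <- as.integer(shape)
  steps <- as.integer(ceiling(shape / stride)) - 1L
  padded <- pmax(steps * stride + patch_size, patch_size)
  ax <- lapply(1:3, function(i) seq(0L, by = stride, length.out = steps[i] + 1L))
  origins <- as.matrix(expand.grid(d = ax[[1]], h = ax[[2]], w = ax[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 shape = shape, padded_shape = as.integer(padded),
                 origins = origins),
            class = "dpf_patch_grid")
}

pad_to <- function(arr, padded) {
  dm <- dim(arr)
  if (all(dm == padded)) return(arr)
  out <- array(0, padded)
  out[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- arr
  out
}

#' Extract the patches of a grid
#'
#' @param arr 3-D array (already in the view the grid was built for).
#' @param grid A [make_patch_grid()] for `dim(arr)`.
#' @return List of `patch_size^3` arrays, one per grid origin.
#' @export
extract_patches <- function(arr, grid) {
  ap <- pad_to(arr, grid$padded_shape)
  ps <- grid$patch_size
  lapply(seq_len(nrow(grid$origins)), function(i) {
    o <- grid$origins[i, ]
    ap[o[1] + seq_len(ps), o[2] + seq_len(ps), o[3] + seq_len(ps)]
  })
}

#' Reassemble per-patch probabilities into a full volume
#'
#' Overlap-weighted mean: each voxel of the output is the average of every
#' patch prediction covering it; the zero padding is cropped away. Exact
#' (not merely approximate) for constant fields and non-overlapping grids.
#'
#' @param prob_patches List of `(p, p, p, classes)` (or `(p, p, p)`)
#'   probability arrays, one per grid origin, in grid order.
#' @param grid The [make_patch_grid()] used for extraction.
#' @return List with `prob` (classes dropped if the patches were 3-D) and
#'   `weights` (coverage count per voxel, all `>= 1`).
#' @export
reconstruct <- function(prob_patches, grid) {
  if (length(prob_patches) != nrow(grid$origins))
    stop("expected ", nrow(grid$origins), " patches, got ", length(prob_patches))
  ps <- grid$patch_size
  d3 <- length(dim(prob_patches[[1]])) == 3L
  ncl <- if (d3) 1L else dim(prob_patches[[1]])[4]
  acc <- array(0, c(grid$padded_shape, ncl))
  wt <- array(0, grid$padded_shape)
  for (i in seq_len(nrow(grid$origins))) {
    o <- grid$origins[i, ]
    id <- o[1] + seq_len(ps); ih <- o[2] + seq_len(ps); iw <- o[3] + seq_len(ps)
    p <- prob_patches[[i]]
    if (d3) dim(p) <- c(ps, ps, ps, 1L)
    acc[id, ih, iw, ] <- acc[id, ih, iw, , drop = FALSE] + p
    wt[id, ih, iw] <- wt[id, ih, iw] + 1
  }
  sd_ <- seq_len(grid$shape[1]); sh <- seq_len(grid$shape[2]); sw <- seq_len(grid$shape[3])
  acc <- acc[sd_, sh, sw, , drop = FALSE]
  wt <- wt[sd_, sh, sw, drop = FALSE]
  prob <- sweep(acc, 1:3, wt, `/`)
  if (d3) dim(prob) <- grid$shape
  list(prob = prob, weights = wt)
}

#' Sample a randomized multi-view training batch
#'
#' Each sample draws a case uniformly, a view uniformly from axial /
#' coronal / sagittal, and a patch origin in the permuted frame; with
#' probability `fg_bias` the window is constrained to contain at least one
#' foreground voxel (when the case has any), counteracting the extreme
#' class imbalance of aneurysm volumes. Image and mask are cropped
#' identically.
#'
#' @param cases List of cases, each a list with `image` (3-D array, unit
#'   scaled) and `mask` (congruent integer array).
#' @param batch_size Number of samples.
#' @param patch_size Patch edge length.
#' @param fg_bias Probability of forcing a foreground-containing window.
#' @param augment Apply [augment_patch()] to every sample.
#' @return List of `batch_size` lists with `image`, `mask`, `view`,
#'   `origin` (0-based, permuted frame) and `case`.
#' @export
sample_training_batch <- function(cases, batch_size = 4L, patch_size = 32L,
                                  fg_bias = 0.5, augment = TRUE) {
  if (length(cases) == 0L) stop("no cases to sample from")
  views <- names(VIEW_PERMS)
  out <- vector("list", batch_size)
  for (s in seq_len(batch_size)) {
    ci <- sample.int(length(cases), 1L)
    vw <- views[sample.int(3L, 1L)]
    img <- permute_view(cases[[ci]]$image, vw)
    msk <- permute_view(cases[[ci]]$mask, vw)
    dm <- dim(img)
    if (any(dm < patch_size)) stop("case smaller than patch size")
    maxo <- dm - patch_size  # 0-based origin range
    fg <- NULL
    if (runif(1) < fg_bias) {
      fgi <- which(msk != 0L)
      if (length(fgi)) fg <- arrayInd(fgi[sample.int(length(fgi), 1L)], dm) - 1L
    }
    origin <- integer(3)
    for (ax in 1:3) {
      if (is.null(fg)) {
        origin[ax] <- sample.int(maxo[ax] + 1L, 1L) - 1L
      } else {
        lo <- max(0L, fg[ax] - patch_size + 1L)
        hi <- min(maxo[ax], fg[ax])
        origin[ax] <- if (hi > lo) sample(lo:hi, 1L) else lo
      }
    }
    idx <- lapply(1:3, function(ax) origin[ax] + seq_len(patch_size))
    pi_ <- img[idx[[1]], idx[[2]], idx[[3]]]
    pm <- msk[idx[[1]], idx[[2]], idx[[3]]]
    if (augment) {
      ap <- augment_patch(pi_, pm)
      pi_ <- ap$image; pm <- ap$mask
    }
    out[[s]] <- list(image = pi_, mask = pm, view = vw, origin = origin, case = ci)
  }
  out
}

#' Random augmentation of a paired image/mask patch
#'
#' Geometric operations (axis flips with probability 1/2 each, a random
#' multiple of 90 degrees in the in-plane axes) are applied identically to
#' image and mask with no interpolation, so labels stay crisp and the mask
#' foreground count is invariant. Photometric jitter — intensity scale
#' `U(0.9, 1.1)`, shift `U(-0.05, 0.05)` and additive Gaussian noise
#' (`noise_sd`, on the unit intensity scale) — touches the image only.
#'
#' @param image,mask Congruent 3-D arrays.
#' @param noise_sd Gaussian noise standard deviation.
#' @return List with augmented `image` and `mask`.
#' @export
augment_patch <- function(image, mask, noise_sd = 0.02) {
  for (ax in 1:3) {
    if (runif(1) < 0.5) {
      idx <- rev(seq_len(dim(image)[ax]))
      image <- flip_axis(image, ax, idx)
      mask <- flip_axis(mask, ax, idx)
    }
  }
  k <- sample(0:3, 1L)
  if (k > 0L) {
    image <- rot90_inplane(image, k)
    mask <- rot90_inplane(mask, k)
  }
  image <- image * runif(1, 0.9, 1.1) + runif(1, -0.05, 0.05)
  image <- image + array(rnorm(length(image), sd = noise_sd), dim(image))
  list(image = image, mask = mask)
}

flip_axis <- function(a, ax, idx) {
  switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# k * 90-degree rotation in the (h, w) plane of a (d, h, w) cube
rot90_inplane <- function(a, k) {
  for (i in seq_len(k %% 4L)) {
    a <- aperm(a, c(1L, 3L, 2L))
    a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  }
  a
}

#' Majority-vote fusion of three per-view masks
#'
#' A voxel is foreground iff at least two of the three (already
#' back-permuted) binary masks mark it.
#'
#' @param masks List of exactly three congruent 0/1 arrays.
#' @return Binary integer array.
#' @export
fuse_views_majority <- function(masks) {
  if (length(masks) != 3L) stop("majority voting needs exactly three masks")
  dm <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == dm), logical(1))))
    stop("masks must be congruent")
  votes <- (masks[[1]] != 0) + (masks[[2]] != 0) + (masks[[3]] != 0)
  array(as.integer(votes >= 2), dm)
}

#' Summation fusion of three per-view probability maps
#'
#' Foreground where the mean foreground probability over the views reaches
#' `threshold` — the "add" fusion manner, which trades the majority vote's
#' stability for higher sensitivity.
#'
#' @param probs List of exactly three congruent foreground-probability
#'   arrays.
#' @param threshold Decision threshold on the mean probability.
#' @return Binary integer array.
#' @export
fuse_views_sum <- function(probs, threshold = 0.5) {
  if (length(probs) != 3L) stop("summation fusion needs exactly three maps")
  dm <- dim(probs[[1]])
  if (!all(vapply(probs, function(m) all(dim(m) == dm), logical(1))))
    stop("probability maps must be congruent")
  array(as.integer((probs[[1]] + probs[[2]] + probs[[3]]) / 3 >= threshold), dm)
}

#' Label connected components of a binary mask
#'
#' @param mask 3-D binary array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  m <- array(as.integer(mask != 0), dim(mask))
  cpp_label_components(m, as.integer(connectivity))
}

#' Remove small connected components
#'
#' Post-processing that drops every connected foreground component with
#' fewer than `min_size` voxels (default 10, 26-connectivity) and leaves
#' the rest untouched. Idempotent; never adds voxels.
#'
#' @param mask 3-D binary array (or `dpf_mask`).
#' @param min_size Minimum voxel count for a component to survive.
#' @param connectivity 6 or 26.
#' @return Object of the same type as `mask`.
#' @export
filter_small_components <- function(mask, min_size = 10L, connectivity = 26L) {
  is_m <- inherits(mask, "dpf_mask")
  m <- if (is_m) mask$labels else mask
  lab <- label_components(m, connectivity)
  if (max(lab) > 0L) {
    keep <- which(tabulate(lab[lab > 0L]) >= min_size)
    m <- array(as.integer(lab %in% keep & m != 0L), dim(m))
  }
  if (is_m) {
    mask$labels <- m
    mask
  } else {
    m
  }
}
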
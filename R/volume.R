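#' Volumetric image and label-mask containers
#'
#' A `dpf_volume` wraps a numeric grid indexed `(depth, height, width)` —
#' or 4-D with a leading channel axis — together with its millimetre voxel
#' spacing and the view tag of its current axis order. A `dpf_mask` is the
#' integer counterpart holding segmentation labels drawn from a declared
#' label set.
#'
#' @param data Numeric 3-D array `(d, h, w)` or 4-D `(channels, d, h, w)`.
#' @param spacing Positive voxel spacing in mm, one value per spatial axis.
#' @param axis_order One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @return A `dpf_volume` object.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), axis_order = "axial") {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("volume data must be 3-D or 4-D (channel-first)")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive mm values")
  axis_order <- match.arg(axis_order, c("axial", "coronal", "sagittal"))
  structure(list(data = data, spacing = as.numeric(spacing),
                 axis_order = axis_order),
            class = "dpf_volume")
}

#' @param labels Integer 3-D array congruent with its paired volume.
#' @param label_set Allowed integer labels; defaults to binary `{0, 1}`.
#' @rdname as_volume
#' @return `as_mask` returns a `dpf_mask` object.
#' @export
as_mask <- function(labels, spacing = c(1, 1, 1), label_set = c(0L, 1L),
                    axis_order = "axial") {
  if (length(dim(labels)) != 3L) stop("mask must be a 3-D integer grid")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), as.integer(label_set))
  if (length(bad))
    stop("mask contains labels outside the label set: ", paste(bad, collapse = ", "))
  axis_order <- match.arg(axis_order, c("axial", "coronal", "sagittal"))
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 label_set = as.integer(label_set), axis_order = axis_order),
            class = "dpf_mask")
}

#' @export
print.dpf_volume <- function(x, ...) {
  cat("<dpf_volume> ", paste(dim(x$data), collapse = " x "),
      " | spacing ", paste(x$spacing, collapse = " x "), " mm | ",
      x$axis_order, " view\n", sep = "")
  invisible(x)
}

#' @export
print.dpf_mask <- function(x, ...) {
  cat("<dpf_mask> ", paste(dim(x$labels), collapse = " x "),
      " | spacing ", paste(x$spacing, collapse = " x "), " mm | labels {",
      paste(x$label_set, collapse = ", "), "} | foreground ",
      sum(x$labels != 0L), " voxels\n", sep = "")
  invisible(x)
}

#' Read a NIfTI volume or label mask
#'
#' Reads a `.nii` / `.nii.gz` file into a [as_volume()] container (or a
#' [as_mask()] when `as_mask = TRUE`), taking voxel spacing from the
#' header. The grid is tagged as axial; 4-D payloads are returned
#' channel-first.
#'
#' @param path Path to a NIfTI file.
#' @param mask Read as an integer label mask.
#' @param label_set Label set to validate against when `mask = TRUE`.
#' @return A `dpf_volume` or `dpf_mask`.
#' @export
read_volume <- function(path, mask = FALSE, label_set = c(0L, 1L)) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop RNifti header attributes
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L))
    stop("expected a 3-D or 4-D NIfTI payload, got ", nd, "-D")
  sp <- RNifti::pixdim(img)[1:3]
  if (mask) {
    if (nd != 3L) stop("label masks must be 3-D")
    return(as_mask(round(arr), spacing = sp, label_set = label_set))
  }
  if (nd == 4L) arr <- aperm(arr, c(4L, 1L, 2L, 3L))  # channel-first in memory
  as_volume(arr, spacing = sp)
}

#' Write a volume or mask to NIfTI
#'
#' Volumes are written as float32 (4-D volumes channel-last on disk, the
#' NIfTI convention); masks as int16. Voxel spacing is stored in the
#' header.
#'
#' @param v A `dpf_volume` or `dpf_mask`.
#' @param path Destination `.nii` or `.nii.gz` path; the parent directory
#'   must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (inherits(v, "dpf_mask")) {
    arr <- v$labels
    sp <- v$spacing
    dt <- "int16"
  } else if (inherits(v, "dpf_volume")) {
    arr <- v$data
    if (length(dim(arr)) == 4L) arr <- aperm(arr, c(2L, 3L, 4L, 1L))
    sp <- v$spacing
    dt <- "float"
  } else {
    stop("write_volume expects a dpf_volume or dpf_mask")
  }
  if (any(sp <= 0)) stop("spacing must be strictly positive")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp, rep(1, length(dim(arr)) - 3L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Truncate image intensities to a window
#'
#' Clamps every voxel to `[lo, hi]`. The defaults are the DSA
#' pre-processing window 1000--2500 used to suppress structures
#' irrelevant to aneurysm segmentation; shape and spacing are unchanged.
#'
#' @param v A `dpf_volume`.
#' @param lo,hi Window bounds, `lo < hi`.
#' @return The truncated `dpf_volume`.
#' @export
truncate_intensities <- function(v, lo = 1000, hi = 2500) {
  stopifnot(inherits(v, "dpf_volume"))
  if (lo >= hi) stop("truncation window requires lo < hi")
  v$data <- pmin(pmax(v$data, lo), hi)
  v
}

#' Rescale a truncated volume to the unit interval
#'
#' Affine map `(x - lo) / (hi - lo)` applied after
#' [truncate_intensities()]; values outside `[lo, hi]` are rejected.
#'
#' @inheritParams truncate_intensities
#' @return The rescaled `dpf_volume` with values in `[0, 1]`.
#' @export
rescale_unit <- function(v, lo = 1000, hi = 2500) {
  stopifnot(inherits(v, "dpf_volume"))
  if (lo >= hi) stop("rescale window requires lo < hi")
  rng <- range(v$data)
  if (rng[1] < lo || rng[2] > hi)
    stop("volume has values outside [", lo, ", ", hi, "]; truncate first")
  v$data <- (v$data - lo) / (hi - lo)
  v
}
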
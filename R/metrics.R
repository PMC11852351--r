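# Training losses (soft Dice + deep supervision) and evaluation metrics
# (DSC / Precision / Recall / IoU on complete scans), size stratification
# and multi-class region compositing.

#' Training-loss configuration
#'
#' @param beta1,beta2 Non-negative weights of the semantic- and
#'   detail-branch auxiliary Dice losses (both default to 1).
#' @param smooth_eps Small positive stabilizer added to the Dice numerator
#'   and denominator so empty patches stay differentiable.
#' @return A `dpf_loss_config` list.
#' @export
train_loss_config <- function(beta1 = 1, beta2 = 1, smooth_eps = 1e-5) {
  if (beta1 < 0 || beta2 < 0) stop("auxiliary weights must be non-negative")
  if (smooth_eps <= 0) stop("smooth_eps must be positive")
  structure(list(beta1 = beta1, beta2 = beta2, smooth_eps = smooth_eps),
            class = "dpf_loss_config")
}

target_labels <- function(target) {
  if (inherits(target, "dpf_mask")) target$labels else target
}

#' Soft Dice loss
#'
#' `1 - 2 |y .. yhat| / (|y| + |yhat|)` with soft intersection and
#' cardinalities computed from foreground probabilities, stabilized by
#' `smooth_eps`. For more than two classes the per-foreground-class losses
#' are averaged.
#'
#' @param pred Per-class probability array `(d, h, w, num_classes)`
#'   (channel rows summing to 1).
#' @param target A `dpf_mask` or integer array of class labels, spatially
#'   congruent with `pred`. Multi-class labels are matched against the
#'   sorted non-zero labels present in the prediction's class axis order.
#' @param smooth_eps Stabilizer, see [train_loss_config()].
#' @param class_labels Integer labels corresponding to prediction channels
#'   `2..num_classes`; defaults to `1:(num_classes-1)`.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(pred, target, smooth_eps = 1e-5,
                           class_labels = NULL) {
  tl <- target_labels(target)
  dm <- dim(pred)
  if (length(dm) != 4L) stop("pred must be (d, h, w, classes)")
  if (!all(dm[1:3] == dim(tl))) stop("pred/target shape mismatch")
  ncl <- dm[4]
  if (is.null(class_labels)) class_labels <- seq_len(ncl - 1L)
  pm <- matrix(pred, prod(dm[1:3]), ncl)
  tv <- as.integer(tl)
  losses <- vapply(seq_len(ncl - 1L), function(ci) {
    yc <- as.numeric(tv == class_labels[ci])
    pc <- pm[, ci + 1L]
    1 - (2 * sum(pc * yc) + smooth_eps) / (sum(pc) + sum(yc) + smooth_eps)
  }, numeric(1))
  mean(losses)
}

#' Composite deep-supervision loss
#'
#' `DL(main) + beta1 * DL(aux_semantic) + beta2 * DL(aux_detail)`. With
#' deep supervision disabled (no auxiliary outputs) only the main term is
#' used.
#'
#' @param outputs List of logits as returned by [dpfnet_forward()].
#' @param target A `dpf_mask` or integer label array.
#' @param cfg A [train_loss_config()].
#' @return Scalar loss.
#' @export
composite_loss <- function(outputs, target, cfg = train_loss_config()) {
  l <- soft_dice_loss(softmax_channels(outputs$main), target, cfg$smooth_eps)
  if (cfg$beta1 > 0 && !is.null(outputs$aux_semantic))
    l <- l + cfg$beta1 * soft_dice_loss(softmax_channels(outputs$aux_semantic),
                                        target, cfg$smooth_eps)
  if (cfg$beta2 > 0 && !is.null(outputs$aux_detail))
    l <- l + cfg$beta2 * soft_dice_loss(softmax_channels(outputs$aux_detail),
                                        target, cfg$smooth_eps)
  l
}

#' Overlap metrics for one complete scan
#'
#' DSC, Precision, Recall and IoU between a binary prediction and ground
#' truth. If both masks are empty all four metrics are defined as 1
#' (perfect agreement); if exactly one is empty, all are 0.
#'
#' @param pred,gt Binary `dpf_mask` objects or 0/1 arrays of equal shape.
#' @return Named list with `dsc`, `precision`, `recall`, `iou`.
#' @export
segmentation_metrics <- function(pred, gt) {
  p <- target_labels(pred) != 0L
  y <- target_labels(gt) != 0L
  if (!all(dim(p) == dim(y))) stop("pred/gt shape mismatch")
  np <- sum(p); ny <- sum(y)
  if (np == 0L && ny == 0L)
    return(list(dsc = 1, precision = 1, recall = 1, iou = 1))
  if (np == 0L || ny == 0L)
    return(list(dsc = 0, precision = 0, recall = 0, iou = 0))
  inter <- sum(p & y)
  list(dsc = 2 * inter / (np + ny),
       precision = inter / np,
       recall = inter / ny,
       iou = inter / (np + ny - inter))
}

#' Relative improvement between two metric values, in percent
#'
#' `100 * (a - b) / b`, rounded to two decimals — the convention used to
#' report one method's metric against a baseline's (e.g. DSC 0.8967 vs
#' 0.8038 is an 11.56% improvement).
#'
#' @param a,b Metric values; `b` must be positive.
#' @return Percentage, rounded to two decimals.
#' @export
relative_improvement <- function(a, b) {
  if (b <= 0) stop("baseline metric must be positive")
  round(100 * (a - b) / b, 2)
}

#' Aneurysm size group of a ground-truth mask
#'
#' Each connected foreground component (26-connectivity) is assigned an
#' equivalent-sphere diameter `2 * (3 V / 4 pi)^(1/3)` from its voxel count
#' and the voxel volume; the case is graded by its largest lesion with the
#' half-open thresholds Small (< 5 mm), Medium (5--15 mm), Large
#' (>= 15 mm).
#'
#' @param gt A non-empty binary `dpf_mask`, or a 0/1 array (then `spacing`
#'   must be given).
#' @param spacing Voxel spacing in mm (taken from the mask if omitted).
#' @return `"Small"`, `"Medium"` or `"Large"`.
#' @export
stratify_by_diameter <- function(gt, spacing = NULL) {
  m <- target_labels(gt)
  if (is.null(spacing)) {
    if (!inherits(gt, "dpf_mask")) stop("spacing required for plain arrays")
    spacing <- gt$spacing
  }
  if (sum(m != 0L) == 0L) stop("size group undefined for an empty mask")
  d <- component_diameters(m != 0L, spacing)
  size_group(max(d))
}

component_diameters <- function(bin, spacing) {
  lab <- label_components(bin, connectivity = 26L)
  counts <- tabulate(lab[lab > 0L])
  vox_vol <- prod(spacing)
  2 * (3 * counts * vox_vol / (4 * pi))^(1 / 3)
}

size_group <- function(d_mm) {
  ifelse(d_mm < 5, "Small", ifelse(d_mm < 15, "Medium", "Large"))
}

#' Composite tumor-region masks from multi-class labels
#'
#' Builds the three nested evaluation regions used for brain-tumor
#' segmentation from labels {0 background, 1 NCR/NET, 2 ED, 4 ET}:
#' Whole Tumor = NCR/NET + ED + ET, Tumor Core = NCR/NET + ET, and
#' Enhancing Tumor = ET alone, so WT contains TC contains ET.
#'
#' @param labels A `dpf_mask` or integer array with values in
#'   {0, 1, 2, 4}.
#' @return List of binary arrays `WT`, `TC`, `ET`.
#' @export
brats_regions <- function(labels) {
  m <- target_labels(labels)
  bad <- setdiff(unique(as.vector(m)), c(0L, 1L, 2L, 4L))
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  list(WT = (m == 1L | m == 2L | m == 4L) * 1L,
       TC = (m == 1L | m == 4L) * 1L,
       ET = (m == 4L) * 1L)
}
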
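# Training and inference orchestration: Adam with polynomial LR decay,
# k-fold splits, multi-view full-volume prediction and evaluation reports.

#' Training configuration
#'
#' Optimizer and schedule settings. Adam runs with first-moment decay 0.9
#' (the conventional reading of "momentum 0.9" for Adam) and second-moment
#' decay 0.999; the learning rate starts at `lr0` and decays by the factor
#' `(1 - iteration / total_iterations)^0.9` each iteration.
#'
#' @param lr0 Initial learning rate.
#' @param total_iterations Total optimizer steps.
#' @param batch_size Patches per step.
#' @param patch_size Patch edge length.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and stabilizer.
#' @param fg_bias Foreground-biased sampling probability
#'   (see [sample_training_batch()]).
#' @param augment Apply data augmentation during sampling.
#' @param seed Seed for weight init and batch sampling.
#' @param loss A [train_loss_config()].
#' @return A `dpf_train_config` list.
#' @export
train_config <- function(lr0 = 1e-4, total_iterations = 300L, batch_size = 4L,
                         patch_size = 32L, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         fg_bias = 0.5, augment = TRUE, seed = 1L,
                         loss = train_loss_config()) {
  if (lr0 <= 0) stop("lr0 must be positive")
  if (total_iterations < 1L) stop("total_iterations must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(lr0 = lr0, total_iterations = as.integer(total_iterations),
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, fg_bias = fg_bias,
                 augment = isTRUE(augment), seed = as.integer(seed),
                 loss = loss),
            class = "dpf_train_config")
}

#' Polynomial learning-rate decay
#'
#' `lr0 * (1 - iteration / total_iterations)^0.9`.
#'
#' @param iteration Current step, `0 <= iteration <= total_iterations`.
#' @param total_iterations Total steps.
#' @param lr0 Initial rate.
#' @param power Decay exponent.
#' @return The learning rate for this step.
#' @export
lr_schedule <- function(iteration, total_iterations, lr0 = 1e-4, power = 0.9) {
  if (iteration < 0 || iteration > total_iterations)
    stop("iteration must lie in [0, total_iterations]")
  lr0 * (1 - iteration / total_iterations)^power
}

#' Cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment into `k` pairwise
#' disjoint folds whose sizes differ by at most one.
#'
#' @param case_ids Character or integer vector of case identifiers.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of `k` vectors of case ids.
#' @export
make_folds <- function(case_ids, k = 5L, seed = 1L) {
  n <- length(case_ids)
  if (k > n) stop("more folds than cases")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(case_ids)
  split(shuffled, rep_len(seq_len(k), n))
}

# Load manifest cases into memory as unit-scaled image + mask arrays.
load_cases <- function(manifest, lo = 1000, hi = 2500) {
  lapply(seq_len(nrow(manifest)), function(i) {
    v <- read_volume(manifest$image_path[i])
    v <- rescale_unit(truncate_intensities(v, lo, hi), lo, hi)
    m <- read_volume(manifest$mask_path[i], mask = TRUE)
    list(image = v$data, mask = m$labels, spacing = v$spacing,
         case_id = manifest$case_id[i])
  })
}

#' Train the dual-path network
#'
#' Adam minimizes the composite deep-supervision Dice loss over randomized
#' multi-view patch batches; the learning rate follows [lr_schedule()].
#' Weight initialization and sampling are pinned by `train_cfg$seed`, so
#' two runs with identical seeds produce identical losses.
#'
#' @param cases List of in-memory cases (`image` unit-scaled array, `mask`
#'   integer array) as produced by `load_cases()`/[generate_phantom_case()];
#'   alternatively a manifest `data.frame` with `image_path`/`mask_path`
#'   columns.
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param checkpoint Optional path; the final model is saved there.
#' @param verbose Print the loss every 25 iterations.
#' @return List with `params`, `config`, and `loss_log` (data.frame of
#'   iteration, lr, loss).
#' @export
train_dpfnet <- function(cases, net_cfg, train_cfg = train_config(),
                         checkpoint = NULL, verbose = FALSE) {
  if (is.data.frame(cases)) cases <- load_cases(cases)
  if (length(cases) == 0L) stop("empty training set")
  cases <- lapply(cases, function(cs) {
    if (inherits(cs, "dpf_phantom_case")) {
      v <- rescale_unit(truncate_intensities(cs$image), 1000, 2500)
      list(image = v$data, mask = cs$mask$labels)
    } else cs
  })
  P <- dpfnet_init(net_cfg, seed = train_cfg$seed)
  opt <- adam_state(P)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(train_cfg$seed + 1L)
  n_iter <- train_cfg$total_iterations
  log <- data.frame(iteration = seq_len(n_iter), lr = NA_real_, loss = NA_real_)

  for (it in seq_len(n_iter)) {
    batch <- sample_training_batch(cases, train_cfg$batch_size,
                                   train_cfg$patch_size,
                                   fg_bias = train_cfg$fg_bias,
                                   augment = train_cfg$augment)
    G <- new.env(parent = emptyenv())
    # Forward every sample on its own tape, keeping the softmax heads; the
    # Dice cardinalities are then accumulated over the whole batch ("batch
    # Dice") so that aneurysm-free patches still contribute a
    # false-positive-suppressing gradient — with per-patch Dice an empty
    # patch's gradient vanishes with the stabilizer.
    tapes <- vector("list", length(batch))
    heads <- vector("list", length(batch))
    for (s in seq_along(batch)) {
      x <- batch[[s]]$image
      dim(x) <- c(dim(x), 1L)
      tp <- ag_tape()
      out <- dpf_forward_nodes(x, P, net_cfg, tp, G)
      ph <- list(main = op_softmax(tp, out$main))
      if (!is.null(out$aux_semantic))
        ph$aux_semantic <- op_softmax(tp, out$aux_semantic)
      if (!is.null(out$aux_detail))
        ph$aux_detail <- op_softmax(tp, out$aux_detail)
      tapes[[s]] <- tp
      heads[[s]] <- ph
    }
    wts <- c(main = 1, aux_semantic = train_cfg$loss$beta1,
             aux_detail = train_cfg$loss$beta2)
    tot <- 0
    eps <- train_cfg$loss$smooth_eps
    ncl <- net_cfg$num_classes
    for (h in names(heads[[1]])) {
      w_h <- wts[[h]]
      if (w_h == 0) next
      for (cl in seq_len(ncl - 1L)) {
        inter <- 0; card <- 0
        ys <- vector("list", length(batch))
        for (s in seq_along(batch)) {
          pc <- heads[[s]][[h]]$v[, , , cl + 1L]
          yc <- as.numeric(batch[[s]]$mask == cl)
          ys[[s]] <- yc
          inter <- inter + sum(pc * yc)
          card <- card + sum(pc) + sum(yc)
        }
        num <- 2 * inter + eps
        den <- card + eps
        tot <- tot + w_h * (1 - num / den) / (ncl - 1L)
        for (s in seq_along(batch)) {
          nd <- heads[[s]][[h]]
          if (is.null(nd$g)) nd$g <- array(0, dim(nd$v))
          nd$g[, , , cl + 1L] <- nd$g[, , , cl + 1L] -
            w_h / (ncl - 1L) * (2 * ys[[s]] * den - num) / (den * den)
        }
      }
    }
    for (s in seq_along(batch)) ag_run_backward(tapes[[s]])
    if (!is.finite(tot)) stop("non-finite loss at iteration ", it)
    lr <- lr_schedule(it - 1L, n_iter, train_cfg$lr0)
    P <- adam_step(P, G, opt, lr, train_cfg, scale = 1)
    log$lr[it] <- lr
    log$loss[it] <- tot
    if (verbose && (it %% 25L == 0L || it == 1L))
      message(sprintf("iter %4d  lr %.3g  loss %.4f", it, lr, tot))
  }
  model <- list(params = P, config = net_cfg,
                meta = list(iterations = n_iter, seed = train_cfg$seed),
                loss_log = log)
  if (!is.null(checkpoint))
    save_model(P, net_cfg, checkpoint,
               meta = model$meta)
  model
}

adam_state <- function(P) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(P, function(p) array(0, dim(p) %||% length(p)))
  st$v <- lapply(P, function(p) array(0, dim(p) %||% length(p)))
  st$t <- 0L
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(P, G, st, lr, cfg, scale = 1) {
  st$t <- st$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (nm in names(P)) {
    g <- G[[nm]]
    if (is.null(g)) next
    g <- g * scale
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    P[[nm]] <- P[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + cfg$adam_eps)
  }
  P
}

#' Segment a full volume
#'
#' The complete inference pipeline: truncate and rescale intensities, then
#' for each requested view permute the volume, slide a patch grid over it,
#' run the network patch-wise, reconstruct with overlap averaging and
#' permute back; finally fuse the views (majority vote on per-view binary
#' masks, or thresholded mean probability) and remove connected components
#' below `min_component` voxels.
#'
#' @param v A `dpf_volume` (raw intensities).
#' @param model List with `params` and `config` (from [train_dpfnet()] or
#'   [load_model()]).
#' @param fusion `"mv"` (majority voting) or `"add"` (probability
#'   summation).
#' @param views Subset of `c("axial", "coronal", "sagittal")`; with fewer
#'   than three views no vote is taken and the mean probability is
#'   thresholded.
#' @param stride Patch stride (defaults to half the patch size).
#' @param window Intensity truncation window.
#' @param min_component Post-processing component threshold in voxels.
#' @return A binary `dpf_mask` with the volume's shape and spacing.
#' @export
predict_case <- function(v, model, fusion = c("mv", "add"),
                         views = c("axial", "coronal", "sagittal"),
                         stride = NULL,
                         window = c(1000, 2500), min_component = 10L) {
  fusion <- match.arg(fusion)
  cfg <- model$config
  ps <- cfg$patch_size
  if (is.null(stride)) stride <- max(ps %/% 2L, 4L)
  stopifnot(inherits(v, "dpf_volume"))
  x <- rescale_unit(truncate_intensities(v, window[1], window[2]),
                    window[1], window[2])$data
  views <- match.arg(views, c("axial", "coronal", "sagittal"),
                     several.ok = TRUE)
  probs <- list()
  # a constant patch maps to a constant probability; compute each distinct
  # constant once (dark far-from-vessel windows dominate overlapping grids)
  const_cache <- new.env(parent = emptyenv())
  predict_patch_cached <- function(p) {
    rng <- range(p)
    if (rng[1] == rng[2]) {
      key <- format(rng[1], digits = 17)
      hit <- const_cache[[key]]
      if (!is.null(hit)) return(hit)
    }
    dim(p) <- c(dim(p), 1L)
    out <- dpfnet_predict_patch(p, model$params, cfg)[, , , 2L]
    if (rng[1] == rng[2]) const_cache[[format(rng[1], digits = 17)]] <- out
    out
  }
  for (vw in views) {
    xp <- permute_view(x, vw)
    grid <- make_patch_grid(dim(xp), ps, stride)
    patches <- extract_patches(xp, grid)
    preds <- lapply(patches, predict_patch_cached)
    rec <- reconstruct(preds, grid)
    probs[[vw]] <- inverse_view(rec$prob, vw)
  }
  fg <- if (length(probs) == 3L) {
    if (fusion == "mv")
      fuse_views_majority(lapply(probs, function(p) (p >= 0.5) * 1L))
    else
      fuse_views_sum(probs)
  } else {
    array(as.integer(Reduce(`+`, probs) / length(probs) >= 0.5), dim(x))
  }
  fg <- filter_small_components(fg, min_size = min_component)
  as_mask(fg, spacing = v$spacing)
}

#' Evaluate predictions against ground truth
#'
#' Computes the per-case overlap metrics on complete scans and aggregates
#' them as mean and standard deviation, overall and per aneurysm size
#' group (by each case's ground-truth lesions). In `"brats"` mode the
#' metrics are computed per composite region (WT / TC / ET) from
#' multi-class labels instead.
#'
#' @param preds Named list of predicted masks (`dpf_mask` or arrays),
#'   names = case ids.
#' @param gts Named list of ground-truth masks, same names; binary masks
#'   in `"binary"` mode, 4-class labels in `"brats"` mode.
#' @param spacing Voxel spacing in mm used for size grouping.
#' @param mode `"binary"` or `"brats"`.
#' @return List with `per_case` (data.frame) and `summary` (data.frame of
#'   mean and sd per metric per group/region).
#' @export
evaluate_predictions <- function(preds, gts, spacing = c(0.5, 0.5, 0.5),
                                 mode = c("binary", "brats")) {
  mode <- match.arg(mode)
  ids <- names(gts)
  if (is.null(ids) || !all(ids %in% names(preds)))
    stop("every ground-truth case needs a prediction with the same name")
  rows <- list()
  for (id in ids) {
    p <- target_labels(preds[[id]])
    y <- target_labels(gts[[id]])
    if (mode == "binary") {
      met <- segmentation_metrics(p, y)
      grp <- if (sum(y != 0L) > 0L) stratify_by_diameter(y, spacing) else NA
      rows[[length(rows) + 1L]] <-
        data.frame(case_id = id, group = grp, met, stringsAsFactors = FALSE)
    } else {
      rp <- brats_regions(p)
      ry <- brats_regions(y)
      for (rg in names(ry)) {
        met <- segmentation_metrics(rp[[rg]], ry[[rg]])
        rows[[length(rows) + 1L]] <-
          data.frame(case_id = id, group = rg, met, stringsAsFactors = FALSE)
      }
    }
  }
  per_case <- do.call(rbind, rows)
  agg <- function(df, tag) {
    out <- data.frame(group = tag, n = nrow(df))
    for (m in c("dsc", "precision", "recall", "iou")) {
      out[[paste0(m, ".mean")]] <- mean(df[[m]])
      out[[paste0(m, ".sd")]] <- if (nrow(df) > 1) sd(df[[m]]) else 0
    }
    out
  }
  groups <- unique(per_case$group)
  summary <- rbind(agg(per_case, "all"),
                   do.call(rbind, lapply(groups[!is.na(groups)], function(g)
                     agg(per_case[!is.na(per_case$group) & per_case$group == g, ], g))))
  rownames(summary) <- NULL
  list(per_case = per_case, summary = summary)
}

#' Write an evaluation report to disk
#'
#' CSV of per-case records plus a JSON summary (mean and sd per metric,
#' per group), mirroring the mean-plus-sd table style of segmentation
#' papers.
#'
#' @param report Result of [evaluate_predictions()].
#' @param out_dir Destination directory.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "metrics_per_case.csv")
  js <- file.path(out_dir, "metrics_summary.json")
  write.csv(report$per_case, csv, row.names = FALSE)
  jsonlite::write_json(report$summary, js, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
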
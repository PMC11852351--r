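# Synthetic DSA-like vascular phantoms: bright tubular vessels on a dark
# background with ellipsoidal aneurysm blebs attached to vessel walls.
# The defaults emulate the data regime the segmentation task targets —
# aneurysm foreground below 0.2% of voxels, intensities meaningful under
# the 1000-2500 truncation window, 0.5 mm isotropic spacing.

#' Phantom specification
#'
#' Parameters of the synthetic vascular volume generator. Intensity
#' defaults place the background (U(0, 800)) below and the vessel lumen
#' (U(1600, 2400)) inside the 1000--2500 DSA truncation window; additive
#' Gaussian noise has sigma 50 intensity units. The default geometry (a
#' 96^3 grid at 0.5 mm with one aneurysm of 3--6 mm diameter) keeps the
#' foreground fraction well below 0.2% of voxels.
#'
#' @param volume_shape Voxels per axis.
#' @param spacing Voxel spacing in mm.
#' @param n_vessels Number of vessel centrelines.
#' @param vessel_radius_range Tube radius range in mm.
#' @param n_aneurysms Number of aneurysm blebs.
#' @param aneurysm_diameter_range Equivalent-sphere diameter range in mm.
#' @param vessel_intensity_range,background_intensity_range Raw intensity
#'   ranges (uniform draws).
#' @param noise_sigma Additive Gaussian noise, intensity units.
#' @param seed Default RNG seed for [generate_phantom_case()].
#' @return A `dpf_phantom_spec` list.
#' @export
phantom_spec <- function(volume_shape = c(96L, 96L, 96L),
                         spacing = c(0.5, 0.5, 0.5),
                         n_vessels = 3L,
                         vessel_radius_range = c(0.6, 1.2),
                         n_aneurysms = 1L,
                         aneurysm_diameter_range = c(3, 6),
                         vessel_intensity_range = c(1600, 2400),
                         background_intensity_range = c(0, 800),
                         noise_sigma = 50,
                         seed = 1L) {
  if (any(volume_shape < 16L)) stop("volume too small to contain a vessel path")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (diff(aneurysm_diameter_range) < 0 || aneurysm_diameter_range[1] <= 0)
    stop("aneurysm diameter range must be positive and ordered")
  if (diff(vessel_intensity_range) < 0 || diff(background_intensity_range) < 0)
    stop("intensity ranges must be ordered")
  if (n_vessels < 0L || n_aneurysms < 0L) stop("counts must be non-negative")
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing = as.numeric(spacing),
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_range = vessel_radius_range,
                 n_aneurysms = as.integer(n_aneurysms),
                 aneurysm_diameter_range = aneurysm_diameter_range,
                 vessel_intensity_range = vessel_intensity_range,
                 background_intensity_range = background_intensity_range,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "dpf_phantom_spec")
}

# Smooth random centreline through the volume: 3-6 control points between
# random boundary faces, cubic-spline interpolated per coordinate (voxel
# units, 1-based continuous coordinates).
random_centreline <- function(shape, n_samples = 400L) {
  npts <- sample(3:6, 1L)
  face <- function() {
    p <- runif(3, 1, shape)
    ax <- sample.int(3L, 1L)
    p[ax] <- if (runif(1) < 0.5) 1 else shape[ax]
    p
  }
  a <- face(); b <- face()
  tt <- seq(0, 1, length.out = npts)
  ctrl <- sapply(1:3, function(i)
    c(a[i], runif(npts - 2L, 0.15, 0.85) * (shape[i] - 1) + 1, b[i]))
  ts <- seq(0, 1, length.out = n_samples)
  sapply(1:3, function(i) spline(tt, ctrl[, i], xout = ts)$y)
}

# Stamp a ball of given voxel radius (possibly anisotropic semi-axes, in
# voxels) at a continuous centre into a logical mask.
stamp_ellipsoid <- function(mask, centre, semi_axes_vox) {
  dm <- dim(mask)
  lo <- pmax(1L, floor(centre - semi_axes_vox))
  hi <- pmin(dm, ceiling(centre + semi_axes_vox))
  if (any(lo > hi)) return(mask)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- (ix - centre[1]) / semi_axes_vox[1]
  gy <- (iy - centre[2]) / semi_axes_vox[2]
  gz <- (iz - centre[3]) / semi_axes_vox[3]
  r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  mask[ix, iy, iz] <- mask[ix, iy, iz, drop = FALSE] | (r2 <= 1)
  mask
}

#' Generate the vessel tree of a phantom
#'
#' Rasterizes `n_vessels` tubes along smooth random centrelines (radius
#' drawn per vessel from `vessel_radius_range`), fills them with
#' vessel-range intensities over a noisy background, and returns the
#' binary vessel mask alongside the image.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` ([as_volume()]) and `vessel_mask` (logical
#'   array). Uses the current RNG state; seed externally (or via
#'   [generate_phantom_case()]) for reproducibility.
#' @export
generate_vessel_tree <- function(spec) {
  dm <- spec$volume_shape
  vox <- spec$spacing
  vmask <- array(FALSE, dm)
  if (spec$n_vessels > 0L) {
    for (v in seq_len(spec$n_vessels)) {
      r_mm <- runif(1, spec$vessel_radius_range[1], spec$vessel_radius_range[2])
      cl <- random_centreline(dm)
      sa <- r_mm / vox  # semi-axes in voxels (anisotropy-aware)
      for (i in seq_len(nrow(cl))) vmask <- stamp_ellipsoid(vmask, cl[i, ], sa)
    }
  }
  img <- array(runif(prod(dm), spec$background_intensity_range[1],
                     spec$background_intensity_range[2]), dm)
  nv <- sum(vmask)
  if (nv > 0L)
    img[vmask] <- runif(nv, spec$vessel_intensity_range[1],
                        spec$vessel_intensity_range[2])
  img <- img + array(rnorm(prod(dm), sd = spec$noise_sigma), dm)
  list(image = as_volume(img, spacing = vox), vessel_mask = vmask)
}

#' Attach aneurysm blebs to a vessel tree
#'
#' Each aneurysm is an ellipsoidal bleb (axis ratios U(0.7, 1), scaled so
#' the equivalent-sphere diameter equals the requested draw from
#' `aneurysm_diameter_range`) centred on a random vessel-surface voxel and
#' painted with vessel-range intensities. The ground-truth mask contains
#' the bleb voxels only — aneurysms, not vessels, are the positive class —
#' with the vessel lumen excluded.
#'
#' @param image A `dpf_volume` from [generate_vessel_tree()].
#' @param vessel_mask Logical vessel array from the same call.
#' @param spec The [phantom_spec()].
#' @param case_id Identifier stored in the returned case.
#' @return A `dpf_phantom_case`: `image`, `mask` ([as_mask()]),
#'   `aneurysm_diameters` (the realized equivalent-sphere diameter of each
#'   rasterized bleb in mm, lumen excluded — consistent with
#'   [stratify_by_diameter()] on the mask), `case_id`.
#' @export
attach_aneurysms <- function(image, vessel_mask, spec, case_id = "case") {
  dm <- spec$volume_shape
  vox <- spec$spacing
  amask <- array(FALSE, dm)
  diams <- numeric(0)
  if (spec$n_aneurysms > 0L) {
    if (!any(vessel_mask)) stop("cannot attach aneurysms to an empty vessel tree")
    surf <- which(vessel_mask & !erode_once(vessel_mask))
    if (!length(surf)) surf <- which(vessel_mask)
    for (a in seq_len(spec$n_aneurysms)) {
      d_mm <- runif(1, spec$aneurysm_diameter_range[1],
                    spec$aneurysm_diameter_range[2])
      ratios <- c(1, runif(2, 0.7, 1))
      # scale so the ellipsoid volume equals a d_mm sphere's
      ratios <- ratios / prod(ratios)^(1 / 3)
      centre <- arrayInd(surf[sample.int(length(surf), 1L)], dm)
      semi_mm <- d_mm / 2 * ratios
      one <- array(FALSE, dm)
      one <- stamp_ellipsoid(one, as.numeric(centre), semi_mm / vox)
      one <- one & !vessel_mask
      amask <- amask | one
      # record the realized equivalent diameter of the rasterized bleb
      # (lumen excluded), so size groups derived from these diameters
      # agree with stratification of the mask itself
      diams <- c(diams, 2 * (3 * sum(one) * prod(vox) / (4 * pi))^(1 / 3))
    }
    amask <- amask & !vessel_mask  # bleb only, lumen excluded
    nfg <- sum(amask)
    if (nfg > 0L)
      image$data[amask] <- runif(nfg, spec$vessel_intensity_range[1],
                                 spec$vessel_intensity_range[2]) +
        rnorm(nfg, sd = spec$noise_sigma)
  }
  structure(list(image = image,
                 mask = as_mask(array(as.integer(amask), dm), spacing = vox),
                 aneurysm_diameters = diams,
                 case_id = case_id),
            class = "dpf_phantom_case")
}

erode_once <- function(m) {
  dm <- dim(m)
  out <- m
  shift <- function(a, ax, by) {
    idx <- seq_len(dm[ax]) + by
    idx[idx < 1L | idx > dm[ax]] <- NA
    sl <- switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    sl[is.na(sl)] <- FALSE
    sl
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(m, ax, by)
  out
}

#' Generate one complete phantom case
#'
#' Seeds the RNG, builds the vessel tree and attaches the aneurysms.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed (defaults to the spec's); fixed seed gives a
#'   bit-identical phantom.
#' @param case_id Identifier.
#' @return A `dpf_phantom_case`.
#' @export
generate_phantom_case <- function(spec, seed = spec$seed, case_id = "case") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vt <- generate_vessel_tree(spec)
  attach_aneurysms(vt$image, vt$vessel_mask, spec, case_id = case_id)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_cases` image/mask NIfTI pairs plus a CSV manifest with the
#' per-case aneurysm diameters and size group (Small / Medium / Large by
#' largest lesion). Fully reproducible from `seed`.
#'
#' @param n_cases Number of cases.
#' @param spec A [phantom_spec()].
#' @param seed Base seed; case `i` is generated with seed `seed + i - 1`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest `data.frame` (also written to
#'   `file.path(out_dir, "manifest.csv")`), invisibly the same.
#' @export
generate_dataset <- function(n_cases, spec = phantom_spec(), seed = 1L,
                             out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cid <- sprintf("case_%03d", i)
    cs <- generate_phantom_case(spec, seed = seed + i - 1L, case_id = cid)
    ip <- file.path(out_dir, paste0(cid, "_image.nii.gz"))
    mp <- file.path(out_dir, paste0(cid, "_mask.nii.gz"))
    write_volume(cs$image, ip)
    write_volume(cs$mask, mp)
    grp <- if (length(cs$aneurysm_diameters))
      size_group(max(cs$aneurysm_diameters)) else NA_character_
    rows[[i]] <- data.frame(case_id = cid, image_path = ip, mask_path = mp,
                            n_aneurysms = length(cs$aneurysm_diameters),
                            diameters_mm = paste(round(cs$aneurysm_diameters, 3),
                                                 collapse = ";"),
                            group = grp,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Generate a multi-class phantom with nested tumor-like regions
#'
#' Builds a 4-channel image (four correlated noisy renderings of one
#' geometry, standing in for multi-modal MRI) whose labels are concentric
#' ellipsoids — an enhancing core (label 4) inside a necrotic shell
#' (label 1) inside an edema rim (label 2) — so the composite regions
#' satisfy WT >= TC >= ET by construction.
#'
#' @param spec A [phantom_spec()]; `volume_shape` and `spacing` are used,
#'   radii scale with the volume.
#' @param seed RNG seed.
#' @return List with `image` (4-channel `dpf_volume`, channel-first),
#'   `labels` ([as_mask()] with label set {0, 1, 2, 4}) and the three
#'   nominal region radii in mm.
#' @export
generate_multiclass_phantom <- function(spec = phantom_spec(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dm <- spec$volume_shape
  vox <- spec$spacing
  centre <- dm / 2 + runif(3, -dm[1] / 10, dm[1] / 10)
  ext_mm <- min(dm * vox)
  r_et <- runif(1, 0.06, 0.09) * ext_mm
  r_ncr <- r_et + runif(1, 0.04, 0.06) * ext_mm
  r_ed <- r_ncr + runif(1, 0.05, 0.08) * ext_mm
  ball <- function(r) stamp_ellipsoid(array(FALSE, dm), centre, rep(r, 3) / vox)
  et <- ball(r_et); ncr <- ball(r_ncr); ed <- ball(r_ed)
  lab <- array(0L, dm)
  lab[ed] <- 2L
  lab[ncr] <- 1L
  lab[et] <- 4L
  base <- array(0.2, dm)
  base[ed] <- 0.5; base[ncr] <- 0.7; base[et] <- 0.9
  img <- array(0, c(4L, dm))
  for (ch in 1:4)
    img[ch, , , ] <- base * runif(1, 0.8, 1.2) +
      array(rnorm(prod(dm), sd = 0.05), dm)
  list(image = as_volume(img, spacing = vox),
       labels = as_mask(lab, spacing = vox, label_set = c(0L, 1L, 2L, 4L)),
       radii_mm = c(ET = r_et, NCR = r_ncr, ED = r_ed))
}
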
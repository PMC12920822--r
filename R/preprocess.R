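# Intensity normalization, mask cleaning and resampling/discretization.

#' Preprocessing configuration
#'
#' @param min_island_voxels connected components smaller than this are
#'   removed from masks (default 10: islands of fewer than 10 voxels,
#'   roughly 0.01 cm3 at CT resolution, are treated as segmentation slips).
#' @param resample_spacing_policy `"dataset-mode"` (isometric target = modal
#'   spacing over all axes of the cohort) or `"explicit"`.
#' @param explicit_spacing mm; used when the policy is `"explicit"`.
#' @param bin_width fixed discretization bin width. Defaults to 0.1, suited
#'   to z-score-normalized intensities (use ~25 on raw HU-like values).
#' @param crop_margin voxels kept around the mask bounding box so context is
#'   available to the imaging filters (default 10).
#' @param connectivity island connectivity, 26 (default) or 6.
#' @param otsu_bins histogram bins for the Otsu threshold (default 256).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(min_island_voxels = 10L,
                              resample_spacing_policy = c("dataset-mode", "explicit"),
                              explicit_spacing = NULL,
                              bin_width = 0.1,
                              crop_margin = 10L,
                              connectivity = 26L,
                              otsu_bins = 256L) {
  stopifnot(min_island_voxels >= 1, bin_width > 0, crop_margin >= 0,
            connectivity %in% c(6L, 26L))
  structure(list(
    min_island_voxels = as.integer(min_island_voxels),
    resample_spacing_policy = match.arg(resample_spacing_policy),
    explicit_spacing = explicit_spacing,
    bin_width = bin_width, crop_margin = as.integer(crop_margin),
    connectivity = as.integer(connectivity), otsu_bins = as.integer(otsu_bins)
  ), class = "preprocess_config")
}

#' Otsu threshold of an image
#'
#' Classic between-class-variance maximization on an `n_bins`-bin histogram
#' of the full volume. Returns the threshold intensity; voxels strictly above
#' it are foreground.
#'
#' @param image numeric array.
#' @param n_bins histogram bins (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("image is constant; Otsu threshold undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1L),
                     n_bins), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  breaks[k + 1L]
}

#' Z-score normalize an image over its Otsu foreground
#'
#' Subtracts the mean and divides by the SD of the voxels above the Otsu
#' threshold of the whole volume, so the foreground of the output has mean 0
#' and SD 1. Affine-equivariant: `a*x + b` (a > 0) normalizes to the same
#' output as `x`.
#'
#' @param image numeric 3D array (at least 2 distinct values).
#' @param n_bins Otsu histogram bins.
#' @return normalized array.
#' @export
zscore_normalize <- function(image, n_bins = 256L) {
  thr <- otsu_threshold(image, n_bins)
  fg <- image > thr
  if (!any(fg)) stop("empty Otsu foreground")
  mu <- mean(image[fg])
  s <- sd(image[fg])
  if (!is.finite(s) || s == 0) stop("constant foreground")
  (image - mu) / s
}

#' Remove small islands from a binary mask
#'
#' Every connected component (26-connectivity by default) with fewer than
#' `min_island_voxels` voxels is removed; a component with exactly
#' `min_island_voxels` voxels is kept.
#'
#' @param mask logical 3D array.
#' @param min_island_voxels integer threshold (default 10).
#' @param connectivity 26 (default) or 6.
#' @return cleaned logical array.
#' @export
clean_mask <- function(mask, min_island_voxels = 10L, connectivity = 26L) {
  d <- as_dim3(mask)
  lab <- cpp_label_components(as.logical(mask), d, as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0) stop("no lesion after cleaning: mask is empty")
  sizes <- tabulate(lab[lab > 0L], ncomp)
  keep <- which(sizes >= min_island_voxels)
  if (length(keep) == 0) stop("no lesion after cleaning")
  out <- array(lab %in% keep, dim = d)
  out
}

#' Validate an image/mask pair
#'
#' Raises an exclusion error (condition class `radrot_exclusion`, carrying
#' the patient id) on mismatched dimensions or an empty mask; passes the
#' pair through otherwise.
#'
#' @param pair a [volume_pair()].
#' @return the validated pair.
#' @export
check_pair <- function(pair) {
  stopifnot(inherits(pair, "volume_pair"))
  d1 <- as_dim3(pair$image)
  d2 <- as_dim3(pair$mask)
  if (!identical(d1, d2))
    exclusion_error("mismatched image and segmentation dimensions",
                    pair$patient_id)
  if (!any(pair$mask))
    exclusion_error("empty segmentation mask", pair$patient_id)
  pair
}

#' Crop a pair to the mask bounding box plus margin
#'
#' @param pair a [volume_pair()].
#' @param margin voxels added on each side, clipped at the volume border.
#' @return cropped [volume_pair()]; the mask voxel count is preserved.
#' @export
crop_to_bbox <- function(pair, margin = 10L) {
  stopifnot(any(pair$mask))
  d <- as_dim3(pair$mask)
  idx <- which(pair$mask)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  lo <- pmax(c(min(i), min(j), min(k)) - margin + 1L, 1L)
  hi <- pmin(c(max(i), max(j), max(k)) + margin + 1L, d)
  out <- pair
  out$image <- pair$image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out$mask <- pair$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  attr(out, "crop_origin") <- lo
  out
}

#' Modal spacing of a cohort
#'
#' Most frequent spacing value over all axes of all patients, used as the
#' isometric resampling target; ties break to the smallest value
#' (conservative: less information loss).
#'
#' @param cohort list of [volume_pair()].
#' @return scalar mm.
#' @export
modal_spacing <- function(cohort) {
  stopifnot(length(cohort) > 0)
  vals <- round(unlist(lapply(cohort, function(p) p$spacing)), 6)
  tab <- table(vals)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)
}

#' Resample a pair to isotropic spacing
#'
#' Image voxels are interpolated trilinearly, the mask with nearest
#' neighbour; the physical extent is preserved to within one voxel.
#'
#' @param pair a [volume_pair()].
#' @param target mm target spacing (> 0).
#' @return resampled [volume_pair()].
#' @export
resample_isotropic <- function(pair, target) {
  stopifnot(target > 0)
  d <- as_dim3(pair$image)
  sp <- pair$spacing
  outdim <- pmax(1L, as.integer(floor((d - 1) * sp / target + 1e-9)) + 1L)
  A <- diag(target / sp)
  b <- c(0, 0, 0)
  img <- cpp_resample_affine(pair$image, d, A, b, outdim, 0L)
  msk <- cpp_resample_affine(pair$mask + 0, d, A, b, outdim, 1L)
  if (!any(msk > 0))
    stop("mask vanished at target spacing ", target, " mm")
  out <- volume_pair(img, msk, rep(target, 3), pair$patient_id,
                     pair$class_label)
  attr(out, "rotation") <- attr(pair, "rotation")
  out
}

#' Discretize masked intensities with a fixed bin width
#'
#' `level(x) = floor((x - edge0)/w) + 1` with
#' `edge0 = floor(min(x[mask])/w) * w`; this anchor keeps levels stable
#' under mask-preserving crops. Levels start at 1; voxels outside the mask
#' are clamped into range but carry no meaning.
#'
#' @param image numeric 3D array.
#' @param mask logical array.
#' @param bin_width w > 0.
#' @return integer array of gray levels with attribute `n_levels`.
#' @export
discretize <- function(image, mask, bin_width) {
  stopifnot(bin_width > 0, any(mask))
  vals <- image[mask]
  edge0 <- floor(min(vals) / bin_width) * bin_width
  lev <- array(as.integer(floor((image - edge0) / bin_width)) + 1L,
               dim = dim(image))
  lev[lev < 1L] <- 1L
  ng <- max(lev[mask])
  lev[lev > ng] <- ng
  attr(lev, "n_levels") <- as.integer(ng)
  lev
}

#' Full per-patient preprocessing (normalize + clean)
#'
#' Applies [check_pair()], [zscore_normalize()] and [clean_mask()]; cropping
#' and isotropic resampling happen after rotation (see
#' [build_rotated_cohort()]) so no context is lost at crop edges.
#'
#' @param pair a [volume_pair()].
#' @param config a [preprocess_config()].
#' @return normalized, cleaned [volume_pair()].
#' @export
preprocess_pair <- function(pair, config = preprocess_config()) {
  pair <- check_pair(pair)
  pair$image <- zscore_normalize(pair$image, config$otsu_bins)
  pair$mask <- clean_mask(pair$mask, config$min_island_voxels,
                          config$connectivity)
  pair
}
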
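# Gray-level texture features (18 first-order + 24 GLCM + 16 GLRLM +
# 16 GLSZM + 14 GLDM + 5 NGTDM = 93 per channel) and 14 mask-only shape
# features, following the standard IBSI-aligned definitions.
#
# NaN policy: degenerate inputs (e.g. a single gray level) return documented
# constants, never NaN, so downstream percentage differences stay finite.

.safe_log2 <- function(p) {
  out <- numeric(length(p))
  pos <- which(p > 0)
  out[pos] <- log2(p[pos])
  out
}

#' First-order intensity statistics (18 features)
#'
#' Entropy and Uniformity are computed on the fixed-bin-width histogram with
#' the same bin anchor as [discretize()]; percentiles use type-7 quantiles.
#' Skewness and Kurtosis of a constant region are 0 by convention.
#'
#' @param image numeric 3D array (channel intensities).
#' @param mask logical array.
#' @param bin_width histogram bin width for Entropy/Uniformity.
#' @param spacing mm 3-vector (for TotalEnergy).
#' @return named numeric vector of 18 features.
#' @export
firstorder_features <- function(image, mask, bin_width, spacing = c(1, 1, 1)) {
  v <- image[mask]
  n <- length(v)
  if (n == 0) stop("empty mask")
  voxvol <- prod(spacing)
  lev <- floor((v - floor(min(v) / bin_width) * bin_width) / bin_width)
  p <- tabulate(as.integer(lev) + 1L)
  p <- p[p > 0] / n
  q <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  rob <- v[v >= q[1] & v <= q[5]]
  c(Energy = sum(v^2),
    TotalEnergy = voxvol * sum(v^2),
    Entropy = -sum(p * .safe_log2(p)),
    Minimum = min(v),
    P10 = q[1], P90 = q[5],
    Maximum = max(v),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(rob)) mean(abs(rob - mean(rob))) else 0,
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

# total area of voxel faces between foreground and background (or border)
.voxel_surface_area <- function(mask, spacing) {
  d <- dim(mask)
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  a <- 0
  for (ax in 1:3) {
    n <- d[ax]
    shift <- function(s) {
      idx <- seq_len(n) + s
      pad <- idx < 1L | idx > n
      idx <- pmin(pmax(idx, 1L), n)
      out <- switch(ax, mask[idx, , , drop = FALSE],
                    mask[, idx, , drop = FALSE], mask[, , idx, drop = FALSE])
      if (any(pad)) {
        z <- which(pad)
        switch(ax, out[z, , ] <- FALSE, out[, z, ] <- FALSE,
               out[, , z] <- FALSE)
      }
      out
    }
    a <- a + face[ax] * (sum(mask & !shift(1L)) + sum(mask & !shift(-1L)))
  }
  a
}

.boundary_voxels <- function(mask) {
  d <- dim(mask)
  inner <- mask
  shift_all <- function(ax, s) {
    idx <- pmin(pmax(seq_len(d[ax]) + s, 1L), d[ax])
    switch(ax, mask[idx, , , drop = FALSE], mask[, idx, , drop = FALSE],
           mask[, , idx, drop = FALSE])
  }
  surrounded <- mask
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- shift_all(ax, s)
    # voxels at the grid border count as boundary: emulate 0-padding
    pad <- array(TRUE, d)
    if (s == -1L) {
      switch(ax, pad[1, , ] <- FALSE, pad[, 1, ] <- FALSE, pad[, , 1] <- FALSE)
    } else {
      switch(ax, pad[d[1], , ] <- FALSE, pad[, d[2], ] <- FALSE,
             pad[, , d[3]] <- FALSE)
    }
    surrounded <- surrounded & nb & pad
  }
  which(mask & !surrounded)
}


#' Shape features of a binary mask (14 features)
#'
#' Mesh volume and surface area come from a marching-tetrahedra surface
#' (iso-level 0.5, averaged over the four cube diagonals so the mesh is
#' exactly invariant under 90-degree axis rotations); axis lengths from the
#' PCA of spacing-weighted voxel coordinates; diameters from boundary voxel
#' centres. Single-voxel masks fall back to the voxel-based surface.
#'
#' @param mask logical 3D array (nonempty).
#' @param spacing mm 3-vector.
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(any(mask))
  d <- as_dim3(mask)
  spacing <- stopifnot_spacing(spacing)
  idx <- which(mask)
  n <- length(idx)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  coords <- cbind(i * spacing[1], j * spacing[2], k * spacing[3])
  voxvol <- prod(spacing)
  if (n > 1) {
    # mesh a smoothed indicator (sigma 1 voxel) so the iso-0.5
    # marching-tetrahedra surface tracks the lesion shape instead of the
    # voxel staircase; zero-pad so the surface always closes
    pd <- d + 8L
    field <- array(0, pd)
    field[5:(d[1] + 4), 5:(d[2] + 4), 5:(d[3] + 4)] <- mask + 0
    g <- exp(-(-3:3)^2 / 2)
    g <- g / sum(g)
    for (ax in 1:3) field <- .rep_conv(field, g, ax)
    va <- cpp_mesh_vol_area(field, pd, spacing, 0.5)
    mesh_v <- va[1]; mesh_a <- va[2]
  } else mesh_v <- mesh_a <- 0
  if (mesh_v <= 0 || mesh_a <= 0) {
    # thin or single-voxel masks can vanish under smoothing: voxel fallback
    mesh_v <- n * voxvol
    mesh_a <- .voxel_surface_area(mask, spacing)
  }
  bidx <- .boundary_voxels(mask)
  bi <- (bidx - 1L) %% d[1]
  bj <- ((bidx - 1L) %/% d[1]) %% d[2]
  bk <- (bidx - 1L) %/% (d[1] * d[2])
  diam <- cpp_max_diameters(cbind(as.integer(bi), as.integer(bj),
                                  as.integer(bk)), spacing)
  max3d <- diam[1]
  cov <- crossprod(sweep(coords, 2, colMeans(coords))) / n
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  sphericity <- if (mesh_a > 0) pi^(1 / 3) * (6 * mesh_v)^(2 / 3) / mesh_a else 0
  c(MeshVolume = mesh_v,
    VoxelVolume = n * voxvol,
    SurfaceArea = mesh_a,
    SurfaceVolumeRatio = if (mesh_v > 0) mesh_a / mesh_v else 0,
    Sphericity = sphericity,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = diam[2],   # in-plane (x, y), same slice
    Maximum2DDiameterRow = diam[3],     # (x, z), same row
    Maximum2DDiameterColumn = diam[4],  # (y, z), same column
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

#' Gray-level co-occurrence count matrices
#'
#' Symmetric co-occurrence counts for the 13 unique 3D direction offsets at
#' Chebyshev distance 1 (each voxel pair contributes to both orders).
#'
#' @param levels integer 3D array of gray levels (from [discretize()]).
#' @param mask logical array.
#' @param n_levels number of gray levels (defaults to the `n_levels`
#'   attribute of `levels`).
#' @return `n_levels x n_levels x 13` count array.
#' @export
glcm_matrix <- function(levels, mask, n_levels = attr(levels, "n_levels")) {
  d <- as_dim3(levels)
  cpp_glcm_counts(as.integer(levels), as.logical(mask), d,
                  as.integer(n_levels))
}

#' GLCM texture features (24 features)
#'
#' Features are computed per direction from the normalized symmetric
#' co-occurrence distribution (held sparsely; only observed level pairs
#' contribute) and averaged over the 13 directions. For the symmetric GLCM
#' the cross entropies satisfy HXY1 = HXY2 = HX + HY, which is used in the
#' Imc1/Imc2 closed forms. Degenerate single-level regions use the
#' documented conventions Correlation = 1, MCC = 1, Imc1 = 0, Imc2 = 0.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(levels, mask, n_levels = attr(levels, "n_levels")) {
  ng <- as.integer(n_levels)
  d3 <- as_dim3(levels)
  tr <- cpp_glcm_sparse(as.integer(levels), as.logical(mask), d3, ng)
  if (length(tr$dir) == 0) {
    # single in-mask voxel: one constant pair per direction
    tr <- list(dir = 1:13, i = rep(1L, 13), j = rep(1L, 13), n = rep(1, 13))
  }
  feats <- cpp_glcm_feats(tr$dir, tr$i, tr$j, tr$n, ng)  # 13 x 22, NA = no pairs
  sumsq <- cpp_glcm_sumsq(tr$dir, tr$i, tr$j, tr$n, ng)
  mcc <- cpp_glcm_mcc_sparse(tr$dir, tr$i, tr$j, tr$n, ng)
  use <- which(!is.na(feats[, 1]))
  m <- colMeans(feats[use, , drop = FALSE])
  c(Autocorrelation = m[1], JointAverage = m[2], ClusterProminence = m[3],
    ClusterShade = m[4], ClusterTendency = m[5], Contrast = m[6],
    Correlation = m[7], DifferenceAverage = m[8], DifferenceEntropy = m[9],
    DifferenceVariance = m[10], Id = m[11], Idm = m[12], Idmn = m[13],
    Idn = m[14], Imc1 = m[15], Imc2 = m[16], InverseVariance = m[17],
    JointEnergy = m[18], JointEntropy = m[19], MCC = mean(mcc[use]),
    MaximumProbability = m[20], SumAverage = m[21], SumEntropy = m[22],
    SumSquares = mean(sumsq[use]))
}

#' Gray-level run-length features (16 features)
#'
#' Runs are maximal straight segments of equal gray level along each of the
#' 13 directions (out-of-mask voxels break runs); features are averaged over
#' directions.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(levels, mask, n_levels = attr(levels, "n_levels")) {
  ng <- as.integer(n_levels)
  d <- as_dim3(levels)
  np <- sum(mask)
  per_dir <- cpp_glrlm_feats(as.integer(levels), as.logical(mask), d, ng,
                             as.numeric(np))
  out <- rowMeans(per_dir)
  names(out) <- c("ShortRunEmphasis", "LongRunEmphasis",
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                  "RunPercentage", "GrayLevelVariance", "RunVariance",
                  "RunEntropy", "LowGrayLevelRunEmphasis",
                  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                  "LongRunHighGrayLevelEmphasis")
  out
}

#' Gray-level size-zone features (16 features)
#'
#' Zones are 26-connected components of equal gray level within the mask.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(levels, mask, n_levels = attr(levels, "n_levels")) {
  d <- as_dim3(levels)
  np <- sum(mask)
  z <- cpp_glszm_zones(as.integer(levels), as.logical(mask), d)
  lev <- z[, 1]; sz <- z[, 2]
  nz <- length(lev)
  n_i <- table(lev); m_s <- table(sz)
  pj <- table(paste(lev, sz)) / nz
  mu_i <- mean(lev); mu_s <- mean(sz)
  c(SmallAreaEmphasis = mean(1 / sz^2),
    LargeAreaEmphasis = mean(sz^2),
    GrayLevelNonUniformity = sum(n_i^2) / nz,
    GrayLevelNonUniformityNormalized = sum(n_i^2) / nz^2,
    SizeZoneNonUniformity = sum(m_s^2) / nz,
    SizeZoneNonUniformityNormalized = sum(m_s^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((lev - mu_i)^2),
    ZoneVariance = mean((sz - mu_s)^2),
    ZoneEntropy = -sum(pj * .safe_log2(pj)),
    LowGrayLevelZoneEmphasis = mean(1 / lev^2),
    HighGrayLevelZoneEmphasis = mean(lev^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (lev^2 * sz^2)),
    SmallAreaHighGrayLevelEmphasis = mean(lev^2 / sz^2),
    LargeAreaLowGrayLevelEmphasis = mean(sz^2 / lev^2),
    LargeAreaHighGrayLevelEmphasis = mean(lev^2 * sz^2))
}

#' Gray-level dependence features (14 features)
#'
#' Dependence of a voxel is 1 plus the number of in-mask 26-neighbours whose
#' level differs from it by at most `alpha`.
#'
#' @inheritParams glcm_matrix
#' @param alpha dependence tolerance (default 0).
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(levels, mask, n_levels = attr(levels, "n_levels"),
                          alpha = 0L) {
  ng <- as.integer(n_levels)
  d <- as_dim3(levels)
  P <- cpp_gldm_counts(as.integer(levels), as.logical(mask), d, ng,
                       as.integer(alpha))
  nz <- sum(P)
  pr <- P / nz
  ivec <- seq_len(ng); jvec <- seq_len(ncol(P))
  ri <- rowSums(P); rj <- colSums(P)
  mu_i <- sum(ivec * rowSums(pr)); mu_j <- sum(jvec * colSums(pr))
  c(SmallDependenceEmphasis = sum(t(P) / jvec^2) / nz,
    LargeDependenceEmphasis = sum(t(P) * jvec^2) / nz,
    GrayLevelNonUniformity = sum(ri^2) / nz,
    DependenceNonUniformity = sum(rj^2) / nz,
    DependenceNonUniformityNormalized = sum(rj^2) / nz^2,
    GrayLevelVariance = sum(pr * (ivec - mu_i)^2),
    DependenceVariance = sum(t(pr) * (jvec - mu_j)^2),
    DependenceEntropy = -sum(pr * .safe_log2(pr)),
    LowGrayLevelEmphasis = sum(P / ivec^2) / nz,
    HighGrayLevelEmphasis = sum(P * ivec^2) / nz,
    SmallDependenceLowGrayLevelEmphasis =
      sum((P / ivec^2) %*% diag(1 / jvec^2, ncol(P))) / nz,
    SmallDependenceHighGrayLevelEmphasis =
      sum((P * ivec^2) %*% diag(1 / jvec^2, ncol(P))) / nz,
    LargeDependenceLowGrayLevelEmphasis =
      sum((P / ivec^2) %*% diag(jvec^2, ncol(P))) / nz,
    LargeDependenceHighGrayLevelEmphasis =
      sum((P * ivec^2) %*% diag(jvec^2, ncol(P))) / nz)
}

#' Neighbourhood gray-tone difference features (5 features)
#'
#' Built from per-level occupancies `n_i` and summed absolute differences
#' `s_i` to the mean 26-neighbourhood level. Degenerate conventions:
#' Coarseness capped at 1e6 when the denominator vanishes; Contrast,
#' Busyness and Strength are 0 when undefined.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(levels, mask, n_levels = attr(levels, "n_levels")) {
  ng <- as.integer(n_levels)
  d <- as_dim3(levels)
  st <- cpp_ngtdm_stats(as.integer(levels), as.logical(mask), d, ng)
  n_i <- st[, 1]; s_i <- st[, 2]
  N <- sum(n_i)
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  iv <- seq_len(ng)
  denom_coarse <- sum(p_i * s_i)
  coarseness <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  contrast <- if (ngp > 1) {
    s1 <- sum(outer(p_i[act], p_i[act]) * outer(iv[act], iv[act], "-")^2) /
      (ngp * (ngp - 1))
    s1 * sum(s_i) / N
  } else 0
  busy_den <- sum(abs(outer(iv[act] * p_i[act], iv[act] * p_i[act], "-")))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  complexity <- if (N > 0 && ngp > 1) {
    pm <- outer(p_i[act], p_i[act], "+")
    num <- abs(outer(iv[act], iv[act], "-")) *
      (outer(p_i[act] * s_i[act], p_i[act] * s_i[act], "+")) / pm
    sum(num) / N
  } else 0
  strength <- if (sum(s_i) > 0 && ngp > 1) {
    sum(outer(p_i[act], p_i[act], "+") * outer(iv[act], iv[act], "-")^2) /
      sum(s_i)
  } else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

.texture_families <- function() {
  list(glcm = glcm_features, glrlm = glrlm_features, glszm = glszm_features,
       gldm = gldm_features, ngtdm = ngtdm_features)
}

#' Extract the full per-lesion feature vector
#'
#' Computes 93 features (18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM +
#' 14 GLDM + 5 NGTDM) for each filter channel, with each channel discretized
#' independently under the configured fixed bin width, plus 14 shape
#' features from the mask alone. Non-finite values are replaced by 0 with a
#' warning (documented NaN policy).
#'
#' @param pair preprocessed, cropped, isotropically resampled
#'   [volume_pair()].
#' @param channels optional list from [apply_filter_bank()]; computed if
#'   missing.
#' @param bin_width discretization bin width (see [preprocess_config()]).
#' @param filter_cfg a [filter_config()] used when `channels` is missing.
#' @return a `data.table` (class `feature_vector`) with columns patient_id,
#'   channel, category, feature, value, is_wd.
#' @export
extract_all <- function(pair, channels = NULL, bin_width = 0.1,
                        filter_cfg = filter_config()) {
  stopifnot(inherits(pair, "volume_pair"), any(pair$mask))
  # texture statistics only involve in-mask voxels (and their immediate
  # neighbours), so restrict to the mask bounding box + 1 for speed; the
  # filters consume the full context
  d <- as_dim3(pair$mask)
  midx <- which(pair$mask)
  mi <- (midx - 1L) %% d[1]
  mj <- ((midx - 1L) %/% d[1]) %% d[2]
  mk <- (midx - 1L) %/% (d[1] * d[2])
  lo <- pmax(c(min(mi), min(mj), min(mk)), 1L)        # 0-based - 1 margin
  hi <- pmin(c(max(mi), max(mj), max(mk)) + 2L, d)    # 0-based + 1 margin
  if (is.null(channels))
    channels <- apply_filter_bank(pair, filter_cfg,
                                  lbp_region = list(lo = lo - 1L, hi = hi - 1L))
  fams <- .texture_families()
  sub <- function(a) a[(lo[1]):hi[1], (lo[2]):hi[2], (lo[3]):hi[3],
                       drop = FALSE]
  mask_c <- sub(pair$mask)
  rows <- vector("list", length(channels) + 1L)
  for (ci in seq_along(channels)) {
    ch <- channels[[ci]]
    res <- tryCatch({
      img_c <- sub(ch$image)
      lev <- discretize(img_c, mask_c, bin_width)
      fo <- firstorder_features(img_c, mask_c, bin_width, pair$spacing)
      tex <- lapply(fams, function(f) f(lev, mask_c))
      vals <- c(fo, unlist(unname(tex)))
      data.table::data.table(
        patient_id = pair$patient_id,
        channel = ch$name,
        category = c(rep("firstorder", length(fo)),
                     rep(names(fams), times = vapply(tex, length, 1L))),
        feature = c(names(fo), unlist(lapply(tex, names), use.names = FALSE)),
        value = as.numeric(vals),
        is_wd = ch$is_wd)
    }, error = function(e)
      stop(sprintf("feature extraction failed on channel '%s': %s",
                   ch$name, conditionMessage(e)), call. = FALSE))
    rows[[ci]] <- res
  }
  sf <- shape_features(pair$mask, pair$spacing)
  rows[[length(channels) + 1L]] <- data.table::data.table(
    patient_id = pair$patient_id, channel = "mask", category = "shape",
    feature = names(sf), value = as.numeric(sf), is_wd = FALSE)
  out <- data.table::rbindlist(rows)
  bad <- !is.finite(out$value)
  if (any(bad)) {
    warning(sum(bad), " non-finite feature value(s) replaced by 0")
    out[bad, "value"] <- 0
  }
  class(out) <- c("feature_vector", class(out))
  out[]
}
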
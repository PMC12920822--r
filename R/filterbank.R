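# 18-channel imaging filter bank: original, 8 undecimated Coiflet-1 wavelet
# components, Laplacian of Gaussian, four monotone intensity transforms,
# gradient magnitude, and three spherical local-binary-pattern maps.

#' Filter-bank configuration
#'
#' @param wavelet mother wavelet name; `"coif1"` (first-order Coiflet) is the
#'   only built-in.
#' @param log_sigma_mm Laplacian-of-Gaussian scale in mm (one sigma: the
#'   18-channel arithmetic implies exactly one LoG channel).
#' @param lbp_radius LBP sphere radius in voxels.
#' @param lbp_samples number of sphere sample points (42: one icosahedron
#'   subdivision).
#' @param enable character subset of
#'   `c("wavelet", "log", "intensity", "gradient", "lbp3d")`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(wavelet = "coif1", log_sigma_mm = 3,
                          lbp_radius = 1, lbp_samples = 42L,
                          enable = c("wavelet", "log", "intensity",
                                     "gradient", "lbp3d")) {
  structure(list(wavelet = wavelet, log_sigma_mm = log_sigma_mm,
                 lbp_radius = lbp_radius, lbp_samples = as.integer(lbp_samples),
                 enable = enable),
            class = "filter_config")
}

filter_channel <- function(name, image, is_wd = FALSE) {
  structure(list(name = name, image = image, is_wd = isTRUE(is_wd)),
            class = "filter_channel")
}

#' @export
print.filter_channel <- function(x, ...) {
  cat(sprintf("<filter_channel %s>%s %s voxels\n", x$name,
              if (x$is_wd) " [WD]" else "",
              paste(dim(x$image), collapse = "x")))
  invisible(x)
}

# Coiflet-1 analysis filters from their closed form; the low-pass sums to
# sqrt(2) and the pair is power-complementary (asserted in tests via perfect
# reconstruction).
.wavelet_filters <- function(name = "coif1") {
  if (!identical(name, "coif1")) stop("unknown wavelet: ", name)
  s7 <- sqrt(7)
  lo <- sqrt(2) / 32 * c(s7 - 3, 1 - s7, 14 - 2 * s7, 14 + 2 * s7, 5 + s7, 1 - s7)
  n <- length(lo)
  hi <- (-1)^(seq_len(n) - 1) * rev(lo)
  list(lo = lo, hi = hi)
}

# circular convolution along an axis: y[n] = sum_k f[k] x[n - (k-1)]
.circ_conv <- function(a, f, axis) {
  cpp_conv_axis(a, as_dim3(a), f, axis - 1L, TRUE, FALSE, 0L)
}

# circular correlation (time-reversed convolution), used for reconstruction
.circ_corr <- function(a, f, axis) {
  cpp_conv_axis(a, as_dim3(a), f, axis - 1L, TRUE, TRUE, 0L)
}

#' One-level undecimated separable 3D wavelet decomposition
#'
#' Stationary (shift-invariant, same-shape) transform with periodic boundary
#' handling. Channel `XYZ` applies filter `X` along axis 1, `Y` along axis 2
#' and `Z` along axis 3 (`L` = low-pass, `H` = high-pass). The eight channels
#' reconstruct the input exactly via [wavelet_reconstruct()].
#'
#' @param image 3D numeric array.
#' @param wavelet_name wavelet name (default `"coif1"`).
#' @return named list of 8 `filter_channel` objects
#'   (`wavelet-LLL` ... `wavelet-HHH`), all flagged `is_wd`.
#' @export
wavelet_decompose <- function(image, wavelet_name = "coif1") {
  flt <- .wavelet_filters(wavelet_name)
  as_dim3(image)
  ax1 <- list(L = .circ_conv(image, flt$lo, 1L),
              H = .circ_conv(image, flt$hi, 1L))
  out <- list()
  for (a in c("L", "H")) {
    ax2 <- list(L = .circ_conv(ax1[[a]], flt$lo, 2L),
                H = .circ_conv(ax1[[a]], flt$hi, 2L))
    for (b in c("L", "H")) {
      for (cc in c("L", "H")) {
        nm <- paste0(a, b, cc)
        out[[paste0("wavelet-", nm)]] <- filter_channel(
          paste0("wavelet-", nm),
          .circ_conv(ax2[[b]], if (cc == "L") flt$lo else flt$hi, 3L),
          is_wd = TRUE)
      }
    }
  }
  out[paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                           "HLL", "HLH", "HHL", "HHH"))]
}

#' Reconstruct an image from its 8 undecimated wavelet channels
#'
#' Inverse of [wavelet_decompose()]: correlation with the same filter pair,
#' halved per axis (the undecimated analysis/synthesis pair satisfies
#' `|H|^2 + |G|^2 = 2` for orthogonal wavelets).
#'
#' @param channels list returned by [wavelet_decompose()].
#' @param wavelet_name wavelet name.
#' @return reconstructed 3D array.
#' @export
wavelet_reconstruct <- function(channels, wavelet_name = "coif1") {
  flt <- .wavelet_filters(wavelet_name)
  get_img <- function(nm) channels[[paste0("wavelet-", nm)]]$image
  rec2 <- list()
  for (a in c("L", "H")) for (b in c("L", "H")) {
    lo3 <- .circ_corr(get_img(paste0(a, b, "L")), flt$lo, 3L)
    hi3 <- .circ_corr(get_img(paste0(a, b, "H")), flt$hi, 3L)
    rec2[[paste0(a, b)]] <- (lo3 + hi3) / 2
  }
  rec1 <- list()
  for (a in c("L", "H")) {
    lo2 <- .circ_corr(rec2[[paste0(a, "L")]], flt$lo, 2L)
    hi2 <- .circ_corr(rec2[[paste0(a, "H")]], flt$hi, 2L)
    rec1[[a]] <- (lo2 + hi2) / 2
  }
  (.circ_corr(rec1$L, flt$lo, 1L) + .circ_corr(rec1$H, flt$hi, 1L)) / 2
}

# centred correlation along an axis with replicate (clamp) boundary padding
.rep_conv <- function(a, f, axis) {
  center0 <- (length(f) + 1L) %/% 2L - 1L
  cpp_conv_axis(a, as_dim3(a), f, axis - 1L, FALSE, TRUE, center0)
}

#' Laplacian-of-Gaussian filter
#'
#' Spacing-aware separable approximation: the LoG response is the sum over
#' axes of a sampled second-derivative-of-Gaussian kernel along that axis
#' combined with Gaussian smoothing along the other two, with sigma given in
#' millimetres. The second-derivative kernels are zero-sum, so constants map
#' exactly to zero.
#'
#' @param image 3D numeric array.
#' @param sigma_mm Gaussian scale in mm (> 0).
#' @param spacing voxel spacing mm 3-vector.
#' @return a `filter_channel` named `log-sigma-<s>-mm`.
#' @export
log_filter <- function(image, sigma_mm = 3, spacing = c(1, 1, 1)) {
  stopifnot(sigma_mm > 0)
  spacing <- stopifnot_spacing(spacing)
  if (sigma_mm < min(spacing) / 2)
    warning("LoG sigma (", sigma_mm, " mm) is below half the smallest voxel ",
            "spacing; the kernel is under-resolved")
  kg <- list(); k2 <- list()
  for (ax in 1:3) {
    s <- spacing[ax]
    r <- max(1L, as.integer(ceiling(4 * sigma_mm / s)))
    x <- (-r:r) * s
    g <- exp(-x^2 / (2 * sigma_mm^2))
    kg[[ax]] <- g / sum(g)
    g2 <- (x^2 / sigma_mm^4 - 1 / sigma_mm^2) * exp(-x^2 / (2 * sigma_mm^2)) * s
    k2[[ax]] <- g2 - mean(g2)   # enforce exact zero response on constants
  }
  acc <- array(0, dim(image))
  for (ax in 1:3) {
    part <- image
    for (bx in 1:3)
      part <- .rep_conv(part, if (bx == ax) k2[[bx]] else kg[[bx]], bx)
    acc <- acc + part
  }
  filter_channel(sprintf("log-sigma-%g-mm", sigma_mm), acc)
}

#' Monotone intensity-transform channels
#'
#' Four per-voxel transforms with output range matched to the input range
#' `M = max(|x|)` (all-zero images map to zero):
#' square `x^2 / M`; squareroot `sign(x) * sqrt(|x| * M)`;
#' logarithm `sign(x) * log(|x| + 1) * M / log(M + 1)`;
#' exponential `exp(x * log(M + 1) / M) - 1`.
#'
#' @param image 3D numeric array.
#' @return named list of 4 `filter_channel` objects.
#' @export
intensity_transforms <- function(image) {
  M <- max(abs(image))
  if (M == 0) {
    z <- array(0, dim(image))
    return(list(square = filter_channel("square", z),
                squareroot = filter_channel("squareroot", z),
                logarithm = filter_channel("logarithm", z),
                exponential = filter_channel("exponential", z)))
  }
  list(
    square = filter_channel("square", image^2 / M),
    squareroot = filter_channel("squareroot", sign(image) * sqrt(abs(image) * M)),
    logarithm = filter_channel("logarithm",
                               sign(image) * log(abs(image) + 1) * M / log(M + 1)),
    exponential = filter_channel("exponential",
                                 exp(image * log(M + 1) / M) - 1)
  )
}

#' Gradient-magnitude channel
#'
#' Per-voxel Euclidean norm of the spacing-aware central-difference gradient
#' (replicate boundary, so borders use one-sided half-differences).
#'
#' @param image 3D numeric array (>= 3 voxels per axis).
#' @param spacing mm 3-vector.
#' @return a `filter_channel` named `gradient`.
#' @export
gradient_filter <- function(image, spacing = c(1, 1, 1)) {
  d <- as_dim3(image)
  stopifnot(all(d >= 3))
  spacing <- stopifnot_spacing(spacing)
  acc <- array(0, d)
  for (ax in 1:3) {
    g <- .rep_conv(image, c(-1, 0, 1) / (2 * spacing[ax]), ax)
    acc <- acc + g^2
  }
  filter_channel("gradient", sqrt(acc))
}

# 42-point sphere sampling scheme: icosahedron vertices plus edge midpoints,
# with the real spherical harmonics of bands 1 and 2 evaluated at each point
.sphere_scheme <- function(n = 42L) {
  key <- paste0("sphere", n)
  if (!is.null(.radrot_env[[key]])) return(.radrot_env[[key]])
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  if (n >= 42L) {
    # append normalized midpoints of the 30 icosahedron edges
    pairs <- which(upper.tri(matrix(0, 12, 12)), arr.ind = TRUE)
    dd <- sqrt(rowSums((v[pairs[, 1], ] - v[pairs[, 2], ])^2))
    edge <- pairs[dd < 1.2, , drop = FALSE]   # edge length ~1.05
    mids <- (v[edge[, 1], ] + v[edge[, 2], ]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
  }
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  Y <- cbind(x, y, z,
             sqrt(3) * x * y, sqrt(3) * y * z, sqrt(3) * z * x,
             sqrt(3) / 2 * (x^2 - y^2), (3 * z^2 - 1) / 2)
  sch <- list(dirs = v, Y = Y)
  .radrot_env[[key]] <- sch
  sch
}

#' Spherical local-binary-pattern channels
#'
#' For each voxel, intensities are sampled (trilinearly) at points on a
#' sphere of the given radius, binarized against the centre voxel, and
#' projected onto real spherical harmonics: `lbp-3D-m1` is the band-1 energy
#' map, `lbp-3D-m2` the band-2 energy map, and `lbp-3D-k` the kurtosis map
#' of the sampled values. The icosahedral sampling makes the maps tolerant
#' (not exactly equivariant) to rotation.
#'
#' @param image 3D numeric array.
#' @param radius_voxels sphere radius in voxels (>= 1).
#' @param n_sphere_samples 42 (icosahedron subdivision) or 12 (icosahedron).
#' @param region optional list with 0-based inclusive `lo`/`hi` index bounds;
#'   maps are computed only inside it (zero elsewhere). Used by the
#'   extraction pipeline, where only the mask neighbourhood is consumed.
#' @return named list of 3 `filter_channel` objects.
#' @export
lbp3d_filter <- function(image, radius_voxels = 1, n_sphere_samples = 42L,
                         region = NULL) {
  d <- as_dim3(image)
  stopifnot(radius_voxels >= 1)
  if (radius_voxels > min(d) / 2)
    stop("LBP radius exceeds half the minimum image extent")
  sch <- .sphere_scheme(n_sphere_samples)
  if (is.null(region)) region <- list(lo = c(0L, 0L, 0L), hi = d - 1L)
  maps <- cpp_lbp3d(image, d, sch$dirs, sch$Y, radius_voxels,
                    as.integer(region$lo), as.integer(region$hi))
  list(`lbp-3D-m1` = filter_channel("lbp-3D-m1", maps$m1),
       `lbp-3D-m2` = filter_channel("lbp-3D-m2", maps$m2),
       `lbp-3D-k` = filter_channel("lbp-3D-k", maps$k))
}

#' Apply the full 18-channel filter bank
#'
#' Produces exactly 18 uniquely named channels in the default configuration:
#' original (1), wavelet (8, flagged WD), LoG (1), square/squareroot/
#' logarithm/exponential (4), gradient (1) and lbp-3D m1/m2/k (3). Errors in
#' a sub-filter propagate with the channel name attached.
#'
#' @param pair preprocessed [volume_pair()].
#' @param config a [filter_config()].
#' @param lbp_region optional region hint for [lbp3d_filter()] (performance
#'   only; `NULL` computes the full maps).
#' @return named list of `filter_channel` objects.
#' @export
apply_filter_bank <- function(pair, config = filter_config(),
                              lbp_region = NULL) {
  stopifnot(inherits(pair, "volume_pair"))
  img <- pair$image
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("filter '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  channels <- list(original = filter_channel("original", img))
  if ("wavelet" %in% config$enable)
    channels <- c(channels, wrap("wavelet",
                                 wavelet_decompose(img, config$wavelet)))
  if ("log" %in% config$enable) {
    ch <- wrap("log", log_filter(img, config$log_sigma_mm, pair$spacing))
    channels[[ch$name]] <- ch
  }
  if ("intensity" %in% config$enable)
    channels <- c(channels, wrap("intensity", intensity_transforms(img)))
  if ("gradient" %in% config$enable) {
    ch <- wrap("gradient", gradient_filter(img, pair$spacing))
    channels[[ch$name]] <- ch
  }
  if ("lbp3d" %in% config$enable) {
    channels <- c(channels, wrap("lbp3d",
                                 lbp3d_filter(img, config$lbp_radius,
                                              config$lbp_samples,
                                              region = lbp_region)))
  } else {
    message("lbp-3D channels disabled: ", length(channels),
            " channels produced (non-default mode)")
  }
  channels
}
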
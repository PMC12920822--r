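# Synthetic CT-like lesion phantoms.
#
# These phantoms are SYNTHETIC stand-ins for a real thorax-CT cohort: an
# ellipsoidal lesion with orientation-bearing texture embedded in a uniform
# background, with additive Gaussian noise. They carry the statistical
# structure the rotation-robustness analysis assumes (directional texture,
# class-dependent texture parameters, anisotropic voxel spacing) but none of
# the physics of real CT.

#' Construct and validate a phantom specification
#'
#' @param grid_shape integer 3-vector, voxels per axis (all >= 8).
#' @param spacing numeric 3-vector, mm per voxel (may be anisotropic).
#' @param lesion_radii numeric 3-vector, mm semi-axes of the ellipsoidal
#'   lesion. The lesion must fit inside the grid with a >= 2 voxel margin.
#' @param texture_kind one of `"isotropic-noise"`, `"oriented-grating"`,
#'   `"oriented-filtered-noise"`, `"none"`.
#' @param texture_orientation unit 3-vector; direction of the grating (or of
#'   the long correlation axis for filtered noise).
#' @param texture_wavelength mm; grating period or noise correlation length.
#' @param texture_amplitude intensity units (HU-like).
#' @param noise_sd additive white-noise SD, intensity units.
#' @param background_level,lesion_level intensity units (HU-like floats; no
#'   DICOM rescale handling).
#' @param lesion_profile `"flat"` (lesion voxels at `lesion_level`) or
#'   `"gaussian"` (radially smooth blob peaking at `lesion_level`; used for
#'   rotation-invariant negative controls).
#' @param class_label integer in `{0, 1, 2}` (histology-like class).
#' @param seed integer; identical spec + seed gives a bit-identical volume.
#' @return a validated `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 32L),
                         spacing = c(1, 1, 3),
                         lesion_radii = c(14, 11, 8),
                         texture_kind = "oriented-grating",
                         texture_orientation = c(1, 0, 0),
                         texture_wavelength = 8,
                         texture_amplitude = 150,
                         noise_sd = 30,
                         background_level = -800,
                         lesion_level = 40,
                         lesion_profile = "flat",
                         class_label = 0L,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- stopifnot_spacing(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three integers all >= 8")
  if (length(lesion_radii) != 3L || any(lesion_radii <= 0))
    stop("lesion_radii must be three positive semi-axes (mm)")
  texture_kind <- match.arg(texture_kind, c("oriented-grating",
                                            "isotropic-noise",
                                            "oriented-filtered-noise",
                                            "none"))
  lesion_profile <- match.arg(lesion_profile, c("flat", "gaussian"))
  o <- as.numeric(texture_orientation)
  no <- sqrt(sum(o^2))
  if (no <= 0) stop("texture_orientation must be a nonzero vector")
  o <- o / no
  if (texture_wavelength <= 0) stop("texture_wavelength must be > 0")
  # fit check: semi-axis in voxels vs half grid minus 2-voxel margin
  rad_vox <- lesion_radii / spacing
  half <- (grid_shape - 1) / 2
  for (ax in 1:3) {
    if (rad_vox[ax] > half[ax] - 2)
      stop(sprintf(
        "lesion does not fit grid along axis %d: semi-axis %.1f voxels, available %.1f",
        ax, rad_vox[ax], half[ax] - 2))
  }
  structure(list(
    grid_shape = grid_shape, spacing = spacing, lesion_radii = lesion_radii,
    texture_kind = texture_kind, texture_orientation = o,
    texture_wavelength = texture_wavelength,
    texture_amplitude = texture_amplitude, noise_sd = noise_sd,
    background_level = background_level, lesion_level = lesion_level,
    lesion_profile = lesion_profile,
    class_label = as.integer(class_label), seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Construct a volume/mask pair
#'
#' A `volume_pair` bundles one lesion: a 3D intensity volume, its binary
#' segmentation mask (same shape), the voxel spacing in mm, a patient id and
#' an optional class label.
#'
#' @param image 3D numeric array.
#' @param mask 3D array coercible to logical, same shape as `image`.
#' @param spacing mm 3-vector.
#' @param patient_id character scalar.
#' @param class_label optional integer.
#' @return a `volume_pair`.
#' @export
volume_pair <- function(image, mask, spacing, patient_id = "P000",
                        class_label = NA_integer_) {
  d1 <- as_dim3(image)
  d2 <- as_dim3(mask)
  if (!identical(d1, d2))
    exclusion_error(sprintf(
      "mismatched image (%s) and mask (%s) dimensions",
      paste(d1, collapse = "x"), paste(d2, collapse = "x")), patient_id)
  m <- array(as.logical(mask != 0), dim = d2)
  structure(list(image = image, mask = m,
                 spacing = stopifnot_spacing(spacing),
                 patient_id = as.character(patient_id),
                 class_label = as.integer(class_label)),
            class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  cat(sprintf("<volume_pair %s> %s voxels @ (%s) mm, %d foreground, class %s\n",
              x$patient_id, paste(dim(x$image), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              sum(x$mask), x$class_label))
  invisible(x)
}

# voxel-center physical coordinates relative to the grid centre, per axis
.axis_coords <- function(n, s) ((seq_len(n) - 1) - (n - 1) / 2) * s

# smooth white noise with a Gaussian kernel (per-axis sigma in voxels) via FFT
.smooth_noise <- function(dim, sigma_vox) {
  w <- array(rnorm(prod(dim)), dim = dim)
  if (all(sigma_vox <= 0)) return(w)
  G <- outer(outer(.freq_gauss(dim[1], sigma_vox[1]),
                   .freq_gauss(dim[2], sigma_vox[2])),
             .freq_gauss(dim[3], sigma_vox[3]))
  dim(G) <- dim
  sm <- Re(fft(fft(w) * G, inverse = TRUE)) / prod(dim)
  sm / sd(sm)
}

.freq_gauss <- function(n, sigma) {
  f <- (seq_len(n) - 1) / n
  f <- ifelse(f > 0.5, f - 1, f)
  exp(-2 * pi^2 * sigma^2 * f^2)
}

#' Generate one synthetic lesion phantom
#'
#' Lesion voxels take `lesion_level + texture + N(0, noise_sd)` and
#' background voxels `background_level + N(0, noise_sd)`; the mask is the
#' ellipsoid indicator. The oriented-grating texture is
#' `amplitude * sin(2*pi*<x, orientation>/wavelength)` evaluated at voxel
#' centres in mm coordinates, so its period is controlled in physical units.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume_pair()].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  cx <- .axis_coords(d[1], spec$spacing[1])
  cy <- .axis_coords(d[2], spec$spacing[2])
  cz <- .axis_coords(d[3], spec$spacing[3])
  X <- array(rep(cx, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)
  rho2 <- (X / spec$lesion_radii[1])^2 + (Y / spec$lesion_radii[2])^2 +
    (Z / spec$lesion_radii[3])^2
  mask <- rho2 <= 1

  with_seed(spec$seed, {
    tex <- array(0, dim = d)
    o <- spec$texture_orientation
    if (spec$texture_kind == "oriented-grating") {
      phase <- (X * o[1] + Y * o[2] + Z * o[3]) / spec$texture_wavelength
      tex <- spec$texture_amplitude * sin(2 * pi * phase)
    } else if (spec$texture_kind == "isotropic-noise") {
      sig <- (spec$texture_wavelength / 2) / spec$spacing
      tex <- spec$texture_amplitude * .smooth_noise(d, sig)
    } else if (spec$texture_kind == "oriented-filtered-noise") {
      # anisotropic smoothing: long axis along the orientation is emulated by
      # smoothing an oriented grating-modulated noise field; cheap and
      # directional without a full steerable filter
      sig <- (spec$texture_wavelength / 2) / spec$spacing
      base <- .smooth_noise(d, sig)
      phase <- (X * o[1] + Y * o[2] + Z * o[3]) / spec$texture_wavelength
      tex <- spec$texture_amplitude * base * cos(2 * pi * phase)
    }
    lesion <- if (spec$lesion_profile == "gaussian") {
      spec$background_level +
        (spec$lesion_level - spec$background_level) * exp(-2 * rho2)
    } else {
      spec$lesion_level
    }
    img <- array(spec$background_level, dim = d)
    if (spec$lesion_profile == "gaussian") img[] <- lesion else img[mask] <- lesion
    img[mask] <- img[mask] + tex[mask]
    if (spec$noise_sd > 0) img <- img + rnorm(prod(d), 0, spec$noise_sd)
    volume_pair(img, mask, spec$spacing,
                patient_id = sprintf("phantom-seed%d", spec$seed),
                class_label = spec$class_label)
  })
}

# documented per-class texture parameter distributions (see vignette):
# class 0 coarse grating, class 1 fine grating, class 2 isotropic noise
.class_texture_defaults <- function() {
  list(
    `0` = list(kind = "oriented-grating", wavelength_mean = 8,  wavelength_sd = 0.8),
    `1` = list(kind = "oriented-grating", wavelength_mean = 4,  wavelength_sd = 0.4),
    `2` = list(kind = "isotropic-noise",  wavelength_mean = 4,  wavelength_sd = 0.4)
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` lesions with class labels sampled from `class_probs`.
#' Per-class texture parameter distributions differ (class 0 coarse oriented
#' grating, class 1 fine oriented grating, class 2 isotropic filtered noise)
#' so classes are partially separable from texture features; each lesion's
#' texture orientation is drawn uniformly on the sphere. A stated fraction of
#' masks receives a spurious island of fewer than 10 voxels, exercising the
#' island-removal step.
#'
#' @param n_patients integer >= 15.
#' @param class_probs length-3 probability vector (sums to 1).
#' @param seed integer cohort seed.
#' @param island_fraction fraction of masks receiving a small spurious
#'   island (default 0.1).
#' @param grid_shape,spacing,lesion_radii passed to [phantom_spec()].
#' @param texture_amplitude,noise_sd intensity units.
#' @return list of [volume_pair()] objects with class labels.
#' @export
make_cohort <- function(n_patients, class_probs = rep(1 / 3, 3), seed = 1L,
                        island_fraction = 0.1,
                        grid_shape = c(48L, 48L, 32L), spacing = c(1, 1, 3),
                        lesion_radii = c(14, 11, 8),
                        texture_amplitude = 150, noise_sd = 30) {
  stopifnot(n_patients >= 15)
  if (abs(sum(class_probs) - 1) > 1e-8 || length(class_probs) != 3)
    stop("class_probs must be a length-3 vector summing to 1")
  if (any(class_probs == 0))
    warning("degenerate class_probs: a class has probability 0")
  cls_defaults <- .class_texture_defaults()
  cohort <- vector("list", n_patients)
  labels <- with_seed(derive_seed(seed, "labels"),
                      sample(0:2, n_patients, replace = TRUE, prob = class_probs))
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    pseed <- derive_seed(seed, pid)
    pars <- with_seed(pseed, {
      cls <- cls_defaults[[as.character(labels[i])]]
      list(
        wl = max(0.5, rnorm(1, cls$wavelength_mean, cls$wavelength_sd)),
        amp = max(10, rnorm(1, texture_amplitude, texture_amplitude * 0.15)),
        kind = cls$kind,
        orient = { v <- rnorm(3); v / sqrt(sum(v^2)) },
        scale = runif(3, 0.85, 1.15),
        island = runif(1) < island_fraction
      )
    })
    spec <- phantom_spec(
      grid_shape = grid_shape, spacing = spacing,
      lesion_radii = lesion_radii * pars$scale,
      texture_kind = pars$kind, texture_orientation = pars$orient,
      texture_wavelength = pars$wl, texture_amplitude = pars$amp,
      noise_sd = noise_sd, class_label = labels[i],
      seed = derive_seed(pseed, "volume")
    )
    pair <- make_phantom(spec)
    pair$patient_id <- pid
    attr(pair, "texture_params") <- pars[c("wl", "amp", "kind")]
    if (pars$island) {
      pair$mask <- with_seed(derive_seed(pseed, "island"),
                             .inject_island(pair$mask))
    }
    cohort[[i]] <- pair
  }
  cohort
}

# add a < 10-voxel spurious 2x2x2-ish island in the background, away from the
# lesion; emulates a manual-segmentation slip
.inject_island <- function(mask) {
  d <- dim(mask)
  for (try in 1:50) {
    at <- sapply(d, function(n) sample(2:(n - 2), 1))
    block <- mask[at[1] + 0:1, at[2] + 0:1, at[3] + 0:1]
    # require clearance of one voxel around the island
    lo <- pmax(at - 1, 1); hi <- pmin(at + 2, d)
    if (!any(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])) {
      mask[at[1] + 0:1, at[2] + 0:1, at[3] + 0:1] <- TRUE
      # drop one voxel so the island has 7 (< 10) voxels
      mask[at[1] + 1, at[2] + 1, at[3] + 1] <- FALSE
      return(mask)
    }
  }
  warning("could not place a spurious island; mask returned unchanged")
  mask
}
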
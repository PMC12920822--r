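# Rotation-perturbation simulator: per-patient sampled rotations grouped
# into sets R5..R80 (label = mean deviation in degrees, SD 10), applied
# about the mask centre of mass; R0 is identity-resampled through the same
# code path so all groups share the interpolation bias.

#' Rotation matrix from axis and angle (Rodrigues)
#'
#' @param axis 3-vector (normalized internally).
#' @param theta_deg rotation angle in degrees.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_from_axis_angle <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_set <- function(label, theta_deg, axis) {
  m <- if (label == 0) diag(3) else rotation_from_axis_angle(axis, theta_deg)
  structure(list(label_degrees = as.integer(label),
                 theta_deg = theta_deg, axis = axis, matrix = m),
            class = "rotation_set")
}

#' Sample per-patient rotation sets
#'
#' For each label `i` in `labels`, the deviation angle is drawn as
#' `theta ~ |N(i, sd_deg)|` (negative draws folded to their magnitude, since
#' theta is a deviation magnitude; the folding bias is reported in the
#' returned attributes) and the rotation axis uniformly on the unit sphere.
#' Label 0 always yields the identity. Draws are deterministic given
#' `(patient_id, seed)`.
#'
#' @param patient_id character id (stream key).
#' @param seed cohort seed.
#' @param labels integer degree labels (default 5, 10, ..., 80).
#' @param sd_deg normal SD in degrees (default 10).
#' @return named list (`R5` ... `R80`) of `rotation_set` objects.
#' @export
sample_rotations <- function(patient_id, seed, labels = seq(5L, 80L, 5L),
                             sd_deg = 10) {
  out <- with_seed(derive_seed(seed, paste0("rot-", patient_id)), {
    lapply(labels, function(lab) {
      if (lab == 0) return(rotation_set(0L, 0, c(0, 0, 1)))
      theta <- abs(rnorm(1, lab, sd_deg))
      z <- runif(1, -1, 1)
      phi <- runif(1, 0, 2 * pi)
      axis <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
      rotation_set(lab, theta, axis)
    })
  })
  names(out) <- paste0("R", labels)
  out
}

# centre of mass of the mask, in physical mm (0-based voxel coords * spacing)
.mask_com <- function(pair) {
  d <- dim(pair$mask)
  idx <- which(pair$mask)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  c(mean(i) * pair$spacing[1], mean(j) * pair$spacing[2],
    mean(k) * pair$spacing[3])
}

#' Rotate an image/mask pair about the mask centre of mass
#'
#' The rigid transform is applied by resampling on the unchanged output grid
#' (trilinear for the image, nearest-neighbour for the mask). Source
#' coordinates within 1e-9 voxel of a lattice point are snapped, so the
#' identity transform and exact 90-degree rotations on matching grids are
#' voxel-exact. An error is raised if the rotated lesion would be clipped by
#' the volume border.
#'
#' @param pair a [volume_pair()] (pre-crop, so context surrounds the
#'   lesion).
#' @param rot a `rotation_set`.
#' @return rotated [volume_pair()] with a `rotation` attribute
#'   (label, theta, axis).
#' @export
rotate_pair <- function(pair, rot) {
  stopifnot(inherits(pair, "volume_pair"), inherits(rot, "rotation_set"))
  d <- as_dim3(pair$image)
  sp <- pair$spacing
  R <- rot$matrix
  com <- .mask_com(pair)
  # forward-map the mask voxels to check the lesion stays inside the grid
  if (rot$label_degrees != 0) {
    idx <- which(pair$mask)
    i <- (idx - 1L) %% d[1]
    j <- ((idx - 1L) %/% d[1]) %% d[2]
    k <- (idx - 1L) %/% (d[1] * d[2])
    pts <- cbind(i * sp[1], j * sp[2], k * sp[3])
    fwd <- sweep(sweep(pts, 2, com) %*% t(R), 2, com, "+")
    vox <- sweep(fwd, 2, sp, "/")
    if (any(vox < -0.5) || any(sweep(vox, 2, d - 0.5, ">")))
      stop("rotated lesion clipped by the volume border (patient ",
           pair$patient_id, ", R", rot$label_degrees, ")")
  }
  # inverse map in voxel-index space: s = D^-1 (R^T (D q - c) + c)
  Dm <- diag(sp); Di <- diag(1 / sp)
  A <- Di %*% t(R) %*% Dm
  b <- as.numeric(Di %*% (com - t(R) %*% com))
  img <- cpp_resample_affine(pair$image, d, A, b, d, 0L)
  msk <- cpp_resample_affine(pair$mask + 0, d, A, b, d, 1L)
  if (!any(msk > 0))
    stop("mask vanished after rotation (patient ", pair$patient_id, ")")
  out <- volume_pair(img, msk, sp, pair$patient_id, pair$class_label)
  attr(out, "rotation") <- list(label = rot$label_degrees,
                                theta_deg = rot$theta_deg, axis = rot$axis)
  out
}

#' Identity-resample a pair
#'
#' Runs the pair through the same resampling code path as [rotate_pair()]
#' with the identity transform, so baseline (R0) features share the
#' interpolation bias of the rotated groups. On the exact lattice the
#' identity resample is bit-preserving.
#'
#' @param pair a [volume_pair()].
#' @return resampled [volume_pair()] labelled R0.
#' @export
identity_resample <- function(pair) {
  rotate_pair(pair, rotation_set(0L, 0, c(0, 0, 1)))
}

#' Build the rotated cohort (R0 plus 16 rotation sets)
#'
#' @param cohort list of preprocessed [volume_pair()] objects.
#' @param seed cohort rotation seed.
#' @param labels degree labels (default 0, 5, ..., 80).
#' @return named list mapping `R<label>` to a list of [volume_pair()];
#'   attribute `manifest` is a `data.table` (patient_id, rotation_label,
#'   theta_deg, axis_x/y/z, seed) sufficient to replay the augmentation.
#' @export
build_rotated_cohort <- function(cohort, seed = 1L,
                                 labels = c(0L, seq(5L, 80L, 5L))) {
  groups <- stats::setNames(
    lapply(labels, function(l) list()), paste0("R", labels))
  man <- list()
  for (pair in cohort) {
    nz <- labels[labels != 0]
    rots <- if (length(nz)) sample_rotations(pair$patient_id, seed,
                                             labels = nz) else list()
    for (lab in labels) {
      key <- paste0("R", lab)
      rs <- if (lab == 0) rotation_set(0L, 0, c(0, 0, 1)) else rots[[key]]
      res <- tryCatch(rotate_pair(pair, rs), error = function(e) {
        warning("patient ", pair$patient_id, " excluded from ", key, ": ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) {
        groups[[key]][[pair$patient_id]] <- res
        man[[length(man) + 1L]] <- data.table::data.table(
          patient_id = pair$patient_id, rotation_label = lab,
          theta_deg = rs$theta_deg, axis_x = rs$axis[1], axis_y = rs$axis[2],
          axis_z = rs$axis[3], seed = seed)
      }
    }
  }
  attr(groups, "manifest") <- data.table::rbindlist(man)
  groups
}
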
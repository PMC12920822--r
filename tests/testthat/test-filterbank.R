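# filterbank: wavelet bank, LoG, intensity transforms, gradient, LBP,
# channel bookkeeping

test_that("undecimated coif1 bank reconstructs perfectly and kills constants", {
  set.seed(7)
  img <- array(rnorm(14 * 11 * 9), c(14, 11, 9))
  ch <- wavelet_decompose(img)
  expect_named(ch, paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                        "HLL", "HLH", "HHL", "HHH")))
  expect_true(all(vapply(ch, function(c) c$is_wd, TRUE)))
  rec <- wavelet_reconstruct(ch)
  expect_lt(max(abs(rec - img)) / max(abs(img)), 1e-6)

  cimg <- array(3.7, c(10, 10, 10))
  cch <- wavelet_decompose(cimg)
  details <- cch[names(cch) != "wavelet-LLL"]
  expect_lt(max(vapply(details, function(c) max(abs(c$image)), 1.0)),
            1e-8 * 3.7)
  # LLL of a constant is proportional to it (gain sqrt(2)^3)
  expect_equal(cch$`wavelet-LLL`$image[5, 5, 5], 3.7 * 2^(3 / 2),
               tolerance = 1e-9)
  expect_error(wavelet_decompose(img, "haar9"), "unknown wavelet")
})

test_that("a pure-x grating concentrates energy in HLL", {
  n <- 32
  x <- array(rep(0:(n - 1), times = n * n), c(n, n, n))
  img <- sin(2 * pi * x / 4)
  ch <- wavelet_decompose(img)
  en <- vapply(ch, function(c) sum(c$image^2), 1.0)
  expect_gt(en["wavelet-HLL"], 10 * en["wavelet-LHL"])
  expect_gt(en["wavelet-HLL"], 10 * en["wavelet-LLH"])

  # 90-degree rotation about z exchanges the first two filter letters
  img90 <- aperm(img[, n:1, ], c(2, 1, 3))
  en90 <- vapply(wavelet_decompose(img90), function(c) sum(c$image^2), 1.0)
  expect_equal(unname(en90["wavelet-LHL"]), unname(en["wavelet-HLL"]),
               tolerance = 1e-9)
  expect_equal(unname(en90["wavelet-HLL"]), unname(en["wavelet-LHL"]),
               tolerance = 1e-9)
})

test_that("LoG responds as a scale-matched blob detector", {
  const <- log_filter(array(2, c(12, 12, 12)), 3, c(1, 1, 1))
  expect_lt(max(abs(const$image)), 1e-10)

  # isotropic Gaussian blob of scale s: extremal response at the centre
  n <- 25; cc <- 12; s <- 3
  ax <- 0:(n - 1)
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  blob <- exp(-((X - cc)^2 + (Y - cc)^2 + (Z - cc)^2) / (2 * s^2))
  resp <- log_filter(blob, s, c(1, 1, 1))$image
  expect_equal(which.min(resp), which.max(blob))  # most negative at centre

  # doubling the spacing with the same sigma_mm halves the per-voxel kernel
  k1 <- radrot:::.rep_conv  # kernel construction is internal; check via dims
  f1 <- log_filter(blob, 3, c(1, 1, 1))
  f2 <- log_filter(blob, 3, c(2, 2, 2))
  expect_s3_class(f2, "filter_channel")
  expect_warning(log_filter(blob, 0.2, c(1, 1, 1)), "sigma")
})

test_that("intensity transforms follow their documented closed forms", {
  z <- intensity_transforms(array(0, c(4, 4, 4)))
  expect_true(all(vapply(z, function(c) all(c$image == 0), TRUE)))

  img <- array(runif(64, -2, 2), c(4, 4, 4))
  img[1] <- -2; img[2] <- 2
  tr <- intensity_transforms(img)
  M <- max(abs(img))
  expect_equal(tr$square$image, img^2 / M, tolerance = 1e-12)
  expect_equal(tr$square$image[1], tr$square$image[2])  # evenness
  expect_equal(tr$squareroot$image, sign(img) * sqrt(abs(img) * M),
               tolerance = 1e-12)
  # monotone on nonnegative inputs
  v <- sort(img[img >= 0])
  expect_true(all(diff(sign(v) * sqrt(abs(v) * M)) >= 0))
  expect_equal(max(tr$exponential$image), M, tolerance = 1e-9)
})

test_that("gradient magnitude matches the closed form on ramps", {
  zero <- gradient_filter(array(1, c(5, 5, 5)), c(1, 1, 1))
  expect_true(all(zero$image == 0))

  n <- 9
  ramp <- array(rep(3 * (0:(n - 1)), times = n * n), c(n, n, n))  # a = 3/vox
  g <- gradient_filter(ramp, c(1, 1, 1))$image
  expect_true(all(abs(g[2:(n - 1), , ] - 3) < 1e-12))

  # ramp along z with 3 mm spacing: slope per mm
  rz <- array(rep(6 * (0:(n - 1)), each = n * n), c(n, n, n))  # 6 per voxel
  gz <- gradient_filter(rz, c(1, 1, 3))$image
  expect_true(all(abs(gz[, , 2:(n - 1)] - 2) < 1e-12))          # 6/3 mm^-1
})

test_that("LBP maps behave on constant and symmetric inputs", {
  cm <- lbp3d_filter(array(5, c(8, 8, 8)))
  expect_length(cm, 3)
  for (ch in cm) expect_equal(max(ch$image) - min(ch$image), 0)

  # spherically symmetric blob: centre-voxel m1/m2 invariant to rotation
  n <- 15; cc <- 7
  ax <- 0:(n - 1)
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  blob <- exp(-((X - cc)^2 + (Y - cc)^2 + (Z - cc)^2) / 18)
  m <- lbp3d_filter(blob)
  m90 <- lbp3d_filter(aperm(blob[, n:1, ], c(2, 1, 3)))
  expect_equal(m$`lbp-3D-m1`$image[cc + 1, cc + 1, cc + 1],
               m90$`lbp-3D-m1`$image[cc + 1, cc + 1, cc + 1],
               tolerance = 1e-9)
  # rotating a random image approximately commutes with the maps
  set.seed(3)
  r <- blob + array(rnorm(n^3, 0, 0.05), c(n, n, n))
  mr <- lbp3d_filter(r)$`lbp-3D-k`$image
  m90r <- lbp3d_filter(aperm(r[, n:1, ], c(2, 1, 3)))$`lbp-3D-k`$image
  back <- aperm(m90r, c(2, 1, 3))[, n:1, ]
  core <- 4:(n - 3)
  expect_lt(median(abs(back - mr)[core, core, core]),
            0.15 * sd(mr[core, core, core]))
  expect_error(lbp3d_filter(blob, radius_voxels = 20), "radius")
})

test_that("apply_filter_bank yields exactly 18 channels, 8 flagged WD", {
  co <- make_cohort(15, seed = 13, grid_shape = c(24, 24, 16),
                    lesion_radii = c(7, 6, 5))
  p <- preprocess_pair(co[[1]])
  ch <- apply_filter_bank(p)
  expect_length(ch, 18)
  expect_equal(sum(vapply(ch, function(c) c$is_wd, TRUE)), 8)
  expect_equal(anyDuplicated(names(ch)), 0)
  for (c in ch) expect_equal(dim(c$image), dim(p$image))

  cfg <- filter_config(enable = c("wavelet", "log", "intensity", "gradient"))
  expect_message(ch15 <- apply_filter_bank(p, cfg), "disabled")
  expect_length(ch15, 15)

  # sub-filter errors carry the channel name
  bad <- p; bad$spacing <- c(1, 1, 1)
  expect_error(apply_filter_bank(volume_pair(array(1, c(2, 2, 2)),
                                             array(TRUE, c(2, 2, 2)),
                                             c(1, 1, 1))),
               "gradient")
})
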
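# features: first-order, shape, texture-matrix oracles, cardinalities,
# rotation invariance

test_that("first-order features match hand arithmetic", {
  const <- array(4.2, c(3, 3, 3))
  mk <- array(TRUE, c(3, 3, 3))
  f <- firstorder_features(const, mk, 0.1)
  expect_equal(unname(f["Mean"]), 4.2)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)
  expect_equal(unname(f["Skewness"]), 0)

  img <- array(0, c(2, 2, 1))
  img[, , 1] <- c(1, 2, 3, 4)
  f2 <- firstorder_features(img, array(TRUE, c(2, 2, 1)), 1, c(1, 1, 1))
  expect_equal(unname(f2["Mean"]), 2.5)
  expect_equal(unname(f2["Range"]), 3)
  expect_equal(unname(f2["Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f2["Median"]), 2.5)
  expect_lt(abs(f2["Skewness"]), 1e-12)   # symmetric values
  expect_length(f2, 18)
})

test_that("shape features: single voxel, digitized ball, rod", {
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  s <- shape_features(single, c(1, 1, 1))
  expect_equal(unname(s["VoxelVolume"]), 1)
  expect_length(s, 14)

  # digitized r = 10 mm ball: sphericity close to the analytic 1.0
  b <- ball_mask(27, 10)
  sb <- shape_features(b, c(1, 1, 1))
  expect_gte(unname(sb["Sphericity"]), 0.95)
  expect_lte(unname(sb["Sphericity"]), 1.0)
  expect_equal(unname(sb["VoxelVolume"]), sum(b))
  expect_equal(unname(sb["MeshVolume"]), 4 / 3 * pi * 1000, tolerance = 0.06)

  # 1x1x5 rod at 1 mm spacing in z-direction: diameter spans 4 voxel centres
  rod <- array(FALSE, c(5, 5, 9)); rod[3, 3, 3:7] <- TRUE
  sr <- shape_features(rod, c(1, 1, 3))
  expect_equal(unname(sr["Maximum3DDiameter"]), 4 * 3)
  # PCA oracle: coordinates (0,0,3k), population covariance eigenvalues
  zs <- (3:7 - 1) * 3
  ev1 <- mean((zs - mean(zs))^2)
  expect_equal(unname(sr["MajorAxisLength"]), 4 * sqrt(ev1), tolerance = 1e-9)
  expect_lt(unname(sr["Elongation"]), 0.01)
})

test_that("count-matrix builders equal brute-force oracles on random arrays", {
  set.seed(42)
  for (trial in 1:20) {
    d <- sample(3:6, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    lev <- array(sample.int(ng, prod(d), replace = TRUE), d)
    msk <- array(runif(prod(d)) < 0.8, d)
    if (!any(msk)) msk[1] <- TRUE
    attr(lev, "n_levels") <- ng

    expect_identical(unname(glcm_matrix(lev, msk, ng) + 0),
                     unname(oracle_glcm(lev, msk, ng) + 0))

    got_rl <- radrot:::cpp_glrlm_counts(as.integer(lev), as.logical(msk),
                                        dim(lev), ng)
    want_rl <- oracle_glrlm(lev, msk, ng)
    expect_identical(unname(got_rl[, seq_len(dim(want_rl)[2]), ] + 0),
                     unname(want_rl + 0))

    z <- radrot:::cpp_glszm_zones(as.integer(lev), as.logical(msk), dim(lev))
    zo <- oracle_glszm(lev, msk)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(z), key(zo))

    expect_identical(unname(radrot:::cpp_gldm_counts(as.integer(lev),
                                                     as.logical(msk),
                                                     dim(lev), ng, 0L) + 0),
                     unname(oracle_gldm(lev, msk, ng) + 0))

    nt <- radrot:::cpp_ngtdm_stats(as.integer(lev), as.logical(msk),
                                   dim(lev), ng)
    expect_equal(unname(nt + 0), unname(oracle_ngtdm(lev, msk, ng) + 0),
                 tolerance = 1e-12)
  }
})

test_that("GLCM matrix on the 2x2x1 worked example equals pair enumeration", {
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  msk <- array(TRUE, c(2, 2, 1))
  attr(lev, "n_levels") <- 2L
  got <- glcm_matrix(lev, msk, 2L)
  want <- oracle_glcm(lev, msk, 2L)
  expect_identical(unname(got + 0), unname(want + 0))
  # direction (1,0,0): pairs (1,1) and (2,2), symmetric
  expect_equal(got[, , 1], matrix(c(2, 0, 0, 2), 2, 2))

  f <- glcm_features(lev, msk)
  expect_length(f, 24)
  # relabelling levels by a permutation leaves JointEnergy unchanged
  lev2 <- array(3L - as.integer(lev), dim(lev))
  attr(lev2, "n_levels") <- 2L
  expect_equal(unname(glcm_features(lev2, msk)["JointEnergy"]),
               unname(f["JointEnergy"]))
})

test_that("constant regions produce the documented degenerate values", {
  lev <- array(1L, c(3, 3, 3)); attr(lev, "n_levels") <- 1L
  msk <- array(TRUE, c(3, 3, 3))
  g <- glcm_features(lev, msk)
  expect_equal(unname(g["MaximumProbability"]), 1)
  expect_equal(unname(g["JointEntropy"]), 0)
  expect_equal(unname(g["Correlation"]), 1)
  expect_equal(unname(g["MCC"]), 1)

  z <- glszm_features(lev, msk)
  expect_equal(unname(z["ZonePercentage"]), 1 / 27)  # one zone of 27 voxels
  expect_equal(unname(z["LargeAreaEmphasis"]), 27^2)

  # run percentage equals (#runs)/(#voxels), oracle-checked per direction
  r <- glrlm_features(lev, msk)
  rl <- oracle_glrlm(lev, msk, 1L)
  rp <- mean(apply(rl, 3, sum) / 27)
  expect_equal(unname(r["RunPercentage"]), rp)
})

test_that("NGTDM features match a brute-force recomputation on a checkerboard", {
  d <- c(4, 4, 4)
  idx <- array(0L, d)
  for (k in 1:4) for (j in 1:4) for (i in 1:4)
    idx[i, j, k] <- (i + j + k) %% 2L
  lev <- idx + 1L
  attr(lev, "n_levels") <- 2L
  msk <- array(TRUE, d)
  st <- oracle_ngtdm(lev, msk, 2L)
  n_i <- st[, 1]; s_i <- st[, 2]; p_i <- n_i / sum(n_i)
  want_coarse <- 1 / sum(p_i * s_i)
  ngp <- sum(p_i > 0)
  want_contrast <- sum(outer(p_i, p_i) * outer(1:2, 1:2, "-")^2) /
    (ngp * (ngp - 1)) * sum(s_i) / sum(n_i)
  f <- ngtdm_features(lev, msk)
  expect_equal(unname(f["Coarseness"]), want_coarse)
  expect_equal(unname(f["Contrast"]), want_contrast)
})

test_that("family cardinalities and extract_all bookkeeping are exact", {
  co <- make_cohort(15, seed = 31, grid_shape = c(24, 24, 16),
                    lesion_radii = c(7, 6, 5))
  p <- preprocess_pair(co[[2]])
  iso <- resample_isotropic(crop_to_bbox(identity_resample(p), 4), 1)
  fv <- extract_all(iso, bin_width = 0.1)
  counts <- table(fv$category)
  expect_equal(as.integer(counts[c("firstorder", "glcm", "glrlm", "glszm",
                                   "gldm", "ngtdm")]),
               c(18, 24, 16, 16, 14, 5) * 18L)
  expect_equal(as.integer(counts["shape"]), 14L)
  expect_equal(nrow(fv[fv$channel != "mask", ]), 1674)
  expect_equal(sum(fv$is_wd), 744)
  expect_equal(nrow(fv[!fv$is_wd & fv$category != "shape", ]), 930)
  expect_true(all(is.finite(fv$value)))
  expect_equal(length(unique(fv$channel[fv$channel != "mask"])), 18)
  # 93 features per channel
  perch <- table(fv$channel[fv$channel != "mask"])
  expect_true(all(perch == 93))
  # determinism
  fv2 <- extract_all(iso, bin_width = 0.1)
  expect_equal(fv$value, fv2$value)
})

test_that("all 93 features are invariant under 90-degree rotation on a cubic grid", {
  sp <- phantom_spec(grid_shape = c(21, 21, 21), spacing = c(1, 1, 1),
                     lesion_radii = c(7, 5, 6),
                     texture_orientation = c(1, 2, 0.5), noise_sd = 15,
                     seed = 8L)
  p <- make_phantom(sp)
  rot <- volume_pair(aperm(p$image[, 21:1, ], c(2, 1, 3)),
                     aperm(p$mask[, 21:1, ], c(2, 1, 3)),
                     p$spacing, p$patient_id)
  fv <- extract_all(p, bin_width = 10)
  fr <- extract_all(rot, bin_width = 10)
  m <- merge(as.data.frame(fv), as.data.frame(fr),
             by = c("channel", "category", "feature"))
  # direction-averaged texture families: invariant; wavelet channels permute
  # names, so compare only non-wavelet channels here
  tex <- m[!grepl("wavelet", m$channel) & m$category != "shape" &
             !grepl("lbp", m$channel), ]
  expect_gt(nrow(tex), 500)
  expect_lt(max(abs(tex$value.x - tex$value.y) /
                  pmax(abs(tex$value.x), 1e-9)), 1e-9)
})
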
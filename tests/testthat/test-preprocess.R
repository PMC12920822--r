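# preprocess: normalization, mask cleaning, cropping, resampling,
# discretization

test_that("zscore_normalize matches a direct Otsu-foreground recomputation", {
  set.seed(4)
  img <- array(c(rnorm(500, 0, 1), rnorm(500, 100, 5)), c(10, 10, 10))
  z <- zscore_normalize(img)
  thr <- otsu_threshold(img)
  fg <- img > thr
  expect_lt(abs(mean(z[fg])), 1e-6)
  expect_lt(abs(sd(z[fg]) - 1), 1e-6)

  # affine equivariance: a*x + b gives the same output
  z2 <- zscore_normalize(3.5 * img + 120)
  expect_equal(z2, z, tolerance = 1e-9)

  # idempotency up to tolerance
  expect_equal(zscore_normalize(z), z, tolerance = 1e-6)

  # constant foreground -> error
  bim <- array(rep(c(0, 100), each = 500), c(10, 10, 10))
  expect_error(zscore_normalize(bim), "constant foreground")
})

test_that("clean_mask implements the fewer-than-10-voxel rule", {
  m <- array(FALSE, c(12, 12, 6))
  m[2:4, 2:4, 2] <- TRUE      # 9-voxel plate + 3 more = 12 voxels
  m[2:4, 2, 3] <- TRUE
  m[9:10, 9:10, 4] <- TRUE    # 4-voxel island
  out <- clean_mask(m, 10)
  lab <- oracle_label(out)
  expect_equal(max(lab), 1)
  expect_equal(sum(out), 12)

  # boundary: exactly 10 connected voxels is NOT fewer than 10 -> kept
  m10 <- array(FALSE, c(8, 8, 8)); m10[2:6, 3, 3] <- TRUE; m10[2:6, 4, 3] <- TRUE
  expect_equal(sum(clean_mask(m10, 10)), 10)

  # everything small -> error
  tiny <- array(FALSE, c(8, 8, 8)); tiny[2:3, 2, 2] <- TRUE
  expect_error(clean_mask(tiny, 10), "no lesion")

  # never increases foreground; all surviving components >= threshold
  set.seed(9)
  rnd <- array(runif(8^3) < 0.2, c(8, 8, 8))
  cl <- tryCatch(clean_mask(rnd, 5), error = function(e) NULL)
  if (!is.null(cl)) {
    expect_lte(sum(cl), sum(rnd))
    lab <- oracle_label(cl)
    expect_true(all(tabulate(lab[lab > 0]) >= 5))
  }
})

test_that("check_pair flags mismatches and empty masks as exclusions", {
  p <- volume_pair(array(0, c(4, 4, 4)), array(TRUE, c(4, 4, 4)), c(1, 1, 1),
                   "OK1")
  expect_identical(check_pair(p), p)
  expect_error(volume_pair(array(0, c(4, 4, 4)), array(TRUE, c(3, 4, 4)),
                           c(1, 1, 1), "BAD"), class = "radrot_exclusion")
  empty <- volume_pair(array(0, c(4, 4, 4)), array(FALSE, c(4, 4, 4)),
                       c(1, 1, 1), "EMPTY")
  err <- tryCatch(check_pair(empty), condition = function(c) c)
  expect_s3_class(err, "radrot_exclusion")
  expect_match(conditionMessage(err), "EMPTY")
})

test_that("crop_to_bbox preserves the mask and clips margins", {
  img <- array(rnorm(16^3), c(16, 16, 16))
  m <- array(FALSE, c(16, 16, 16)); m[8, 9, 7] <- TRUE
  p <- volume_pair(img, m, c(1, 1, 1))
  c0 <- crop_to_bbox(p, 0)
  expect_equal(dim(c0$image), c(1, 1, 1))
  expect_equal(c0$image[1, 1, 1], img[8, 9, 7])

  m2 <- ball_mask(16, 4)
  p2 <- volume_pair(img, m2, c(1, 1, 1))
  c2 <- crop_to_bbox(p2, 2)
  expect_equal(sum(c2$mask), sum(m2))
  expect_true(all(dim(c2$image) <= dim(m2)))

  # margin larger than the volume clips to the full extent
  cbig <- crop_to_bbox(p2, 100)
  expect_equal(dim(cbig$image), dim(img))
})

test_that("modal_spacing takes the most frequent axis value, ties smallest", {
  mk <- function(sp) volume_pair(array(0, c(4, 4, 4)),
                                 array(TRUE, c(4, 4, 4)), sp)
  expect_equal(modal_spacing(rep(list(mk(c(1, 1, 3))), 10)), 1)
  expect_equal(modal_spacing(list(mk(c(2, 2, 2)))), 2)
  # tie between 1 and 3 -> 1
  expect_equal(modal_spacing(list(mk(c(1, 3, 1)), mk(c(3, 1, 3)))), 1)
})

test_that("resample_isotropic is exact on identity/constant/ramp cases", {
  img <- array(rnorm(10 * 12 * 8), c(10, 12, 8))
  m <- array(FALSE, c(10, 12, 8)); m[4:7, 5:8, 3:6] <- TRUE
  p <- volume_pair(img, m, c(2, 2, 2))
  same <- resample_isotropic(p, 2)
  expect_identical(same$image, img)     # identity resample
  expect_identical(same$mask, m)

  cp <- volume_pair(array(7, c(10, 12, 8)), m, c(2, 2, 2))
  down <- resample_isotropic(cp, 3)
  expect_true(all(abs(down$image - 7) < 1e-12))

  # linear ramp: interior voxels equal the ramp at the new centres
  ramp <- array(rep((0:9) * 2, times = 12 * 8), c(10, 12, 8))  # 1 per mm in x
  rp <- volume_pair(ramp, m, c(2, 2, 2))
  r2 <- resample_isotropic(rp, 4)
  expect_equal(r2$image[2, 3, 2], 4 * 1, tolerance = 1e-9)
  expect_equal(r2$image[4, 2, 2], 12, tolerance = 1e-9)

  expect_error(resample_isotropic(p, 1000), "vanish")
})

test_that("discretize applies the anchored fixed-bin-width rule", {
  img <- array(c(0, 10, 30, 0, 0, 0, 0, 0), c(2, 2, 2))
  msk <- array(c(TRUE, TRUE, TRUE, rep(FALSE, 5)), c(2, 2, 2))
  lev <- discretize(img, msk, 25)
  expect_equal(lev[msk], c(1L, 1L, 2L))
  expect_equal(attr(lev, "n_levels"), 2L)

  const <- discretize(array(5, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 25)
  expect_true(all(const == 1L))
  expect_equal(attr(const, "n_levels"), 1L)

  # monotone: x <= y implies level(x) <= level(y)
  set.seed(2)
  v <- array(runif(64, -3, 3), c(4, 4, 4))
  lv <- discretize(v, array(TRUE, c(4, 4, 4)), 0.4)
  o <- order(as.vector(v))
  expect_true(all(diff(as.vector(lv)[o]) >= 0))
})

test_that("preprocess_pair composes normalization and cleaning", {
  co <- make_cohort(15, seed = 21, island_fraction = 1)
  p <- preprocess_pair(co[[1]])
  lab <- oracle_label(p$mask)
  expect_equal(max(lab), 1)  # island removed
  thr <- otsu_threshold(p$image)
  fg <- p$image > thr
  expect_lt(abs(mean(p$image[fg])), 1e-6)
})
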
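# stability: percentage differences, IQR confidence intervals, Spearman
# strata, subgroup aggregation

test_that("percent_difference follows the guarded signed formula", {
  expect_equal(percent_difference(3, 2), 50)
  expect_equal(percent_difference(2, 2), 0)
  expect_equal(percent_difference(1e-9, 0, eps = 1e-6), 100 * 1e-9 / 1e-6)
  expect_true(is.finite(percent_difference(1, 0)))
  # antisymmetry up to the denominator change
  expect_equal(percent_difference(3, 2) * 2, -percent_difference(2, 3) * 3)
})

test_that("iqr_with_ci uses type-7 quantiles and the t interval", {
  v <- list(`5` = c(1, 2, 3, 4), `10` = c(1, 2, 3, 4))
  res <- iqr_with_ci(v)
  q <- quantile(c(1, 2, 3, 4), c(0.25, 0.75), type = 7)
  expect_equal(unname(res$per_label_iqr[1]), unname(q[2] - q[1]))  # 1.5

  # identical per-label IQRs give a zero-width interval
  same <- iqr_with_ci(list(`5` = c(0, 0, 2, 2), `10` = c(5, 5, 7, 7),
                           `15` = c(1, 1, 3, 3)))
  expect_equal(same$mean_iqr, 2)
  expect_equal(same$ci, c(2, 2))

  # per-label IQRs {2, 4}: mean 3, CI from t with 1 df
  two <- iqr_with_ci(list(`5` = c(0, 0, 2, 2), `10` = c(0, 0, 4, 4)))
  half <- qt(0.975, 1) * sd(c(2, 4)) / sqrt(2)
  expect_equal(two$mean_iqr, 3)
  expect_equal(two$ci, c(3 - half, 3 + half))
})

test_that("spearman_vs_rotation strata and conventions", {
  # y strictly increasing with the label: maximal rank agreement given the
  # tied x ranks within labels
  inc <- list(`5` = 1:4, `10` = 5:8, `15` = 9:12)
  s <- spearman_vs_rotation(inc)
  expect_gt(s$cc, 0.9)
  expect_equal(s$stratum, "strong")
  expect_true(s$significant_nontrivial)
  # one point per label, strictly increasing -> exactly 1
  one <- stats::setNames(as.list(1:10), seq(5, 50, 5))
  s1p <- spearman_vs_rotation(one)
  expect_equal(s1p$cc, 1, tolerance = 1e-9)

  # boundary strata are inclusive on the left
  expect_equal(effect_stratum(0.3), "moderate")
  expect_equal(effect_stratum(0.1), "weak")
  expect_equal(effect_stratum(-0.7), "strong")
  expect_equal(effect_stratum(0.0999), "trivial")

  const <- list(`5` = rep(1, 5), `10` = rep(1, 5), `15` = rep(1, 5))
  expect_warning(sc <- spearman_vs_rotation(const), "constant")
  expect_equal(sc$cc, 0)
  expect_equal(sc$p, 1)

  # label-independent y: |CC| < 0.1 with high probability at large n
  set.seed(5)
  null <- lapply(seq(5, 80, 5), function(l) rnorm(50))
  names(null) <- seq(5, 80, 5)
  sn <- spearman_vs_rotation(null)
  expect_lt(abs(sn$cc), 0.1)

  # invariant to strictly monotone transforms of y
  y <- lapply(seq(5, 20, 5), function(l) runif(10) + l / 10)
  names(y) <- seq(5, 20, 5)
  s1 <- spearman_vs_rotation(y)
  s2 <- spearman_vs_rotation(lapply(y, function(v) exp(3 * v)))
  expect_equal(s1$cc, s2$cc)
})

test_that("feature_stability produces consistent records on a toy table", {
  # two features: one rotation-sensitive (grows with label), one stable
  set.seed(6)
  labs <- c(0, seq(5, 80, 5))
  pats <- sprintf("P%02d", 1:8)
  grid <- expand.grid(patient_id = pats, rotation = labs,
                      stringsAsFactors = FALSE)
  mk <- function(f) data.table::data.table(
    patient_id = grid$patient_id, rotation = grid$rotation,
    channel = "original", category = "firstorder", feature = f,
    is_wd = FALSE)
  sens <- mk("sensitive")
  sens$value <- 10 + grid$rotation * 0.3 + rnorm(nrow(grid), 0, 0.05)
  stab <- mk("stable")
  stab$value <- 5 + rnorm(nrow(grid), 0, 1e-4)
  recs <- feature_stability(rbind(sens, stab))
  expect_equal(nrow(recs), 2)
  r1 <- recs[recs$feature == "sensitive", ]
  r2 <- recs[recs$feature == "stable", ]
  expect_true(r1$significant_nontrivial)
  expect_gt(r1$spearman_cc, 0.7)
  expect_false(r2$significant_nontrivial)
  expect_gt(r1$mean_iqr, r2$mean_iqr)
  expect_true(all(paste0("iqr_R", seq(5, 80, 5)) %in% names(recs)))
  expect_true(r1$iqr_ci_lo <= r1$mean_iqr && r1$mean_iqr <= r1$iqr_ci_hi)
})

test_that("aggregate_subgroups reproduces the percentage convention", {
  recs <- data.table::data.table(
    channel = rep("wavelet-LLH", 93), category = "glcm",
    feature = sprintf("f%02d", 1:93), is_wd = TRUE,
    mean_iqr = rep(c(3, 5), length.out = 93),
    iqr_ci_lo = 0, iqr_ci_hi = 10, spearman_cc = 0.5, spearman_p = 0.001,
    stratum = "moderate",
    significant_nontrivial = c(rep(TRUE, 50), rep(FALSE, 43)))
  sub <- aggregate_subgroups(recs)
  # 50 of 93 flagged -> 53.76%
  expect_equal(round(sub$per_channel$pct_significant, 2), 53.76)
  expect_equal(sub$per_channel$n_flagged, 50)
  # weighted mean of the channel x category cell
  expect_equal(sub$iqr$mean_iqr, mean(rep(c(3, 5), length.out = 93)))
})
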
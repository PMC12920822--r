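# modeling: feature filtering/selection, classifiers, CV protocol, trends

# small synthetic feature table helper: n patients x 3 classes with a few
# informative columns among noise
toy_matrix <- function(n = 30, p_signal = 4, p_noise = 20, sep = 3,
                       seed = 1) {
  set.seed(seed)
  y <- rep(1:3, length.out = n)
  X <- matrix(rnorm(n * (p_signal + p_noise)), n)
  # give every class its own signal direction so the problem is one-vs-rest
  # separable (a shared direction is not, for the middle class)
  for (s in seq_len(p_signal))
    X[, s] <- X[, s] + sep * (y == ((s - 1) %% 3 + 1))
  colnames(X) <- c(sprintf("sig%02d", seq_len(p_signal)),
                   sprintf("noise%02d", seq_len(p_noise)))
  rownames(X) <- sprintf("P%03d", seq_len(n))
  list(X = X, y = y)
}

test_that("prelim_filter drops constant and duplicated features", {
  tm <- toy_matrix()
  X <- cbind(tm$X, constant = 1, dup = tm$X[, "sig01"])
  out <- prelim_filter(X, 0.95)
  expect_false("constant" %in% colnames(out))
  expect_true(xor("dup" %in% colnames(out), "sig01" %in% colnames(out)))
  expect_true("sig01" %in% colnames(out))  # keep-first ordering
})

test_that("feature_wide partitions WD and non-WD correctly", {
  ft <- data.table::data.table(
    patient_id = rep(c("A", "B"), each = 4),
    rotation = 0,
    channel = rep(c("wavelet-LLH", "original", "gradient", "mask"), 2),
    category = rep(c("glcm", "glcm", "glcm", "shape"), 2),
    feature = rep(c("f", "f", "f", "Sphericity"), 2),
    value = rnorm(8),
    is_wd = rep(c(TRUE, FALSE, FALSE, FALSE), 2))
  wd <- feature_wide(ft, 0, "WD")
  expect_true(all(grepl("wavelet", colnames(wd))))
  nwd <- feature_wide(ft, 0, "nWD")
  expect_false(any(grepl("wavelet", colnames(nwd))))
  expect_true(any(grepl("shape", colnames(nwd))))
  nwd2 <- feature_wide(ft, 0, "nWD", include_shape = FALSE)
  expect_false(any(grepl("shape", colnames(nwd2))))
})

test_that("fine_select finds signal columns within the cap", {
  tm <- toy_matrix(n = 45, sep = 4)
  sel <- fine_select(tm$X, tm$y, max_features = 10, top_k = 15)
  expect_lte(length(sel), 10)
  expect_true(any(grepl("^sig", sel)))
  expect_identical(sel, fine_select(tm$X, tm$y, max_features = 10,
                                    top_k = 15))
  sel1 <- fine_select(tm$X, tm$y, max_features = 1, top_k = 15)
  expect_lte(length(sel1), 1)
  expect_error(fine_select(tm$X, rep(1, 45), 10), "single class")
})

test_that("all five classifiers separate an easy problem deterministically", {
  tm <- toy_matrix(n = 45, sep = 5, seed = 2)
  Z <- scale(tm$X[, 1:6])
  for (kind in c("knn", "logistic", "random_forest", "svm_linear",
                 "svm_rbf")) {
    m <- fit_classifier(kind, Z, tm$y, seed = 7)
    pred <- predict_classifier(m, Z)
    expect_gt(mean(pred == tm$y), 0.9)
    m2 <- fit_classifier(kind, Z, tm$y, seed = 7)
    expect_identical(predict_classifier(m2, Z), pred)
  }
  expect_error(fit_classifier("knn", Z, rep(2, 45)), "single class")
})

test_that("macro metrics match hand confusion-matrix arithmetic", {
  truth <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  pred <- c(1, 1, 2, 2, 2, 3, 3, 3, 3)
  met <- macro_metrics(truth, pred, classes = 1:3)
  # per-class recalls: 2/3, 2/3, 3/3
  expect_equal(unname(met["macro_sensitivity"]), mean(c(2 / 3, 2 / 3, 1)))
  expect_equal(unname(met["accuracy"]), 7 / 9)
  # perfect classifier: specificity 1
  perf <- macro_metrics(truth, truth, classes = 1:3)
  expect_equal(unname(perf["macro_specificity"]), 1)
  expect_equal(unname(perf["macro_f1"]), 1)
  expect_true(all(met >= 0 & met <= 1))
})

# compact synthetic long-format feature table over rotation labels for CV
toy_feature_table <- function(n = 24, labels = c(0, 20, 40, 60, 80),
                              seed = 3, degrade_wd = TRUE) {
  set.seed(seed)
  pats <- sprintf("P%03d", 1:n)
  y <- rep(0:2, length.out = n)
  rows <- list()
  for (f in 1:6) {
    wd <- f <= 3
    base <- if (wd) 2 * y + rnorm(n, 0, 0.6) else 2 * y + rnorm(n, 0, 0.8)
    for (lab in labels) {
      val <- base
      if (wd && degrade_wd && lab > 0)
        val <- base * (1 - lab / 100) + rnorm(n, 0, 0.2 + lab / 80)
      rows[[length(rows) + 1]] <- data.table::data.table(
        patient_id = pats, rotation = lab,
        channel = if (wd) "wavelet-LLH" else "original",
        category = "glcm", feature = sprintf("f%d", f),
        value = val, is_wd = wd)
    }
  }
  list(table = data.table::rbindlist(rows),
       labels = stats::setNames(y, pats))
}

test_that("run_repeated_cv produces the exact cycle accounting", {
  tf <- toy_feature_table()
  cfg <- pipeline_config(n_repeats = 2, n_folds = 5,
                         classifiers = c("knn", "logistic"),
                         partitions = c("WD", "nWD"), max_features = 3,
                         top_k_prefilter = 3, seed = 11)
  rec <- run_repeated_cv(tf$table, tf$labels, cfg)
  # 2 repeats x 5 folds = 10 cycles per classifier and partition
  cyc <- unique(rec[, c("partition", "repeat_idx", "fold_idx")])
  expect_equal(nrow(cyc), 2 * 2 * 5)
  expect_equal(nrow(rec), 2 * 10 * 2 * 5)  # x classifiers x labels
  expect_true(all(rec$accuracy >= 0 & rec$accuracy <= 1))
  # every patient appears in exactly one test fold per repeat: fold sizes
  # sum to n and folds are disjoint by construction of the partition
  expect_true(all(rec$n_test >= 3))
  tab <- rec[rec$classifier == "knn" & rec$rotation_label == 0 &
               rec$partition == "WD", ]
  expect_equal(sum(tab$n_test), 2 * length(tf$labels))
})

test_that("no test-fold leakage: a test-only canary cannot inflate R0 accuracy", {
  # make the class signal weak so only the canary could give accuracy 1.0
  tf <- toy_feature_table(n = 24, seed = 9, degrade_wd = FALSE)
  tbl <- tf$table
  tbl$value <- tbl$value + rnorm(nrow(tbl), 0, 4)
  cfg <- pipeline_config(n_repeats = 1, n_folds = 4, classifiers = "logistic",
                         partitions = "nWD", max_features = 3,
                         top_k_prefilter = 4, seed = 5)
  # replay the (seeded) fold assignment to learn which patients land in the
  # test fold of the single repeat, then plant a canary that equals the
  # class label on exactly those rows and is pure noise on training rows
  pats <- sort(names(tf$labels))
  y <- tf$labels[pats] + 1L
  folds <- radrot:::.stratified_folds(y, 4, derive_seed(5, "nWD-rep1"))
  test_ids <- pats[folds == 1]
  set.seed(2)
  can <- data.table::rbindlist(lapply(unique(tbl$rotation), function(l)
    data.table::data.table(
      patient_id = pats, rotation = l, channel = "original",
      category = "glcm", feature = "canary",
      value = ifelse(pats %in% test_ids, as.numeric(tf$labels[pats]),
                     rnorm(length(pats), 0, 1)),
      is_wd = FALSE)))
  rec <- run_repeated_cv(rbind(tbl, can), tf$labels, cfg)
  r0 <- rec[rec$rotation_label == 0 & rec$fold_idx == 1, ]
  # with selection and training confined to the training rows, the canary
  # (noise there) cannot produce a perfect test score
  expect_lt(mean(r0$accuracy), 1)
})

test_that("performance_trend computes pooled Spearman rows", {
  # strictly decreasing metric per cycle -> CC = -1
  rec <- data.table::data.table(
    partition = "WD",
    classifier = rep(c("knn", "logistic"), each = 50),
    rotation_label = rep(seq(0, 80, 20), 20),
    accuracy = 1 - rep(seq(0, 80, 20), 20) / 100,
    macro_f1 = 0.5, macro_sensitivity = 0.5, macro_specificity = 0.5,
    repeat_idx = 1, fold_idx = 1)
  tr <- performance_trend(rec, metrics = "accuracy")
  expect_equal(nrow(tr), 3)  # All + 2 classifiers
  expect_equal(tr$cc[tr$classifier == "All"], -1, tolerance = 1e-9)
  expect_equal(tr$n[tr$classifier == "All"], 100)
  expect_equal(tr$stratum[tr$classifier == "knn"], "strong")
  # constant metric convention
  tr2 <- performance_trend(rec, metrics = "macro_f1")
  expect_equal(tr2$cc, rep(0, 3))
  expect_equal(tr2$p, rep(1, 3))
})
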
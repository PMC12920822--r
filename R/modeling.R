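# Performance-level analysis: wavelet-only vs non-wavelet-only 3-class
# models, trained on the unrotated (R0) features of the training folds of a
# repeated stratified 5-fold CV and tested on the R0..R80 features of the
# held-out fold; metric trends against rotation are summarized by pooled
# Spearman statistics.

#' Modeling pipeline configuration
#'
#' @param n_repeats CV repetitions (protocol default 50).
#' @param n_folds folds per repetition (default 5).
#' @param classifiers subset of `c("knn", "logistic", "random_forest",
#'   "svm_linear", "svm_rbf")`.
#' @param partitions feature partitions to run (`"WD"`, `"nWD"`).
#' @param max_features cap on finely selected features (default 30).
#' @param top_k_prefilter Kruskal-Wallis pre-ranking kept before the L1
#'   selection (default 60).
#' @param corr_threshold preliminary redundancy cut: one of each feature
#'   pair with |Spearman rho| above this is dropped, keep-first (default
#'   0.95).
#' @param include_shape_in_nwd assign the filter-independent shape features
#'   to the non-WD partition (default TRUE).
#' @param seed pipeline seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_repeats = 50L, n_folds = 5L,
                            classifiers = c("knn", "logistic",
                                            "random_forest", "svm_linear",
                                            "svm_rbf"),
                            partitions = c("WD", "nWD"),
                            max_features = 30L, top_k_prefilter = 60L,
                            corr_threshold = 0.95,
                            include_shape_in_nwd = TRUE, seed = 1L) {
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds), classifiers = classifiers,
                 partitions = match.arg(partitions, several.ok = TRUE),
                 max_features = as.integer(max_features),
                 top_k_prefilter = as.integer(top_k_prefilter),
                 corr_threshold = corr_threshold,
                 include_shape_in_nwd = isTRUE(include_shape_in_nwd),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Cast a long feature table to a patients x features matrix
#'
#' @param feature_table long table (patient_id, rotation, channel, category,
#'   feature, value, is_wd).
#' @param rotation_label which rotation set to extract.
#' @param partition `"WD"` (wavelet channels only), `"nWD"` (everything
#'   else), or `"all"`.
#' @param include_shape keep shape features (only meaningful for nWD/all).
#' @return numeric matrix with patient ids as row names and
#'   `channel|category|feature` keys as column names (stable order).
#' @export
feature_wide <- function(feature_table, rotation_label = 0,
                         partition = c("all", "WD", "nWD"),
                         include_shape = TRUE) {
  partition <- match.arg(partition)
  ft <- data.table::as.data.table(feature_table)
  ft <- ft[ft$rotation == rotation_label]
  if (partition == "WD") ft <- ft[ft$is_wd == TRUE]
  if (partition == "nWD") ft <- ft[ft$is_wd == FALSE]
  if (!include_shape || partition == "WD") ft <- ft[ft$category != "shape"]
  key <- paste(ft$channel, ft$category, ft$feature, sep = "|")
  ft$key <- factor(key, levels = unique(key))
  w <- data.table::dcast(ft, patient_id ~ key, value.var = "value")
  m <- as.matrix(w[, -1])
  rownames(m) <- w$patient_id
  m
}

#' Preliminary feature filtering (phase i)
#'
#' Performed on all samples of the unrotated table, label-free: drops
#' zero-variance columns, then one of each pair with |Spearman rho| above
#' the threshold (keep-first under the stable column ordering).
#'
#' @param X patients x features matrix.
#' @param corr_threshold redundancy cutoff (default 0.95).
#' @return matrix restricted to the surviving columns.
#' @export
prelim_filter <- function(X, corr_threshold = 0.95) {
  v <- apply(X, 2, var)
  X <- X[, v > 1e-12, drop = FALSE]
  if (ncol(X) == 0) stop("no features survive the variance filter")
  rho <- suppressWarnings(cor(X, method = "spearman"))
  rho[is.na(rho)] <- 0
  keep <- rep(TRUE, ncol(X))
  for (j in seq_len(ncol(X))[-1]) {
    if (any(abs(rho[j, seq_len(j - 1)][keep[seq_len(j - 1)]]) > corr_threshold))
      keep[j] <- FALSE
  }
  X[, keep, drop = FALSE]
}

# vectorized Kruskal-Wallis H statistic per column (tie-corrected)
.kw_stat <- function(X, y) {
  n <- nrow(X)
  grp <- split(seq_len(n), y)
  apply(X, 2, function(x) {
    r <- rank(x)
    H <- 12 / (n * (n + 1)) *
      sum(vapply(grp, function(g) sum(r[g])^2 / length(g), numeric(1))) -
      3 * (n + 1)
    ties <- table(x)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (corr > 0) H / corr else 0
  })
}

#' Fine feature selection (phase ii, per training fold)
#'
#' Standardizes on the training fold, ranks features by the Kruskal-Wallis
#' statistic across the classes, keeps the top `top_k`, then shrinks to at
#' most `max_features` via an L1-penalized multinomial path (smallest lambda
#' whose active set fits the cap). Never sees test rows.
#'
#' @param train_X training matrix, `train_y` integer labels 1..3.
#' @param train_y integer class labels.
#' @param max_features selection cap (default 30).
#' @param top_k Kruskal-Wallis shortlist size (default 60).
#' @return character vector of selected column names.
#' @export
fine_select <- function(train_X, train_y, max_features = 30L, top_k = 60L) {
  if (length(unique(train_y)) < 2) stop("training fold has a single class")
  mu <- colMeans(train_X)
  sdv <- apply(train_X, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(train_X, 2, mu), 2, sdv, "/")
  H <- .kw_stat(Z, train_y)
  short <- names(sort(H, decreasing = TRUE))[seq_len(min(top_k, ncol(Z)))]
  Zs <- Z[, short, drop = FALSE]
  sel <- tryCatch({
    fitp <- suppressWarnings(
      glmnet::glmnet(Zs, factor(train_y), family = "multinomial",
                     alpha = 1, nlambda = 50))
    nz <- sapply(seq_along(fitp$lambda), function(i) {
      cf <- coef(fitp, s = fitp$lambda[i])
      length(unique(unlist(lapply(cf, function(m) rownames(m)[m[, 1] != 0][-1]))))
    })
    ok <- which(nz <= max_features & nz > 0)
    if (length(ok) == 0) character(0) else {
      i <- max(ok)
      cf <- coef(fitp, s = fitp$lambda[i])
      setdiff(unique(unlist(lapply(cf, function(m) rownames(m)[m[, 1] != 0]))),
              "(Intercept)")
    }
  }, error = function(e) character(0))
  if (length(sel) == 0)
    sel <- short[seq_len(min(max_features, length(short)))]
  sel
}

#' Train the classifier bundle on a training fold
#'
#' Standardization parameters are fitted on the training rows and stored for
#' reuse at test time.
#'
#' @param train_X selected-feature training matrix.
#' @param train_y integer labels 1..3.
#' @param classifiers classifier kinds.
#' @param seed integer seed.
#' @return list of `radrot_model` objects plus the scaler.
#' @export
train_classifiers <- function(train_X, train_y,
                              classifiers = c("knn", "logistic"),
                              seed = 1L) {
  mu <- colMeans(train_X)
  sdv <- apply(train_X, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(train_X, 2, mu), 2, sdv, "/")
  models <- lapply(classifiers, function(k)
    fit_classifier(k, Z, train_y, seed = derive_seed(seed, k)))
  names(models) <- classifiers
  list(models = models, center = mu, scale = sdv,
       features = colnames(train_X))
}

#' Evaluate a trained bundle on every rotation set
#'
#' Uses the training-fold feature subset and scaler; a patient missing from
#' a rotation label is dropped from that label's evaluation.
#'
#' @param bundle output of [train_classifiers()].
#' @param wide_by_label named list `R<label>` -> patients x features matrix
#'   (full feature set; columns are subset here).
#' @param test_ids patient ids of the held-out fold.
#' @param truth named integer vector of labels (1..3) for all patients.
#' @return `data.table` with one row per classifier x rotation label.
#' @export
evaluate_rotated <- function(bundle, wide_by_label, test_ids, truth) {
  rows <- list()
  for (key in names(wide_by_label)) {
    lab <- as.integer(sub("^R", "", key))
    W <- wide_by_label[[key]]
    ids <- intersect(test_ids, rownames(W))
    if (length(ids) == 0) next
    X <- W[ids, bundle$features, drop = FALSE]
    Z <- sweep(sweep(X, 2, bundle$center), 2, bundle$scale, "/")
    for (cname in names(bundle$models)) {
      pred <- predict_classifier(bundle$models[[cname]], Z)
      met <- macro_metrics(truth[ids], pred, classes = 1:3)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        classifier = cname, rotation_label = lab,
        accuracy = met[["accuracy"]], macro_f1 = met[["macro_f1"]],
        macro_sensitivity = met[["macro_sensitivity"]],
        macro_specificity = met[["macro_specificity"]],
        n_test = length(ids),
        n_selected_features = length(bundle$features))
    }
  }
  data.table::rbindlist(rows)
}

# stratified fold assignment: shuffle within class, deal round-robin
.stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Repeated stratified k-fold CV, trained on R0, tested on R0..R80
#'
#' Phase (i) preliminary filtering uses all samples of the R0 table
#' (label-free); phases (ii)-(iii) (fine selection, model fitting,
#' standardization) are refit inside every training fold, so no test
#' information leaks. Produces `n_repeats * n_folds` train-test cycles per
#' classifier and partition.
#'
#' @param feature_table long table over all rotation labels (from
#'   [extract_cohort_features()]).
#' @param labels named integer class labels (0..2) per patient id.
#' @param config a [pipeline_config()].
#' @return `data.table` of CV records: one row per
#'   (partition x repeat x fold x classifier x rotation label).
#' @export
run_repeated_cv <- function(feature_table, labels, config = pipeline_config()) {
  ft <- data.table::as.data.table(feature_table)
  rot_labels <- sort(unique(ft$rotation))
  truth <- stats::setNames(as.integer(labels) + 1L, names(labels))
  all_rows <- list()
  for (part in config$partitions) {
    wide_by_label <- stats::setNames(lapply(rot_labels, function(l)
      feature_wide(ft, l, partition = part,
                   include_shape = config$include_shape_in_nwd)),
      paste0("R", rot_labels))
    W0 <- prelim_filter(wide_by_label$R0, config$corr_threshold)
    pats <- rownames(W0)
    y <- truth[pats]
    for (r in seq_len(config$n_repeats)) {
      folds <- .stratified_folds(y, config$n_folds,
                                 derive_seed(config$seed,
                                             paste0(part, "-rep", r)))
      for (f in seq_len(config$n_folds)) {
        train_ids <- pats[folds != f]
        test_ids <- pats[folds == f]
        sel <- fine_select(W0[train_ids, , drop = FALSE], y[train_ids],
                           config$max_features, config$top_k_prefilter)
        bundle <- train_classifiers(
          W0[train_ids, sel, drop = FALSE], y[train_ids],
          classifiers = config$classifiers,
          seed = derive_seed(config$seed, paste0(part, "-rep", r, "-f", f)))
        rec <- evaluate_rotated(bundle, wide_by_label, test_ids, truth)
        rec$partition <- part
        rec$repeat_idx <- r
        rec$fold_idx <- f
        all_rows[[length(all_rows) + 1L]] <- rec
      }
    }
  }
  data.table::rbindlist(all_rows)
}

# Fisher-z confidence interval for a correlation
.fisher_ci <- function(r, n, conf = 0.95) {
  if (n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Spearman trends of performance metrics against rotation
#'
#' Pools per-(cycle, rotation-label) metric points; reports one row per
#' classifier plus a pooled `All` row, per partition and metric, with
#' Fisher-z confidence intervals and effect-size strata.
#'
#' @param records output of [run_repeated_cv()].
#' @param metrics metric columns to summarize.
#' @return `data.table`: partition, classifier, metric, cc, ci_lo, ci_hi,
#'   p, n, stratum.
#' @export
performance_trend <- function(records,
                              metrics = c("accuracy", "macro_f1",
                                          "macro_sensitivity",
                                          "macro_specificity")) {
  r <- data.table::as.data.table(records)
  out <- list()
  trend_row <- function(sub, part, cname, met) {
    x <- sub$rotation_label
    yv <- sub[[met]]
    if (length(unique(yv)) == 1L || length(unique(x)) < 3) {
      return(data.table::data.table(partition = part, classifier = cname,
                                    metric = met, cc = 0, ci_lo = NA_real_,
                                    ci_hi = NA_real_, p = 1, n = length(yv),
                                    stratum = "trivial"))
    }
    ct <- suppressWarnings(cor.test(x, yv, method = "spearman", exact = FALSE))
    ci <- .fisher_ci(unname(ct$estimate), length(yv))
    data.table::data.table(partition = part, classifier = cname, metric = met,
                           cc = unname(ct$estimate), ci_lo = ci[1],
                           ci_hi = ci[2], p = ct$p.value, n = length(yv),
                           stratum = effect_stratum(unname(ct$estimate)))
  }
  for (part in unique(r$partition)) {
    rp <- r[r$partition == part]
    for (met in metrics) {
      out[[length(out) + 1L]] <- trend_row(rp, part, "All", met)
      for (cname in unique(rp$classifier))
        out[[length(out) + 1L]] <-
          trend_row(rp[rp$classifier == cname], part, cname, met)
    }
  }
  data.table::rbindlist(out)
}
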
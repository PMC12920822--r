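# The five classifier backends for the model-stability protocol.
#
# KNN uses FNN, multinomial logistic uses glmnet (ridge at a fixed small
# lambda). No random-forest or SVM implementation is available in the
# dependency set, so compact versions are implemented here: a
# random-subspace bagged CART forest and one-vs-rest SVMs solved by dual
# coordinate descent on the kernel matrix. All are deterministic given the
# seed and sized for desk-scale cohorts (tens to hundreds of samples).

.gini_best_split <- function(x, y, n_classes) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cum <- matrix(0, n, n_classes)
  for (c in seq_len(n_classes)) cum[, c] <- cumsum(ys == c)
  tot <- cum[n, ]
  # candidate splits between distinct consecutive x values
  cand <- which(diff(xs) > 0)
  if (length(cand) == 0) return(NULL)
  nl <- cand
  nr <- n - nl
  gl <- 1 - rowSums((cum[cand, , drop = FALSE] / nl)^2)
  gr <- 1 - rowSums((sweep(-cum[cand, , drop = FALSE], 2, tot, "+") / nr)^2)
  imp <- (nl * gl + nr * gr) / n
  b <- which.min(imp)
  list(threshold = (xs[cand[b]] + xs[cand[b] + 1]) / 2, impurity = imp[b])
}

.grow_tree <- function(X, y, n_classes, mtry, depth, max_depth, min_n) {
  counts <- tabulate(y, n_classes)
  node <- list(pred = which.max(counts))
  if (depth >= max_depth || length(y) < min_n || length(unique(y)) == 1L)
    return(node)
  feats <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL
  for (f in feats) {
    sp <- .gini_best_split(X[, f], y, n_classes)
    if (!is.null(sp) && (is.null(best) || sp$impurity < best$impurity)) {
      best <- sp; best$feature <- f
    }
  }
  if (is.null(best)) return(node)
  left <- X[, best$feature] <= best$threshold
  node$feature <- best$feature
  node$threshold <- best$threshold
  node$left <- .grow_tree(X[left, , drop = FALSE], y[left], n_classes, mtry,
                          depth + 1, max_depth, min_n)
  node$right <- .grow_tree(X[!left, , drop = FALSE], y[!left], n_classes,
                           mtry, depth + 1, max_depth, min_n)
  node
}

.tree_predict <- function(node, X) {
  n <- nrow(X)
  out <- integer(n)
  rec <- function(node, idx) {
    if (is.null(node$feature)) { out[idx] <<- node$pred; return(invisible()) }
    left <- X[idx, node$feature] <= node$threshold
    if (any(left)) rec(node$left, idx[left])
    if (any(!left)) rec(node$right, idx[!left])
  }
  rec(node, seq_len(n))
  out
}

.fit_rf <- function(X, y, n_classes, n_trees = 200L, seed = 1L) {
  mtry <- max(1L, floor(sqrt(ncol(X))))
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(nrow(X), replace = TRUE)
      .grow_tree(X[idx, , drop = FALSE], y[idx], n_classes, mtry,
                 depth = 0L, max_depth = 12L, min_n = 2L)
    })
    list(trees = trees, n_classes = n_classes)
  })
}

.predict_rf <- function(model, X) {
  votes <- matrix(0L, nrow(X), model$n_classes)
  for (tr in model$trees) {
    p <- .tree_predict(tr, X)
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1L
  }
  max.col(votes, ties.method = "first")
}

# one-vs-rest soft-margin SVM via dual coordinate descent on the kernel
# matrix (Hsieh et al. style); returns alpha*t and bias per class
.fit_svm <- function(X, y, n_classes, kernel = c("linear", "rbf"), C = 1,
                     max_epochs = 200L) {
  kernel <- match.arg(kernel)
  n <- nrow(X)
  gamma <- if (kernel == "rbf") {
    v <- mean(apply(X, 2, var))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else NA_real_
  K <- if (kernel == "linear") tcrossprod(X) else {
    d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
    exp(-gamma * pmax(d2, 0))
  }
  diagK <- pmax(diag(K), 1e-12)
  models <- lapply(seq_len(n_classes), function(cl) {
    t <- ifelse(y == cl, 1, -1)
    alpha <- numeric(n)
    g <- numeric(n)            # g_i = sum_j alpha_j t_j K_ij
    for (ep in seq_len(max_epochs)) {
      moved <- 0
      for (i in seq_len(n)) {
        G <- t[i] * g[i] - 1
        a_old <- alpha[i]
        a_new <- min(max(a_old - G / diagK[i], 0), C)
        if (abs(a_new - a_old) > 1e-12) {
          g <- g + (a_new - a_old) * t[i] * K[, i]
          alpha[i] <- a_new
          moved <- moved + abs(a_new - a_old)
        }
      }
      if (moved < 1e-8) break
    }
    free <- alpha > 1e-8 & alpha < C - 1e-8
    b <- if (any(free)) mean(t[free] - g[free]) else {
      sv <- alpha > 1e-8
      if (any(sv)) mean(t[sv] - g[sv]) else 0
    }
    list(coef = alpha * t, b = b)
  })
  list(models = models, X = X, kernel = kernel, gamma = gamma,
       n_classes = n_classes)
}

.predict_svm <- function(model, X) {
  K <- if (model$kernel == "linear") tcrossprod(X, model$X) else {
    d2 <- outer(rowSums(X^2), rowSums(model$X^2), "+") -
      2 * tcrossprod(X, model$X)
    exp(-model$gamma * pmax(d2, 0))
  }
  dec <- sapply(model$models, function(m) K %*% m$coef + m$b)
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  max.col(dec, ties.method = "first")
}

#' Fit one classifier
#'
#' Hyperparameters are fixed and documented: KNN k = 5; logistic =
#' glmnet multinomial ridge at lambda 0.01; random forest = 200
#' random-subspace bagged CART trees (mtry = sqrt(p), depth <= 12); SVMs
#' C = 1, RBF gamma = 1/(p * mean feature variance).
#'
#' @param kind one of `"knn"`, `"logistic"`, `"random_forest"`,
#'   `"svm_linear"`, `"svm_rbf"`.
#' @param X numeric matrix (standardized by the caller).
#' @param y integer class labels 1..n_classes.
#' @param n_classes number of classes (default 3).
#' @param seed integer seed (used by the forest bootstrap).
#' @return a `radrot_model`.
#' @export
fit_classifier <- function(kind, X, y, n_classes = 3L, seed = 1L) {
  kind <- match.arg(kind, c("knn", "logistic", "random_forest",
                            "svm_linear", "svm_rbf"))
  if (length(unique(y)) < 2) stop("training fold has a single class")
  fit <- switch(kind,
    knn = list(X = X, y = y, k = 5L, seed = seed),
    logistic = {
      Xg <- if (ncol(X) < 2) cbind(X, 0) else X
      suppressWarnings(
        glmnet::glmnet(Xg, factor(y, levels = seq_len(n_classes)),
                       family = "multinomial", alpha = 0, lambda = 0.01))
    },
    random_forest = .fit_rf(X, y, n_classes, seed = seed),
    svm_linear = .fit_svm(X, y, n_classes, "linear"),
    svm_rbf = .fit_svm(X, y, n_classes, "rbf"))
  structure(list(kind = kind, fit = fit, n_classes = n_classes),
            class = "radrot_model")
}

#' Predict classes from a fitted classifier
#'
#' @param model a `radrot_model`.
#' @param X feature matrix on the training standardization.
#' @return integer class labels 1..n_classes.
#' @export
predict_classifier <- function(model, X) {
  switch(model$kind,
    knn = {
      k <- min(model$fit$k, nrow(model$fit$X))
      # FNN breaks distance/vote ties through the RNG; pin it for
      # reproducible predictions
      with_seed(model$fit$seed,
                as.integer(as.character(FNN::knn(model$fit$X, X,
                                                 factor(model$fit$y),
                                                 k = k))))
    },
    logistic = {
      Xg <- if (ncol(X) < 2) cbind(X, 0) else X
      as.integer(as.character(predict(model$fit, Xg, type = "class")))
    },
    random_forest = .predict_rf(model$fit, X),
    svm_linear = ,
    svm_rbf = .predict_svm(model$fit, X))
}

#' One-vs-rest macro classification metrics
#'
#' Accuracy plus macro-averaged F1, sensitivity and specificity over the
#' classes present in the truth (absent classes are skipped in the macro
#' averages; an undefined per-class F1 on an empty prediction counts as 0).
#'
#' @param truth,pred integer class labels.
#' @param classes the full class set.
#' @return named numeric vector: accuracy, macro_f1, macro_sensitivity,
#'   macro_specificity.
#' @export
macro_metrics <- function(truth, pred, classes = sort(unique(truth))) {
  acc <- mean(truth == pred)
  f1 <- sens <- spec <- numeric(0)
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    if (tp + fn == 0) next  # class absent from truth
    sens <- c(sens, tp / (tp + fn))
    spec <- c(spec, if (tn + fp > 0) tn / (tn + fp) else 1)
    f1 <- c(f1, if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
  }
  c(accuracy = acc, macro_f1 = mean(f1), macro_sensitivity = mean(sens),
    macro_specificity = mean(spec))
}
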
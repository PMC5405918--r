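# SBE/NSBE fragment classification: feature selection, classifier backends
# (SVM via e1071, random forest via randomForest, kNN in-package to support
# the full set of distance metrics), and nested cross-validation.

#' Classifier specification
#'
#' @param family `"svm"`, `"knn"` or `"rf"`.
#' @param grid data.frame of hyper-parameter combinations to search in the
#'   inner loop; `NULL` uses a compact default grid, see
#'   [default_grid()] / [paper_grid()].
#' @param selection feature-selection strategy: `"null"` (all features),
#'   `"infogain"` or `"sfs"` (sequential forward).
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "knn", "rf"), grid = NULL,
                            selection = c("null", "infogain", "sfs")) {
  family <- match.arg(family)
  selection <- match.arg(selection)
  if (is.null(grid)) grid <- default_grid(family)
  structure(list(family = family, grid = grid, selection = selection),
            class = "classifier_spec")
}

#' Compact default hyper-parameter grids
#'
#' @param family classifier family.
#' @return data.frame of parameter combinations.
#' @export
default_grid <- function(family) {
  switch(family,
    svm = expand.grid(kernel = "radial", C = 4^(-1:3), gamma = 4^(-2:2),
                      stringsAsFactors = FALSE),
    knn = expand.grid(k = 2^(0:5), metric = c("euclidean", "cityblock"),
                      stringsAsFactors = FALSE),
    rf = expand.grid(ntree = c(64, 256), mtry = c(2, 4), minleaf = c(1, 4)))
}

#' Full published search grids
#'
#' The complete grids used in the reference experiments: kNN neighbours
#' `2^0..2^10` with eight distance metrics; random forests with
#' `2^0..2^10` trees, all attribute counts and leaf sizes `2^0..2^4`; SVM
#' kernels linear/polynomial/RBF/sigmoid with `C, gamma` in `2^-4..2^8`,
#' offset `c` in `{0, 0.1}` and polynomial order 2..5.  These grids are
#' large; use them deliberately.
#'
#' @param family classifier family.
#' @param n_features number of features (for the RF `mtry` axis).
#' @return data.frame of parameter combinations.
#' @export
paper_grid <- function(family, n_features = 18) {
  switch(family,
    knn = expand.grid(k = 2^(0:10),
                      metric = c("cosine", "chebychev", "cityblock",
                                 "correlation", "euclidean", "hamming",
                                 "minkowski", "seuclidean"),
                      stringsAsFactors = FALSE),
    rf = expand.grid(ntree = 2^(0:10), mtry = seq_len(n_features),
                     minleaf = 2^(0:4)),
    svm = rbind(
      expand.grid(kernel = "linear", C = 2^(-4:8), gamma = NA, coef0 = NA,
                  degree = NA, stringsAsFactors = FALSE),
      expand.grid(kernel = "polynomial", C = 2^(-4:8), gamma = 2^(-4:8),
                  coef0 = c(0, 0.1), degree = 2:5, stringsAsFactors = FALSE),
      expand.grid(kernel = "radial", C = 2^(-4:8), gamma = 2^(-4:8),
                  coef0 = NA, degree = NA, stringsAsFactors = FALSE),
      expand.grid(kernel = "sigmoid", C = 2^(-4:8), gamma = 2^(-4:8),
                  coef0 = c(0, 0.1), degree = NA, stringsAsFactors = FALSE)))
}

# ---- internal fit/predict ------------------------------------------------

# median-impute NA cells using training-column medians
.impute <- function(X, med = NULL) {
  X <- as.matrix(X)
  if (is.null(med)) med <- apply(X, 2, function(c) median(c, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- med[j]
  list(X = X, med = med)
}

.dist_matrix <- function(A, B, metric, p = 3, scale = NULL) {
  switch(metric,
    euclidean = sqrt(outer(rowSums(A^2), rowSums(B^2), "+") -
                       2 * A %*% t(B)),
    seuclidean = {
      s <- scale; s[s == 0] <- 1
      As <- sweep(A, 2, s, "/"); Bs <- sweep(B, 2, s, "/")
      sqrt(pmax(outer(rowSums(As^2), rowSums(Bs^2), "+") -
                  2 * As %*% t(Bs), 0))
    },
    cityblock = {
      m <- matrix(0, nrow(A), nrow(B))
      for (j in seq_len(ncol(A))) m <- m + abs(outer(A[, j], B[, j], "-"))
      m
    },
    chebychev = {
      m <- matrix(0, nrow(A), nrow(B))
      for (j in seq_len(ncol(A))) m <- pmax(m, abs(outer(A[, j], B[, j], "-")))
      m
    },
    minkowski = {
      m <- matrix(0, nrow(A), nrow(B))
      for (j in seq_len(ncol(A))) m <- m + abs(outer(A[, j], B[, j], "-"))^p
      m^(1 / p)
    },
    cosine = {
      na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
      na[na == 0] <- 1; nb[nb == 0] <- 1
      1 - (A %*% t(B)) / outer(na, nb)
    },
    correlation = {
      Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
      na <- sqrt(rowSums(Ac^2)); nb <- sqrt(rowSums(Bc^2))
      na[na == 0] <- 1; nb[nb == 0] <- 1
      1 - (Ac %*% t(Bc)) / outer(na, nb)
    },
    hamming = {
      m <- matrix(0, nrow(A), nrow(B))
      for (j in seq_len(ncol(A))) m <- m + (outer(A[, j], B[, j], "!=") * 1)
      m / ncol(A)
    },
    stop("unknown metric: ", metric))
}

.fit_model <- function(X, y, family, par) {
  y <- factor(y)
  switch(family,
    svm = {
      args <- list(x = X, y = y, kernel = as.character(par$kernel),
                   cost = par$C, scale = apply(X, 2, sd) > 0)
      if (!is.null(par$gamma) && is.finite(par$gamma)) args$gamma <- par$gamma
      if (!is.null(par$coef0) && is.finite(par$coef0)) args$coef0 <- par$coef0
      if (!is.null(par$degree) && is.finite(par$degree))
        args$degree <- par$degree
      do.call(e1071::svm, args)
    },
    rf = randomForest::randomForest(
      x = X, y = y, ntree = par$ntree,
      mtry = max(1, min(par$mtry, ncol(X))), nodesize = par$minleaf),
    knn = list(X = X, y = y, k = par$k, metric = as.character(par$metric),
               scale = apply(X, 2, sd)))
}

.predict_model <- function(model, X, family) {
  switch(family,
    svm = predict(model, X),
    rf = predict(model, X),
    knn = {
      D <- .dist_matrix(X, model$X, model$metric, scale = model$scale)
      k <- min(model$k, nrow(model$X))
      lev <- levels(model$y)
      apply(D, 1, function(d) {
        nb <- model$y[order(d)[seq_len(k)]]
        lev[which.max(tabulate(nb, nbins = length(lev)))]
      })
    })
}

.stratified_folds <- function(y, k) {
  y <- factor(y)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    ii <- sample(which(y == lv))
    fold[ii] <- rep_len(seq_len(k), length(ii))
  }
  fold
}

.cv_error <- function(X, y, family, par, k = 5) {
  fold <- .stratified_folds(y, k)
  err <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    imp <- .impute(X[tr, , drop = FALSE])
    te <- .impute(X[!tr, , drop = FALSE], imp$med)
    mod <- .fit_model(imp$X, y[tr], family, par)
    pred <- .predict_model(mod, te$X, family)
    err <- err + sum(pred != y[!tr])
  }
  err / length(y)
}

# ---- feature selection ---------------------------------------------------

.entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.info_gain <- function(f, y, bins) {
  br <- unique(quantile(f, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE))
  if (length(br) < 2) return(0)
  b <- cut(f, breaks = br, include.lowest = TRUE)
  h <- 0
  for (lv in levels(b)) {
    sel <- which(b == lv)
    if (length(sel)) h <- h + length(sel) / length(y) * .entropy(y[sel])
  }
  .entropy(y) - h
}

#' Information-gain feature selection
#'
#' Discretises each feature into up to `bins` equal-frequency bins and
#' computes the information gain about the (binary) labels.  Because the
#' raw gain of a continuous feature is biased upward in finite samples, a
#' feature is kept only when its gain exceeds the `1 - alpha` quantile of
#' its permutation-null gains -- the bias-corrected version of the "keep
#' gains larger than zero" rule.  Constant features have zero gain and are
#' dropped.
#'
#' @param X feature matrix (data.frame or matrix).
#' @param y binary labels.
#' @param bins number of equal-frequency bins (default 10).
#' @param n_perm label permutations for the null (default 100).
#' @param alpha permutation-test level (default 0.05).
#' @return Integer indices of the retained features, with the observed
#'   gains as attribute `"gain"`.
#' @export
info_gain_select <- function(X, y, bins = 10, n_perm = 100, alpha = 0.05) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("labels are single-class", call. = FALSE)
  X <- as.matrix(X)
  gains <- numeric(ncol(X))
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    f <- X[, j]
    ok <- is.finite(f)
    if (sum(ok) < 4 || length(unique(f[ok])) < 2) next
    g <- .info_gain(f[ok], y[ok], bins)
    null <- vapply(seq_len(n_perm), function(i)
      .info_gain(f[ok], sample(y[ok]), bins), numeric(1))
    gains[j] <- g
    keep[j] <- g > max(0, quantile(null, 1 - alpha))
  }
  out <- which(keep)
  attr(out, "gain") <- gains
  out
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: starting from the empty set, repeatedly add
#' the feature whose inclusion most decreases the inner cross-validated
#' misclassification rate of the specified classifier (at its first grid
#' row); stop when no addition strictly decreases the error.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param spec a [classifier_spec()].
#' @param k inner folds (default 5).
#' @param seed RNG seed for the folds.
#' @return Integer indices of the selected features, in selection order.
#' @export
sequential_forward_select <- function(X, y, spec = classifier_spec("svm"),
                                      k = 5, seed = 1L) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("labels are single-class", call. = FALSE)
  X <- as.matrix(X)
  if (ncol(X) == 0) return(integer(0))
  set.seed(seed)
  par <- spec$grid[1, , drop = FALSE]
  chosen <- integer(0)
  best_err <- Inf
  repeat {
    cand <- setdiff(seq_len(ncol(X)), chosen)
    if (!length(cand)) break
    errs <- vapply(cand, function(j) {
      .cv_error(X[, c(chosen, j), drop = FALSE], y, spec$family, par, k)
    }, numeric(1))
    if (min(errs) < best_err) {
      best_err <- min(errs)
      chosen <- c(chosen, cand[which.min(errs)])
    } else break
  }
  chosen
}

#' Nested cross-validated training of an SBE/NSBE classifier
#'
#' Outer stratified `outer_k`-fold cross-validation reports unbiased
#' accuracy/precision/recall; within each outer training set, feature
#' selection (per the spec) and an inner `inner_k`-fold grid search choose
#' the features and hyper-parameters, so no model is ever evaluated on
#' samples that influenced its configuration.  The final model is refit on
#' all data with the most frequently chosen configuration.
#'
#' @param X feature matrix (rows = fragments, columns = features).
#' @param y binary labels (`"SBE"` / `"NSBE"` or any two-level factor; the
#'   first level sorted last alphabetically is treated as positive unless
#'   `positive` is given).
#' @param spec a [classifier_spec()].
#' @param outer_k,inner_k fold counts (defaults 10 and 5); reduced with a
#'   warning if a class is too small.
#' @param seed RNG seed; fixes fold assignment and all stochastic fits.
#' @param positive label treated as positive for precision/recall
#'   (default `"SBE"` when present).
#' @return List of class `nested_cv_fit`: `model`, `family`, `features`
#'   (indices used by the final model), `impute` medians, `metrics`
#'   (accuracy/precision/recall, outer-fold means), `fold` assignment,
#'   `params` (final hyper-parameters).
#' @export
nested_cv_train <- function(X, y, spec = classifier_spec("svm"),
                            outer_k = 10, inner_k = 5, seed = 1L,
                            positive = NULL) {
  y <- factor(y)
  X <- as.matrix(X)
  if (nlevels(y) < 2) stop("labels are single-class", call. = FALSE)
  n_min <- min(table(y))
  if (n_min < outer_k) {
    outer_k <- max(2, n_min)
    warning(sprintf("class too small for requested folds; outer_k = %d",
                    outer_k))
  }
  if (is.null(positive))
    positive <- if ("SBE" %in% levels(y)) "SBE" else levels(y)[1]
  set.seed(seed)
  fold <- .stratified_folds(y, outer_k)
  acc <- prec <- rec <- numeric(outer_k)
  configs <- list()
  for (f in seq_len(outer_k)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    feat <- switch(spec$selection,
      null = seq_len(ncol(X)),
      infogain = {
        s <- info_gain_select(Xtr, ytr)
        if (length(s)) s else seq_len(ncol(X))
      },
      sfs = {
        s <- sequential_forward_select(Xtr, ytr, spec, k = inner_k,
                                       seed = seed + f)
        if (length(s)) s else seq_len(ncol(X))
      })
    errs <- vapply(seq_len(nrow(spec$grid)), function(g) {
      .cv_error(Xtr[, feat, drop = FALSE], ytr, spec$family,
                spec$grid[g, , drop = FALSE], inner_k)
    }, numeric(1))
    g_best <- which.min(errs)
    imp <- .impute(Xtr[, feat, drop = FALSE])
    mod <- .fit_model(imp$X, ytr, spec$family, spec$grid[g_best, , drop = FALSE])
    te <- .impute(X[!tr, feat, drop = FALSE], imp$med)
    pred <- factor(.predict_model(mod, te$X, spec$family), levels = levels(y))
    truth <- y[!tr]
    acc[f] <- mean(pred == truth)
    tp <- sum(pred == positive & truth == positive)
    prec[f] <- if (sum(pred == positive) > 0) tp / sum(pred == positive) else NA
    rec[f] <- if (sum(truth == positive) > 0) tp / sum(truth == positive) else NA
    configs[[f]] <- list(feat = feat, g = g_best)
  }
  g_tab <- table(vapply(configs, `[[`, numeric(1), "g"))
  g_final <- as.integer(names(g_tab)[which.max(g_tab)])
  feat_final <- switch(spec$selection,
    null = seq_len(ncol(X)),
    infogain = {
      s <- info_gain_select(X, y)
      if (length(s)) s else seq_len(ncol(X))
    },
    sfs = {
      s <- sequential_forward_select(X, y, spec, k = inner_k, seed = seed)
      if (length(s)) s else seq_len(ncol(X))
    })
  imp <- .impute(X[, feat_final, drop = FALSE])
  model <- .fit_model(imp$X, y, spec$family,
                      spec$grid[g_final, , drop = FALSE])
  structure(list(model = model, family = spec$family,
                 features = feat_final, impute = imp$med,
                 metrics = c(accuracy = mean(acc),
                             precision = mean(prec, na.rm = TRUE),
                             recall = mean(rec, na.rm = TRUE)),
                 fold = fold, params = spec$grid[g_final, , drop = FALSE],
                 levels = levels(y), positive = positive),
            class = "nested_cv_fit")
}

#' Predict fragment labels with a fitted classifier
#'
#' @param object a [nested_cv_train()] fit.
#' @param newdata feature matrix with the same columns as the training
#'   matrix.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.nested_cv_fit <- function(object, newdata, ...) {
  Xi <- .impute(as.matrix(newdata)[, object$features, drop = FALSE],
                object$impute)
  factor(.predict_model(object$model, Xi$X, object$family),
         levels = object$levels)
}

#' @export
print.nested_cv_fit <- function(x, ...) {
  cat(sprintf("<nested_cv_fit> %s; outer accuracy %.3f precision %.3f recall %.3f\n",
              x$family, x$metrics["accuracy"], x$metrics["precision"],
              x$metrics["recall"]))
  invisible(x)
}
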
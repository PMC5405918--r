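make_two_class <- function(n = 60, p_noise = 5, sep = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("SBE", "NSBE"), each = n / 2)
  X <- matrix(rnorm(n * (p_noise + 1)), n)
  X[, 1] <- X[, 1] + ifelse(y == "SBE", sep, 0)
  colnames(X) <- paste0("f", seq_len(p_noise + 1))
  list(X = X, y = y)
}

test_that("information gain keeps informative features and drops noise", {
  d <- make_two_class(n = 80, seed = 2)
  # a feature identical to the label is always retained
  Xid <- cbind(d$X, label_copy = as.numeric(d$y == "SBE"))
  sel <- info_gain_select(Xid, d$y)
  expect_true(ncol(Xid) %in% sel)
  expect_true(1 %in% sel)  # the separated feature survives too

  # constant features are always dropped
  Xc <- cbind(d$X, const = 1)
  expect_false(ncol(Xc) %in% info_gain_select(Xc, d$y))

  # a permuted (label-independent) feature is dropped in >= 95% of seeds
  dropped <- vapply(1:60, function(s) {
    set.seed(s)
    Xp <- cbind(d$X[, 1, drop = FALSE], perm = rnorm(nrow(d$X)))
    !(2 %in% info_gain_select(Xp, d$y, n_perm = 60))
  }, logical(1))
  expect_gte(mean(dropped), 0.95)

  expect_error(info_gain_select(d$X, rep("SBE", nrow(d$X))), "single-class")
})

test_that("sequential forward selection finds the separating feature first", {
  d <- make_two_class(n = 60, sep = 4, seed = 3)
  sel <- sequential_forward_select(d$X, d$y, classifier_spec("svm"), seed = 4)
  expect_equal(sel[1], 1)

  # all-noise features: at most one accepted
  set.seed(5)
  Xn <- matrix(rnorm(60 * 4), 60)
  yn <- rep(c("SBE", "NSBE"), each = 30)
  expect_lte(length(sequential_forward_select(Xn, yn, seed = 6)), 1)

  expect_identical(
    sequential_forward_select(d$X[, 0, drop = FALSE], d$y),
    integer(0))
})

test_that("nested CV is honest, stratified and reproducible", {
  d <- make_two_class(n = 60, sep = 5, seed = 7)
  spec <- classifier_spec("svm",
                          grid = expand.grid(kernel = "radial", C = c(1, 10),
                                             gamma = c(0.1, 1),
                                             stringsAsFactors = FALSE))
  fit <- nested_cv_train(d$X, d$y, spec, seed = 8)
  expect_equal(unname(fit$metrics["accuracy"]), 1)

  # outer folds never share samples with their own training sets
  expect_length(fit$fold, nrow(d$X))
  expect_true(all(table(fit$fold) >= 4))

  # permuted labels: accuracy near the majority-class rate
  set.seed(9)
  yp <- sample(d$y)
  fitp <- nested_cv_train(d$X, yp, spec, seed = 10)
  expect_lt(abs(fitp$metrics["accuracy"] - 0.5), 0.18)

  # determinism: identical folds and metrics for the same seed
  fit2 <- nested_cv_train(d$X, d$y, spec, seed = 8)
  expect_identical(fit$fold, fit2$fold)
  expect_equal(fit$metrics, fit2$metrics)

  # small classes reduce the outer fold count with a warning
  ds <- make_two_class(n = 12, seed = 11)
  expect_warning(nested_cv_train(ds$X, ds$y, spec, seed = 12), "folds")
})

test_that("kNN backend handles all advertised distance metrics", {
  d <- make_two_class(n = 40, sep = 4, seed = 13)
  for (m in c("euclidean", "cityblock", "chebychev", "minkowski", "cosine",
              "correlation", "seuclidean", "hamming")) {
    spec <- classifier_spec("knn",
                            grid = data.frame(k = 3, metric = m,
                                              stringsAsFactors = FALSE))
    fit <- suppressWarnings(nested_cv_train(d$X, d$y, spec, outer_k = 4,
                                            inner_k = 3, seed = 14))
    expect_true(is.finite(fit$metrics["accuracy"]))
    if (m %in% c("euclidean", "cityblock", "minkowski", "seuclidean"))
      expect_gt(fit$metrics["accuracy"], 0.85)
  }
})

test_that("random-forest backend trains and predicts through the same API", {
  d <- make_two_class(n = 50, sep = 4, seed = 15)
  spec <- classifier_spec("rf", grid = data.frame(ntree = 64, mtry = 2,
                                                  minleaf = 1))
  fit <- nested_cv_train(d$X, d$y, spec, outer_k = 5, seed = 16)
  expect_gt(fit$metrics["accuracy"], 0.9)
  pred <- predict(fit, d$X)
  expect_gt(mean(pred == d$y), 0.9)
})
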
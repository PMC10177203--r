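# Fold-scoped scaling, Nystroem kernel approximation, and the four
# classifier families.

test_that("standard scaler uses population statistics from training rows only", {
  sc <- fit_scaler(matrix(c(1, 3), 2, 1))
  expect_equal(as.vector(apply_scaler(sc, matrix(c(1, 3), 2, 1))), c(-1, 1))

  Xc <- cbind(c(2, 2, 2), c(1, 2, 3))
  sc2 <- fit_scaler(Xc)
  out <- apply_scaler(sc2, Xc)
  expect_equal(out[, 1], rep(0, 3))            # constant column, no NaN

  # held-out rows keep training statistics (4 x 2 hand-worked example)
  Xtr <- cbind(c(0, 2, 4, 6), c(10, 20, 30, 40))
  sc3 <- fit_scaler(Xtr)
  m <- c(3, 25); s <- c(sqrt(mean((c(0, 2, 4, 6) - 3)^2)),
                        sqrt(mean((c(10, 20, 30, 40) - 25)^2)))
  Xte <- matrix(c(10, 50), 1, 2)
  expect_equal(as.vector(apply_scaler(sc3, Xte)), (c(10, 50) - m) / s)
  expect_false(isTRUE(all.equal(mean(apply_scaler(sc3, Xte)), 0)))

  expect_error(fit_scaler(matrix(1, 1, 2)), "at least 2 rows")
  expect_error(apply_scaler(sc3, matrix(1, 2, 3)), "dimension")
})

# Independent exact-kernel oracle: plain double loop over row pairs.
loop_kernel <- function(X, kernel, gamma) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- if (kernel == "rbf") exp(-gamma * sum((X[i, ] - X[j, ])^2))
    else (gamma * sum(X[i, ] * X[j, ]) + 1)^3
  }
  K
}

test_that("full-rank Nystroem reproduces the exact kernel Gram matrix", {
  set.seed(31)
  X <- matrix(rnorm(50 * 10), 50, 10)
  for (kern in c("rbf", "poly3")) {
    gamma <- if (kern == "rbf") 0.05 else 0.01
    map <- fit_nystroem(X, kern, gamma, n_components = 50L, seed = 4L)
    Phi <- apply_nystroem(map, X)
    K <- loop_kernel(X, kern, gamma)
    expect_lt(max(abs(Phi %*% t(Phi) - K)), 1e-6)
  }
})

test_that("Nystroem maps are seeded, clipped, and unit-norm for RBF self-similarity", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6)
  m1 <- fit_nystroem(X, "rbf", 0.1, 20L, seed = 7L)
  m2 <- fit_nystroem(X, "rbf", 0.1, 20L, seed = 7L)
  expect_identical(m1$landmark_idx, m2$landmark_idx)
  expect_identical(m1$B, m2$B)
  m3 <- fit_nystroem(X, "rbf", 0.1, 20L, seed = 8L)
  expect_false(identical(m1$landmark_idx, m3$landmark_idx))

  # K(x, x) = 1 for RBF, so mapped rows have (approximately) unit norm
  Phi <- apply_nystroem(fit_nystroem(X, "rbf", 0.1, 40L, seed = 1L), X)
  expect_equal(unname(rowSums(Phi^2)), rep(1, 40), tolerance = 1e-8)

  expect_warning(fit_nystroem(X, "rbf", 0.1, 60L, seed = 1L), "clipped")
  expect_error(fit_nystroem(X, "rbf", 0.1, 0L), "n_components")
})

test_that("Nystroem error shrinks as landmark count grows", {
  set.seed(11)
  X <- matrix(rnorm(100 * 8), 100, 8)
  K <- loop_kernel(X, "rbf", 0.05)
  errs <- vapply(c(10L, 25L, 50L, 100L), function(m) {
    Phi <- apply_nystroem(fit_nystroem(X, "rbf", 0.05, m, seed = 3L), X)
    max(abs(Phi %*% t(Phi) - K))
  }, numeric(1))
  for (i in seq_len(length(errs) - 1L)) expect_lte(errs[i + 1L], errs[i] + 1e-8)
  expect_lt(errs[length(errs)], 1e-6)
})

sep_toy <- function() {
  X <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)) * 2
  y <- c("benign", "benign", "malignant", "malignant")
  list(X = X, y = y)
}

test_that("SVM families separate a separable toy and are deterministic", {
  toy <- sep_toy()
  for (fam in c("linear_svm", "rbf_svm", "poly3_svm")) {
    cs <- classifier_spec(fam, seed = 2L)
    h <- list(C = 10, gamma = 0.5, n_components = 4L)
    m <- train_classifier(cs, h, toy$X, toy$y)
    pred <- predict(m, toy$X)
    expect_equal(as.character(pred$label), toy$y)
    expect_true(all(is.finite(pred$score)))
    m2 <- train_classifier(cs, h, toy$X, toy$y)
    probe <- matrix(seq(-3, 3, length.out = 10), 5, 2)
    expect_identical(predict(m, probe), predict(m2, probe))
  }
  expect_error(train_classifier(classifier_spec("linear_svm"), list(C = 1),
                                toy$X, rep("benign", 4)), "single class")
})

test_that("decision scores are mirror-antisymmetric on a symmetric toy", {
  toy <- sep_toy()
  m <- train_classifier(classifier_spec("linear_svm"), list(C = 10),
                        toy$X, toy$y)
  p <- predict(m, rbind(c(2, 0), c(-2, 0)))
  expect_equal(p$score[1], -p$score[2], tolerance = 1e-8)
  expect_gt(p$score[1], 0)   # positive side is malignant
})

test_that("batch prediction equals row-by-row prediction", {
  toy <- sep_toy()
  for (fam in c("linear_svm", "sgb")) {
    h <- if (fam == "sgb") {
      list(learning_rate = 0.2, n_trees = 20L, tree_depth = 2L,
           subsample_fraction = 1.0)
    } else list(C = 1)
    m <- train_classifier(classifier_spec(fam, seed = 3L), h, toy$X, toy$y)
    set.seed(17); probe <- matrix(rnorm(20), 10, 2)
    batch <- predict(m, probe)
    rows <- do.call(rbind, lapply(seq_len(10), function(i) {
      predict(m, probe[i, , drop = FALSE])
    }))
    expect_equal(batch$score, rows$score, tolerance = 1e-7)
    expect_equal(batch$label, rows$label)
  }
  m <- train_classifier(classifier_spec("linear_svm"), list(C = 1), toy$X, toy$y)
  expect_error(predict(m, matrix(0, 2, 5)), "dimension")
})

test_that("a single-stump boosting fit reproduces the exhaustive best stump", {
  set.seed(23)
  x <- sort(runif(40, -1, 1))
  y <- ifelse(x > 0.2, "malignant", "benign")
  X <- cbind(x)
  h <- list(learning_rate = 0.5, n_trees = 1L, tree_depth = 1L,
            subsample_fraction = 1.0)
  m <- train_classifier(classifier_spec("sgb", seed = 5L), h, X, y)
  pred <- as.character(predict(m, X)$label)

  # oracle: exhaustive search over all threshold stumps on the raw feature
  cuts <- (x[-1] + x[-length(x)]) / 2
  best <- -Inf; best_pred <- NULL
  for (cc in cuts) for (dir in c(1, -1)) {
    p <- ifelse(dir * (x - cc) > 0, "malignant", "benign")
    if (mean(p == y) > best) { best <- mean(p == y); best_pred <- p }
  }
  expect_equal(best, 1)          # toy is stump-separable
  expect_equal(pred, best_pred)
})

test_that("boosting training loss is non-increasing in the iteration count", {
  set.seed(29)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.5) > 0, "malignant", "benign")
  logloss <- vapply(c(5L, 20L, 80L), function(tr) {
    h <- list(learning_rate = 0.3, n_trees = tr, tree_depth = 2L,
              subsample_fraction = 1.0)
    m <- train_classifier(classifier_spec("sgb", seed = 7L), h, X, y)
    s <- predict(m, X)$score
    p <- 1 / (1 + exp(-s))
    yy <- as.integer(y == "malignant")
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }, numeric(1))
  expect_lte(logloss[2], logloss[1] + 1e-8)
  expect_lte(logloss[3], logloss[2] + 1e-8)
})

test_that("models never depend on rows outside their training set", {
  set.seed(37)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rep(c("benign", "malignant"), 15)
  tr <- 1:20
  m1 <- train_classifier(classifier_spec("rbf_svm", seed = 1L),
                         list(C = 1, gamma = 0.05, n_components = 20L),
                         X[tr, ], y[tr])
  X2 <- X; X2[21:30, ] <- X2[21:30, ] + 100   # perturb held-out rows only
  m2 <- train_classifier(classifier_spec("rbf_svm", seed = 1L),
                         list(C = 1, gamma = 0.05, n_components = 20L),
                         X2[tr, ], y[tr])
  probe <- matrix(rnorm(25), 5, 5)
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_equal(m1$scaler$mean, m2$scaler$mean)
  expect_identical(m1$nystroem$landmark_idx, m2$nystroem$landmark_idx)
})
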
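## classification: fold-scoped standardization, Nystroem kernel
## approximation, and the four classifier families (linear / poly-3 / RBF
## SVM, stochastic gradient boosting). SVM fitting is delegated to libsvm
## (e1071) and boosting to xgboost; the scaler, the Nystroem map and all
## fold scoping are owned here.

#' Fit / apply a per-dimension standard scaler
#'
#' Statistics come from the training rows only (population sd, denominator
#' n); constant dimensions get scale 1 so they map to exactly 0 on the
#' training set with no division error.
#'
#' @param X numeric matrix, rows = observations (n >= 2).
#' @return `fit_scaler()`: a `feature_scaler`; `apply_scaler()`: the
#'   transformed matrix.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_histocad("need at least 2 rows to fit a scaler")
  m <- colMeans(X)
  v <- colMeans(X^2) - m^2
  s <- sqrt(pmax(v, 0))
  s[s == 0] <- 1
  structure(list(mean = m, sd = s, dim = ncol(X)), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a `feature_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  if (ncol(X) != scaler$dim) {
    stop_histocad("feature dimension ", ncol(X), " does not match scaler (",
                  scaler$dim, ")")
  }
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Exact kernel matrix (RBF or degree-3 polynomial)
#'
#' `rbf`: `exp(-gamma * ||x - y||^2)`; `poly3`: `(gamma * <x, y> + 1)^3`.
#'
#' @param X,Y numeric matrices with matching column count (`Y` defaults to
#'   `X`).
#' @param kernel `"rbf"` or `"poly3"`.
#' @param gamma kernel scale parameter.
#' @return `nrow(X) x nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(X, Y = X, kernel = c("rbf", "poly3"), gamma) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); Y <- as.matrix(Y)
  G <- X %*% t(Y)
  if (kernel == "poly3") return((gamma * G + 1)^3)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
  exp(-gamma * pmax(d2, 0))
}

#' Fit a Nystroem low-rank kernel feature map
#'
#' Subsamples `n_components` landmark rows (without replacement, seeded),
#' eigendecomposes the landmark kernel block `K_mm = U L U'` and maps any
#' row `x` to `K(x, landmarks) U L^(-1/2)` (eigenvalues below a relative
#' tolerance are dropped). Inner products of mapped rows approximate kernel
#' values, exactly so when `n_components = n` and `K` has full rank.
#' `n_components > n` is clipped to `n` with a warning.
#'
#' @param X training feature matrix (already standardized).
#' @param kernel `"rbf"` or `"poly3"`.
#' @param gamma kernel scale parameter.
#' @param n_components number of landmarks.
#' @param seed seed for the landmark draw.
#' @return a `nystroem_map` object.
#' @export
fit_nystroem <- function(X, kernel = c("rbf", "poly3"), gamma, n_components,
                         seed = 1L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_components < 1) stop_histocad("n_components must be >= 1")
  if (n_components > n) {
    warning("n_components (", n_components, ") > n (", n, "); clipped to n",
            call. = FALSE)
    n_components <- n
  }
  idx <- with_seed(seed, sort(sample.int(n, n_components)))
  L <- X[idx, , drop = FALSE]
  Kmm <- kernel_matrix(L, L, kernel, gamma)
  e <- eigen((Kmm + t(Kmm)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-12
  if (!any(keep)) stop_histocad("landmark kernel block is numerically zero")
  B <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
  structure(list(kernel = kernel, gamma = gamma, landmarks = L,
                 landmark_idx = idx, B = B, dim = ncol(X)),
            class = "nystroem_map")
}

#' @rdname fit_nystroem
#' @param map a `nystroem_map`.
#' @export
apply_nystroem <- function(map, X) {
  X <- as.matrix(X)
  if (ncol(X) != map$dim) {
    stop_histocad("feature dimension ", ncol(X),
                  " does not match Nystroem map (", map$dim, ")")
  }
  kernel_matrix(X, map$landmarks, map$kernel, map$gamma) %*% map$B
}

#' Specify a classifier family and its hyperparameter search space
#'
#' The search distributions are the package's own (log-uniform soft-margin
#' `C` in `[1e-4, 1e2]`; kernel scale `gamma` log-uniform in `[1e-5, 1e-1]`
#' for the poly-3/RBF families with Nystroem landmark counts in
#' `{256, 512, 1024}` capped at the training size; boosting: learning rate
#' log-uniform in `[0.01, 0.3]`, trees in `{100, 300, 1000}`, depth in
#' `{1, 2, 3}`, per-iteration subsample fraction in `{0.5, 0.75, 1}`); they
#' are echoed into every report.
#'
#' @param family `"linear_svm"`, `"poly3_svm"`, `"rbf_svm"` or `"sgb"`.
#' @param seed seed for hyperparameter draws and (sgb) subsampling.
#' @param class_weights `"none"` (default) or `"balanced"`
#'   (inverse-frequency class weights).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family = c("linear_svm", "poly3_svm", "rbf_svm", "sgb"),
                            seed = 1L, class_weights = c("none", "balanced")) {
  family <- match.arg(family)
  class_weights <- match.arg(class_weights)
  hyper_space <- switch(
    family,
    linear_svm = list(C = c(1e-4, 1e2)),
    poly3_svm = ,
    rbf_svm = list(C = c(1e-4, 1e2), gamma = c(1e-5, 1e-1),
                   n_components = c(256L, 512L, 1024L), degree = 3L),
    sgb = list(learning_rate = c(0.01, 0.3), n_trees = c(100L, 300L, 1000L),
               tree_depth = 1:3, subsample_fraction = c(0.5, 0.75, 1.0)))
  structure(list(family = family, hyper_space = hyper_space,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "classifier_spec")
}

## One random hyperparameter draw per row; deterministic given seed.
sample_hypers <- function(cspec, n_iter, seed) {
  hs <- cspec$hyper_space
  with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      h <- list()
      if (!is.null(hs$C)) h$C <- exp(stats::runif(1, log(hs$C[1]), log(hs$C[2])))
      if (!is.null(hs$gamma)) {
        h$gamma <- exp(stats::runif(1, log(hs$gamma[1]), log(hs$gamma[2])))
        h$n_components <- hs$n_components[sample.int(length(hs$n_components), 1)]
      }
      if (cspec$family == "sgb") {
        h$learning_rate <- exp(stats::runif(1, log(hs$learning_rate[1]),
                                            log(hs$learning_rate[2])))
        h$n_trees <- hs$n_trees[sample.int(length(hs$n_trees), 1)]
        h$tree_depth <- hs$tree_depth[sample.int(length(hs$tree_depth), 1)]
        h$subsample_fraction <-
          hs$subsample_fraction[sample.int(length(hs$subsample_fraction), 1)]
      }
      h
    })
  })
}

LABELS <- c("benign", "malignant")

as_label_factor <- function(y) factor(as.character(y), levels = LABELS)

#' Train a classifier on raw (unscaled) feature rows
#'
#' The returned model owns its preprocessing: a standard scaler fitted on
#' `X` only, an optional Nystroem map (poly-3/RBF families) whose landmarks
#' are training rows only, and the fitted classifier. Malignant is the
#' positive class everywhere. Deterministic given the spec seed.
#'
#' @param cspec a [classifier_spec()].
#' @param hypers one hyperparameter draw (named list, see
#'   [classifier_spec()] for the fields per family).
#' @param X numeric feature matrix (training rows).
#' @param y labels, coercible to `benign` / `malignant`; both classes must
#'   be present.
#' @return a `trained_model`.
#' @export
train_classifier <- function(cspec, hypers, X, y) {
  X <- as.matrix(X)
  y <- as_label_factor(y)
  if (any(is.na(y))) stop_histocad("labels must be 'benign' or 'malignant'")
  if (length(unique(y)) < 2) {
    stop_histocad("training labels contain a single class: ", unique(as.character(y)))
  }
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  nys <- NULL
  cw <- NULL
  if (cspec$class_weights == "balanced") {
    tab <- table(y)
    cw <- stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  }
  if (cspec$family %in% c("poly3_svm", "rbf_svm")) {
    kern <- if (cspec$family == "poly3_svm") "poly3" else "rbf"
    nc <- min(hypers$n_components, nrow(Xs))
    nys <- fit_nystroem(Xs, kern, hypers$gamma, nc,
                        seed = derive_seed(cspec$seed, "landmarks"))
    Xs <- apply_nystroem(nys, Xs)
  }
  fit <- if (cspec$family == "sgb") {
    d <- xgboost::xgb.DMatrix(Xs, label = as.integer(y == "malignant"))
    with_seed(derive_seed(cspec$seed, "sgb"),
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hypers$tree_depth,
                      eta = hypers$learning_rate,
                      subsample = hypers$subsample_fraction,
                      nthread = 1L,
                      seed = derive_seed(cspec$seed, "sgb")),
        d, nrounds = hypers$n_trees, verbose = 0))
  } else {
    e1071::svm(Xs, y, kernel = "linear", cost = hypers$C, scale = FALSE,
               class.weights = cw)
  }
  structure(list(family = cspec$family, scaler = scaler, nystroem = nys,
                 fit = fit, chosen_hypers = hypers,
                 label_order = LABELS),
            class = "trained_model")
}

#' Predict labels and decision scores
#'
#' Applies the model's own scaler (and Nystroem map, if any) to `newdata`
#' and returns one row per input row with the predicted label and a finite
#' real decision score whose sign encodes the label: positive = malignant.
#'
#' @param object a `trained_model`.
#' @param newdata numeric feature matrix on the raw (unscaled) feature
#'   scale, same dimension the model was trained on.
#' @param ... unused.
#' @return `data.frame(label, score)`.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  Xs <- apply_scaler(object$scaler, as.matrix(newdata))
  if (!is.null(object$nystroem)) Xs <- apply_nystroem(object$nystroem, Xs)
  score <- if (object$family == "sgb") {
    predict(object$fit, xgboost::xgb.DMatrix(Xs), outputmargin = TRUE)
  } else {
    dv <- attr(predict(object$fit, Xs, decision.values = TRUE), "decision.values")
    ## libsvm's decision value is positive for the class named first in the
    ## column label; flip so malignant is always the positive score.
    if (startsWith(colnames(dv)[1], "malignant")) drop(dv) else -drop(dv)
  }
  if (any(!is.finite(score))) stop_histocad("non-finite decision scores")
  data.frame(label = factor(ifelse(score > 0, "malignant", "benign"),
                            levels = LABELS),
             score = unname(score))
}
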
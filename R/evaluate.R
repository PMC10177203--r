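## evaluation: patient-grouped nested k-fold cross-validation with
## random-search tuning, center-/ten-crop majority-vote testing, and report
## assembly (accuracy mean +/- sd, PPV, NPV with malignant positive).

#' Build a grouped nested cross-validation fold plan
#'
#' Outer folds partition the cases: within each label the case ids are
#' shuffled by the seed and dealt round-robin to the k folds, so fold label
#' counts differ by at most one and all images of a case follow the case.
#' For each outer fold, the remaining (training) cases are dealt the same
#' way into `k_inner` inner folds — inner splits are grouped by case too.
#' With `grouping = "image"` every image is treated as its own group, which
#' deliberately allows images of one case on both sides of a split; this
#' exists only to demonstrate the leakage such ungrouped splitting causes.
#'
#' @param manifest a `dataset_manifest`.
#' @param k,k_inner outer / inner fold counts.
#' @param seed shuffle seed.
#' @param grouping `"case"` (default) or `"image"`.
#' @return a `fold_plan`: `outer` (named integer vector unit -> fold) and
#'   `inner` (list of k named vectors over that outer fold's training
#'   units).
#' @export
make_fold_plan <- function(manifest, k = 5L, k_inner = 5L, seed = 1L,
                           grouping = c("case", "image")) {
  grouping <- match.arg(grouping)
  validate_manifest(manifest)
  r <- manifest$records
  if (grouping == "case") {
    units <- unique(r$case_id)
    labels <- r$label[match(units, r$case_id)]
  } else {
    units <- r$image_id
    labels <- r$label
  }
  if (length(units) < k) {
    stop_histocad(length(units), " ", grouping, "s is fewer than k = ", k)
  }
  deal <- function(units, labels, k, seed) {
    assign <- integer(0)
    with_seed(seed, {
      for (lab in LABELS) {
        u <- sort(units[labels == lab])
        u <- u[sample.int(length(u))]
        a <- rep(seq_len(k), length.out = length(u))
        assign <- c(assign, stats::setNames(a, u))
      }
    })
    assign[order(names(assign))]
  }
  outer <- deal(units, labels, k, derive_seed(seed, "outer"))
  inner <- lapply(seq_len(k), function(f) {
    tr <- names(outer)[outer != f]
    deal(tr, labels[match(tr, units)], k_inner, derive_seed(seed, "inner", f))
  })
  structure(list(outer = outer, inner = inner, k = as.integer(k),
                 k_inner = as.integer(k_inner), seed = as.integer(seed),
                 grouping = grouping),
            class = "fold_plan")
}

## image row indices on each side of a split, given a unit->fold assignment
split_rows <- function(assign, fold, units_of_rows) {
  test_units <- names(assign)[assign == fold]
  train_units <- names(assign)[assign != fold]
  if (length(intersect(test_units, train_units))) {
    stop_histocad("internal leakage: units on both sides of a split")
  }
  list(train = which(units_of_rows %in% train_units),
       test = which(units_of_rows %in% test_units))
}

#' Random-search hyperparameter tuning on grouped inner folds
#'
#' Draws `n_iter` candidates from the classifier's search space; each is
#' scored by the mean image-level accuracy over the inner folds, training
#' on the augmented replicates of the inner-training images and validating
#' on the center-crop feature of each inner-validation image (the
#' test-time pipeline without randomness). The arg-max candidate is
#' returned; ties break toward the earliest draw. Deterministic given
#' `seed`.
#'
#' @param cspec a [classifier_spec()].
#' @param feats a feature set from [extract_dataset_features()].
#' @param inner_assign named unit -> inner-fold assignment (one element of
#'   `fold_plan$inner`).
#' @param grouping `"case"` or `"image"` (how units map to images).
#' @param n_iter number of random draws.
#' @param seed draw seed.
#' @return list: `hypers` (chosen draw), `score` (its mean inner accuracy),
#'   `draws` (all candidates with scores).
#' @export
tune_classifier <- function(cspec, feats, inner_assign, grouping = "case",
                            n_iter = 20L, seed = 1L) {
  if (n_iter < 1) stop_histocad("n_iter must be >= 1")
  cands <- sample_hypers(cspec, n_iter, seed)
  unit_of_image <- if (grouping == "case") feats$case_id else feats$image_id
  unit_of_replicate <- unit_of_image[match(feats$train_meta$image_id, feats$image_id)]
  k_inner <- max(inner_assign)
  scores <- vapply(cands, function(h) {
    accs <- vapply(seq_len(k_inner), function(f) {
      sp_rep <- split_rows(inner_assign, f, unit_of_replicate)
      sp_img <- split_rows(inner_assign, f, unit_of_image)
      if (!length(sp_img$test) || !length(sp_rep$train)) return(NA_real_)
      y_tr <- feats$label[match(feats$train_meta$image_id[sp_rep$train],
                                feats$image_id)]
      if (length(unique(y_tr)) < 2) return(NA_real_)
      m <- train_classifier(cspec, h,
                            feats$train[sp_rep$train, , drop = FALSE], y_tr)
      pred <- predict(m, feats$center[sp_img$test, , drop = FALSE])
      mean(as.character(pred$label) == feats$label[sp_img$test])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  scores[is.nan(scores)] <- -Inf   # no evaluable inner split for this draw
  best <- if (all(!is.finite(scores))) 1L else which.max(scores)  # earliest draw wins ties
  list(hypers = cands[[best]], score = scores[best],
       draws = lapply(seq_along(cands),
                      function(i) c(cands[[i]], list(score = scores[i]))))
}

#' Majority vote over ten per-crop decision scores
#'
#' Each crop votes by the sign of its score (positive = malignant). A label
#' with at least 6 of the 10 votes wins. A 5-5 tie is broken by the label
#' whose side has the larger absolute summed score, i.e. by the sign of the
#' total score; an exactly zero total resolves to malignant (favouring
#' sensitivity).
#'
#' @param scores numeric vector of 10 decision scores.
#' @return list: `label`, `votes_malignant`, `tie` (logical).
#' @export
majority_vote <- function(scores) {
  stopifnot(length(scores) == 10L, all(is.finite(scores)))
  vm <- sum(scores > 0)
  if (vm >= 6L) return(list(label = "malignant", votes_malignant = vm, tie = FALSE))
  if (vm <= 4L) return(list(label = "benign", votes_malignant = vm, tie = FALSE))
  s <- sum(scores)
  list(label = if (s >= 0) "malignant" else "benign",
       votes_malignant = vm, tie = TRUE)
}

#' Classify one image with a trained model and a test-time crop strategy
#'
#' Applies the deterministic test pipeline (shorter-edge resize, then the
#' center crop or the ten crops, then normalization), extracts features
#' with the frozen backbone, and classifies: the single center-crop score
#' for `"center_crop"`, or [majority_vote()] over the ten per-crop scores
#' for `"ten_crop"`.
#'
#' @param model a `trained_model` fitted on features of the same backbone
#'   and augmentation geometry.
#' @param handle a `backbone_handle`.
#' @param img array `[H, W, 3]` on the 0..255 scale.
#' @param cfg the [augmentation_config()] used for the experiment (supplies
#'   `resize_edge` and `target_size`).
#' @param test_strategy `"center_crop"` or `"ten_crop"`.
#' @param stats normalization statistics, ImageNet by default.
#' @return list: `label`, `scores` (length 1 or 10), and for ten-crop the
#'   vote breakdown.
#' @export
predict_image <- function(model, handle, img, cfg,
                          test_strategy = c("center_crop", "ten_crop"),
                          stats = imagenet_stats()) {
  test_strategy <- match.arg(test_strategy)
  crops <- test_time_crops(img, cfg, test_strategy)
  X <- t(vapply(crops, function(cr) {
    extract_features(handle, normalize_image(cr, stats))
  }, numeric(feature_dimension(handle$spec))))
  pred <- predict(model, X)
  if (test_strategy == "center_crop") {
    list(label = as.character(pred$label[1]), scores = pred$score)
  } else {
    v <- majority_vote(pred$score)
    list(label = v$label, scores = pred$score,
         votes_malignant = v$votes_malignant, tie = v$tie)
  }
}

#' Configuration of one experiment combination
#'
#' One cell of the experiment grid: a backbone, a classifier family, an
#' augmentation strategy and a test strategy, evaluated by grouped nested
#' cross-validation.
#'
#' @param backbone a [backbone_spec()].
#' @param classifier a [classifier_spec()].
#' @param augmentation an [augmentation_config()] whose `target_size` equals
#'   the backbone `input_size` (checked).
#' @param test_strategy `"center_crop"` or `"ten_crop"`.
#' @param n_search_iter random-search draws per outer fold.
#' @param k,k_inner outer / inner fold counts.
#' @param grouping `"case"` (default) or `"image"` (leakage demonstration).
#' @param seed master seed; every stage seed is derived from it.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(backbone, classifier, augmentation,
                              test_strategy = c("center_crop", "ten_crop"),
                              n_search_iter = 20L, k = 5L, k_inner = 5L,
                              grouping = c("case", "image"), seed = 1L) {
  test_strategy <- match.arg(test_strategy)
  grouping <- match.arg(grouping)
  stopifnot(inherits(backbone, "backbone_spec"),
            inherits(classifier, "classifier_spec"),
            inherits(augmentation, "augmentation_config"))
  if (augmentation$target_size != backbone$input_size) {
    stop_histocad("augmentation$target_size (", augmentation$target_size,
                  ") must equal backbone$input_size (", backbone$input_size, ")")
  }
  if (n_search_iter < 1) stop_histocad("n_search_iter must be >= 1")
  structure(list(backbone = backbone, classifier = classifier,
                 augmentation = augmentation, test_strategy = test_strategy,
                 n_search_iter = as.integer(n_search_iter), k = as.integer(k),
                 k_inner = as.integer(k_inner), grouping = grouping,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run one experiment combination under grouped nested cross-validation
#'
#' For each outer fold: tune on the fold's grouped inner splits
#' ([tune_classifier()]), refit on the full outer-training replicates with
#' the chosen hyperparameters (scaler and any Nystroem landmarks from
#' training rows only), and predict every outer-test image with the
#' configured test strategy (single center crop, or ten crops combined by
#' [majority_vote()]). Accuracy is image-level; the report carries per-fold
#' accuracies, their mean and sample sd, pooled confusion counts with
#' malignant positive, PPV, NPV, the chosen hyperparameters per fold and
#' full provenance (seeds, config hash, tap-registry version). Every split
#' is mechanically checked for case overlap before use.
#'
#' @param config an [experiment_config()].
#' @param manifest a `dataset_manifest`.
#' @param features optional precomputed feature set from
#'   [extract_dataset_features()] for this manifest/backbone/augmentation
#'   (e.g. to evaluate several fold plans on identical features); computed
#'   if omitted.
#' @param cache_dir optional feature cache directory, passed through to
#'   [extract_dataset_features()].
#' @return an `evaluation_report`.
#' @export
run_experiment <- function(config, manifest, features = NULL, cache_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  validate_manifest(manifest)
  if (is.null(features)) {
    handle <- build_backbone(config$backbone)
    features <- extract_dataset_features(manifest, handle, config$augmentation,
                                         derive_seed(config$seed, "augment"),
                                         cache_dir = cache_dir)
  }
  plan <- make_fold_plan(manifest, config$k, config$k_inner,
                         derive_seed(config$seed, "folds"), config$grouping)
  unit_of_image <- if (config$grouping == "case") features$case_id else features$image_id
  unit_of_replicate <-
    unit_of_image[match(features$train_meta$image_id, features$image_id)]

  fold_acc <- numeric(config$k)
  chosen <- vector("list", config$k)
  conf <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (f in seq_len(config$k)) {
    sp_rep <- split_rows(plan$outer, f, unit_of_replicate)
    sp_img <- split_rows(plan$outer, f, unit_of_image)
    cspec <- config$classifier
    cspec$seed <- derive_seed(config$seed, "classifier", f)
    tuned <- tune_classifier(cspec, features, plan$inner[[f]], config$grouping,
                             config$n_search_iter,
                             derive_seed(config$seed, "search", f))
    chosen[[f]] <- tuned$hypers
    y_rep <- features$label[match(features$train_meta$image_id[sp_rep$train],
                                  features$image_id)]
    model <- train_classifier(cspec, tuned$hypers,
                              features$train[sp_rep$train, , drop = FALSE], y_rep)
    pred <- if (config$test_strategy == "center_crop") {
      as.character(predict(model, features$center[sp_img$test, , drop = FALSE])$label)
    } else {
      vapply(sp_img$test, function(i) {
        sc <- predict(model, features$ten[i, , ])$score
        majority_vote(sc)$label
      }, character(1))
    }
    truth <- features$label[sp_img$test]
    fold_acc[f] <- mean(pred == truth)
    conf["TP"] <- conf["TP"] + sum(pred == "malignant" & truth == "malignant")
    conf["FP"] <- conf["FP"] + sum(pred == "malignant" & truth == "benign")
    conf["TN"] <- conf["TN"] + sum(pred == "benign" & truth == "benign")
    conf["FN"] <- conf["FN"] + sum(pred == "benign" & truth == "malignant")
  }
  cfg_echo <- list(
    backbone = unclass(config$backbone), classifier = unclass(config$classifier),
    augmentation = unclass(config$augmentation),
    test_strategy = config$test_strategy, n_search_iter = config$n_search_iter,
    k = config$k, k_inner = config$k_inner, grouping = config$grouping,
    seed = config$seed)
  structure(list(
    combination = list(extractor = config$backbone$name,
                       classifier = config$classifier$family,
                       augmentation = paste0(config$augmentation$strategy, " ",
                                             config$augmentation$repeats, "x"),
                       test_strategy = config$test_strategy),
    fold_accuracy = fold_acc,
    mean_accuracy = mean(fold_acc),
    sd_accuracy = stats::sd(fold_acc),
    confusion = as.list(conf),
    ppv = unname(conf["TP"] / (conf["TP"] + conf["FP"])),
    npv = unname(conf["TN"] / (conf["TN"] + conf["FN"])),
    chosen_hypers = chosen,
    n_images = length(features$image_id),
    n_cases = length(unique(features$case_id)),
    grouping = config$grouping,
    seed = config$seed,
    config_hash = object_hash(cfg_echo),
    config = cfg_echo,
    tap_registry_version = TAP_REGISTRY$version),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cb <- x$combination
  cat(sprintf("evaluation_report: %s + %s (%s, %s)\n", cb$extractor,
              cb$classifier, cb$augmentation, cb$test_strategy))
  cat(sprintf("  accuracy: %.3f +/- %.3f over %d folds (%s-grouped)\n",
              x$mean_accuracy, x$sd_accuracy, length(x$fold_accuracy), x$grouping))
  cat(sprintf("  PPV: %.3f  NPV: %.3f  (TP %d, FP %d, TN %d, FN %d)\n",
              x$ppv, x$npv, x$confusion$TP, x$confusion$FP, x$confusion$TN,
              x$confusion$FN))
  invisible(x)
}

#' Summarize one or more evaluation reports as an experiment-grid table
#'
#' One row per combination: extractor, classifier, augmentation, test
#' strategy, mean accuracy, sample sd (ddof 1), PPV, NPV.
#'
#' @param reports an `evaluation_report` or a list of them.
#' @return a data frame.
#' @export
summarize_reports <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(extractor = r$combination$extractor,
               classifier = r$combination$classifier,
               augmentation = r$combination$augmentation,
               test_strategy = r$combination$test_strategy,
               mean_accuracy = r$mean_accuracy,
               sd_accuracy = r$sd_accuracy,
               ppv = r$ppv, npv = r$npv,
               stringsAsFactors = FALSE)
  }))
}

#' Write an evaluation report to disk (JSON + CSV)
#'
#' Output is deterministic: identical reports produce byte-identical files.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(summarize_reports(report), file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
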
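# Grouped nested cross-validation, random-search tuning, majority voting,
# and report assembly.

test_that("the 44-case outer plan deals label-balanced folds of 9,9,9,9,8", {
  m <- records_only_manifest(c(rep("benign", 20), rep("malignant", 24)))
  plan <- make_fold_plan(m, k = 5L, k_inner = 5L, seed = 3L)
  sizes <- as.vector(table(plan$outer))
  expect_equal(sort(sizes), c(8L, 9L, 9L, 9L, 9L))
  # labels balanced within one unit per fold
  labs <- m$records$label[match(names(plan$outer), m$records$case_id)]
  ben <- table(plan$outer[labs == "benign"])
  mal <- table(plan$outer[labs == "malignant"])
  expect_lte(diff(range(ben)), 1)
  expect_lte(diff(range(mal)), 1)
})

test_that("no case ever sits on both sides of any outer or inner split", {
  m <- records_only_manifest(rep(c("benign", "malignant"), each = 11),
                             images_per_case = 3L)
  plan <- make_fold_plan(m, k = 5L, k_inner = 4L, seed = 9L)
  all_cases <- unique(m$records$case_id)
  expect_setequal(names(plan$outer), all_cases)
  for (f in seq_len(plan$k)) {
    test_cases <- names(plan$outer)[plan$outer == f]
    train_cases <- names(plan$outer)[plan$outer != f]
    expect_length(intersect(test_cases, train_cases), 0L)
    inner <- plan$inner[[f]]
    expect_setequal(names(inner), train_cases)   # inner covers outer-train only
    for (g in seq_len(plan$k_inner)) {
      expect_length(intersect(names(inner)[inner == g],
                              names(inner)[inner != g]), 0L)
      expect_length(intersect(names(inner)[inner == g], test_cases), 0L)
    }
  }
})

test_that("fold plans are seed-deterministic and error below k cases", {
  m <- records_only_manifest(rep(c("benign", "malignant"), each = 6))
  p1 <- make_fold_plan(m, k = 4L, seed = 5L)
  p2 <- make_fold_plan(m, k = 4L, seed = 5L)
  expect_identical(p1, p2)
  p3 <- make_fold_plan(m, k = 4L, seed = 6L)
  expect_false(identical(p1$outer, p3$outer))
  tiny <- records_only_manifest(c("benign", "malignant", "benign"))
  expect_error(make_fold_plan(tiny, k = 5L), "fewer than k")
})

test_that("image-level grouping exists, and only as an explicit opt-in", {
  m <- records_only_manifest(rep(c("benign", "malignant"), each = 3),
                             images_per_case = 4L)
  plan <- make_fold_plan(m, k = 4L, seed = 1L, grouping = "image")
  expect_setequal(names(plan$outer), m$records$image_id)
  # images of one case straddle folds (that is the point of the demo mode)
  folds_of_case <- tapply(plan$outer, sub("/.*", "", names(plan$outer)),
                          function(x) length(unique(x)))
  expect_gt(max(folds_of_case), 1)
})

test_that("random search returns the arg-max of directly evaluated draws", {
  fs <- toy_feature_set(n_cases = 8L, images_per_case = 4L, shift = 0.8)
  man <- records_only_manifest(rep(c("benign", "malignant"), 4), 4L)
  # align unit names with the toy feature set's case ids
  inner <- setNames(rep(1:3, length.out = 8L), sprintf("c%02d", 1:8))
  cs <- classifier_spec("linear_svm", seed = 3L)
  tuned <- tune_classifier(cs, fs, inner, grouping = "case", n_iter = 6L,
                           seed = 11L)
  scores <- vapply(tuned$draws, function(d) d$score, numeric(1))
  expect_equal(tuned$score, max(scores))
  expect_equal(tuned$hypers$C, tuned$draws[[which.max(scores)]]$C)

  # oracle: re-evaluate every candidate's mean inner accuracy independently
  for (d in tuned$draws[c(1, which.max(scores))]) {
    accs <- vapply(1:3, function(f) {
      tr_units <- names(inner)[inner != f]
      te_units <- names(inner)[inner == f]
      tr <- fs$case_id %in% tr_units
      te <- fs$case_id %in% te_units
      m <- train_classifier(cs, d, fs$train[tr, ], fs$label[tr])
      mean(as.character(predict(m, fs$center[te, ])$label) == fs$label[te])
    }, numeric(1))
    expect_equal(d$score, mean(accs), tolerance = 1e-12)
  }

  # identical seed, identical choice; collapsed space returns its only point
  tuned2 <- tune_classifier(cs, fs, inner, grouping = "case", n_iter = 6L,
                            seed = 11L)
  expect_identical(tuned$hypers, tuned2$hypers)
  cs1 <- cs; cs1$hyper_space$C <- c(2, 2)
  t1 <- tune_classifier(cs1, fs, inner, grouping = "case", n_iter = 5L, seed = 1L)
  expect_equal(t1$hypers$C, 2)
})

test_that("ten-crop majority voting follows votes then the score-sum tie-break", {
  expect_equal(majority_vote(rep(1, 10))$label, "malignant")
  expect_equal(majority_vote(rep(-0.3, 10))$label, "benign")
  v <- majority_vote(c(rep(0.5, 7), rep(-4, 3)))   # 7 malignant / 3 benign
  expect_equal(v$label, "malignant")
  expect_equal(v$votes_malignant, 7)
  expect_false(v$tie)
  # 5/5: larger absolute summed score side wins
  t1 <- majority_vote(c(rep(2, 5), rep(-0.1, 5)))
  expect_true(t1$tie); expect_equal(t1$label, "malignant")
  t2 <- majority_vote(c(rep(0.1, 5), rep(-2, 5)))
  expect_equal(t2$label, "benign")
  # exact zero sum resolves to malignant
  t3 <- majority_vote(c(rep(1, 5), rep(-1, 5)))
  expect_equal(t3$label, "malignant")
  expect_error(majority_vote(rep(1, 9)))
})

test_that("single-image prediction equals the manual crop-extract-vote chain", {
  m <- tiny_dataset(n_cases = 2L, n_images = 3L, seed = 51L,
                    nucleus_rate = c(benign = 10, malignant = 80))
  spec <- backbone_spec("stub", input_size = 64L, widths = c(4L, 8L), seed = 3L)
  h <- build_backbone(spec)
  cfg <- augmentation_config("base", target_size = 64L, resize_edge = 64L)
  fe <- extract_dataset_features(m, h, cfg, seed = 4L)
  model <- train_classifier(classifier_spec("linear_svm"), list(C = 1),
                            fe$train, fe$label)
  img <- read_image(file.path(m$root, m$records$path[1]))

  pc <- predict_image(model, h, img, cfg, "center_crop")
  manual <- predict(model, matrix(extract_features(
    h, normalize_image(center_crop(resize_shorter_edge(img, 64L), 64L))), 1))
  expect_equal(pc$label, as.character(manual$label))
  expect_equal(pc$scores, manual$score, tolerance = 1e-10)

  pt <- predict_image(model, h, img, cfg, "ten_crop")
  crops <- ten_crops(resize_shorter_edge(img, 64L), 64L)
  sc <- vapply(crops, function(cr) {
    predict(model, matrix(extract_features(h, normalize_image(cr)), 1))$score
  }, numeric(1))
  expect_equal(unname(pt$scores), unname(sc), tolerance = 1e-10)
  expect_equal(pt$label, majority_vote(sc)$label)
})

test_that("report summaries equal recomputation from stored per-fold values", {
  rep_obj <- structure(list(
    combination = list(extractor = "stub", classifier = "linear_svm",
                       augmentation = "base 1x", test_strategy = "center_crop"),
    fold_accuracy = c(0.8, 0.9, 0.85, 0.8, 0.9),
    mean_accuracy = mean(c(0.8, 0.9, 0.85, 0.8, 0.9)),
    sd_accuracy = sd(c(0.8, 0.9, 0.85, 0.8, 0.9)),
    confusion = list(TP = 9L, FP = 1L, TN = 8L, FN = 2L),
    ppv = 9 / 10, npv = 8 / 10), class = "evaluation_report")
  s <- summarize_reports(rep_obj)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mean_accuracy, 0.85)
  expect_equal(s$sd_accuracy, 0.05)     # sample sd, ddof 1
  expect_equal(s$ppv, 0.9)
  expect_equal(s$npv, 0.8)
})

test_that("an experiment run is reproducible and internally consistent", {
  m <- tiny_dataset(n_cases = 3L, n_images = 3L, seed = 15L,
                    nucleus_rate = c(benign = 10, malignant = 80))
  bb <- backbone_spec("stub", input_size = 64L, widths = c(4L, 8L), seed = 2L)
  cfg <- augmentation_config("base", target_size = 64L, resize_edge = 64L)
  ec <- experiment_config(bb, classifier_spec("linear_svm"), cfg,
                          test_strategy = "ten_crop", n_search_iter = 3L,
                          k = 3L, k_inner = 2L, seed = 21L)
  r1 <- run_experiment(ec, m)
  r2 <- run_experiment(ec, m)
  expect_identical(r1, r2)
  expect_equal(r1$mean_accuracy, mean(r1$fold_accuracy))
  expect_equal(r1$sd_accuracy, sd(r1$fold_accuracy))
  cf <- r1$confusion
  expect_equal(r1$ppv, cf$TP / (cf$TP + cf$FP))
  expect_equal(r1$npv, cf$TN / (cf$TN + cf$FN))
  expect_equal(cf$TP + cf$FP + cf$TN + cf$FN, r1$n_images)
  expect_length(r1$chosen_hypers, 3L)
  expect_match(r1$config_hash, "^[0-9a-f]{32}$")

  # strong class effect at this scale should classify essentially perfectly
  expect_gte(r1$mean_accuracy, 0.9)

  # config consistency is enforced before compute
  bad_cfg <- augmentation_config("base", target_size = 32L, resize_edge = 64L)
  expect_error(experiment_config(bb, classifier_spec("linear_svm"), bad_cfg),
               "target_size")
})

test_that("written reports are byte-identical across identical runs", {
  m <- tiny_dataset(n_cases = 2L, n_images = 2L, seed = 33L)
  bb <- backbone_spec("stub", input_size = 64L, widths = c(4L, 8L), seed = 2L)
  cfg <- augmentation_config("base", target_size = 64L, resize_edge = 64L)
  ec <- experiment_config(bb, classifier_spec("linear_svm"), cfg,
                          n_search_iter = 2L, k = 2L, k_inner = 2L, seed = 8L)
  d1 <- withr_tempdir(); d2 <- withr_tempdir()
  write_report(run_experiment(ec, m), d1)
  write_report(run_experiment(ec, m), d2)
  for (f in c("report.json", "summary.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})
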
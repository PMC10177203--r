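# Shared fixture builders. Everything is generated in code at test time;
# nothing binary ships with the package.

# A small case-structured dataset on disk; returns its manifest.
tiny_dataset <- function(dir = withr_tempdir(), n_cases = 2L, n_images = 3L,
                         seed = 7L, ...) {
  p <- synthetic_params(n_cases_per_class = n_cases, images_per_case = n_images,
                        image_size = c(64L, 64L), seed = seed, ...)
  generate_dataset(p, dir)
}

withr_tempdir <- function() {
  d <- tempfile("histocad-test-")
  dir.create(d)
  d
}

# A manifest object without any images on disk (fold-plan tests only).
records_only_manifest <- function(case_labels, images_per_case = 1L) {
  recs <- do.call(rbind, lapply(seq_along(case_labels), function(i) {
    data.frame(
      image_id = sprintf("c%02d/img%02d", i, seq_len(images_per_case)),
      path = sprintf("c%02d/img%02d.png", i, seq_len(images_per_case)),
      case_id = sprintf("c%02d", i),
      label = case_labels[i],
      magnification = 400L, width_px = 64L, height_px = 64L,
      stringsAsFactors = FALSE)
  }))
  structure(list(records = recs, root = ".", layout = "flat-csv"),
            class = "dataset_manifest")
}

# Flat gray test image (H x W x 3, 0..255 scale).
gray_image <- function(h, w, value = 128) array(value, c(h, w, 3L))

# Deterministic colorful test image with full-rank structure.
pattern_image <- function(h, w, seed = 1L) {
  set.seed(seed)
  array(runif(h * w * 3L, 0, 255), c(h, w, 3L))
}

# A small stub feature set built directly in memory (no disk round trip),
# for classifier and tuning tests.
toy_feature_set <- function(n_cases = 6L, images_per_case = 4L, shift = 3,
                            seed = 42L) {
  set.seed(seed)
  n <- n_cases * images_per_case
  case_id <- rep(sprintf("c%02d", seq_len(n_cases)), each = images_per_case)
  label <- rep(rep(c("benign", "malignant"), length.out = n_cases),
               each = images_per_case)
  F <- 8L
  X <- matrix(rnorm(n * F), n, F)
  X[label == "malignant", 1] <- X[label == "malignant", 1] + shift
  ten <- array(rep(X, each = 1), c(n, 10L, F))
  for (j in 1:10) ten[, j, ] <- X + matrix(rnorm(n * F, 0, 0.01), n, F)
  list(train = X,
       train_meta = data.frame(image_id = sprintf("%s/i%02d", case_id, seq_len(n)),
                               replicate = 1L, stringsAsFactors = FALSE),
       center = X + matrix(rnorm(n * F, 0, 0.01), n, F),
       ten = ten,
       image_id = sprintf("%s/i%02d", case_id, seq_len(n)),
       case_id = case_id, label = label, feature_dim = F)
}
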
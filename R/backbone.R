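## backbones: frozen feature extractors. Intermediate convolutional maps are
## tapped at named stages, globally average-pooled (one value per channel)
## and concatenated into a single descriptor. A seeded random "stub" CNN
## exercises the identical contract without pretrained weights.

## Tap registry, version 1. Channel counts per tapped map, in forward order.
## vgg16: output of each of the five convolutional blocks, just before the
##   max-pooling layer. inception_v3: after the first two convolutional
##   blocks and the first two inception blocks, resolved against the
##   standard published definition (Conv2d_1a, Conv2d_2b, Mixed_5b,
##   Mixed_5c) — an interpretation of the verbal rule, flagged as such.
## efficientnet_b4: the last map at each block width, i.e. before every
##   channel increase (also an interpretation of the verbal rule).
TAP_REGISTRY <- list(
  version = 1L,
  vgg16 = list(
    input_size = 224L,
    taps = c(block1_prepool = 64L, block2_prepool = 128L, block3_prepool = 256L,
             block4_prepool = 512L, block5_prepool = 512L)),
  inception_v3 = list(
    input_size = 299L,
    taps = c(Conv2d_1a = 32L, Conv2d_2b = 64L, Mixed_5b = 256L, Mixed_5c = 288L),
    interpretation = TRUE),
  efficientnet_b4 = list(
    input_size = 380L,
    taps = c(stage1 = 24L, stage2 = 32L, stage3 = 56L, stage4 = 112L,
             stage5 = 160L, stage6 = 272L, stage7 = 448L),
    interpretation = TRUE)
)

#' Specify a frozen feature-extraction backbone
#'
#' @param name `"vgg16"`, `"inception_v3"`, `"efficientnet_b4"` or `"stub"`.
#'   The stub is a small frozen CNN with seeded random 3x3 kernels (ReLU,
#'   2x2 mean-pooling between stages, taps after every stage) that runs the
#'   full pipeline without any downloaded weights.
#' @param input_size expected square input edge in px (defaults: 224 / 299 /
#'   380 for the named architectures, 96 for the stub).
#' @param weights `"pretrained"` or `"seeded_random"`; the stub only
#'   supports `"seeded_random"`.
#' @param widths stub only: channel widths of the convolution stages.
#' @param seed stub only: seed for the random kernels.
#' @return a `backbone_spec` with derived `tap_points` and
#'   `channels_at_taps`.
#' @export
backbone_spec <- function(name = c("stub", "vgg16", "inception_v3", "efficientnet_b4"),
                          input_size = NULL,
                          weights = NULL,
                          widths = c(8L, 16L, 32L),
                          seed = 1L) {
  name <- match.arg(name)
  if (name == "stub") {
    widths <- as.integer(widths)
    if (!length(widths) || any(widths < 1)) {
      stop_histocad("stub backbone needs at least one positive stage width")
    }
    taps <- stats::setNames(widths, paste0("stage", seq_along(widths)))
    input_size <- as.integer(input_size %||% 96L)
    weights <- weights %||% "seeded_random"
    if (weights != "seeded_random") {
      stop_histocad("the stub backbone only supports seeded_random weights")
    }
  } else {
    reg <- TAP_REGISTRY[[name]]
    taps <- reg$taps
    input_size <- as.integer(input_size %||% reg$input_size)
    weights <- weights %||% "pretrained"
  }
  if (!length(taps)) stop_histocad("tap_points must be non-empty")
  structure(list(name = name, input_size = input_size,
                 tap_points = names(taps),
                 channels_at_taps = unname(taps),
                 weights = weights, seed = as.integer(seed),
                 tap_registry_version = TAP_REGISTRY$version),
            class = "backbone_spec")
}

#' Feature dimension of a backbone specification
#'
#' The length of every vector [extract_features()] produces under the spec:
#' the sum of channel counts over the tapped maps (e.g. VGG16:
#' 64 + 128 + 256 + 512 + 512 = 1472).
#'
#' @param spec a [backbone_spec()].
#' @return positive integer.
#' @export
feature_dimension <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  sum(spec$channels_at_taps)
}

## He-initialized 3x3 kernels, flattened to an (9 * in_ch) x out_ch matrix
## in the column order conv2d_same() builds its patch matrix.
stub_weights <- function(widths, seed) {
  with_seed(seed, {
    in_ch <- 3L
    lapply(widths, function(out_ch) {
      W <- matrix(stats::rnorm(9L * in_ch * out_ch, 0, sqrt(2 / (9 * in_ch))),
                  9L * in_ch, out_ch)
      in_ch <<- out_ch
      W
    })
  })
}

## 3x3 same-padding convolution via im2col: one matrix product per stage.
conv2d_same <- function(x, W) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  P <- matrix(0, h * w, 9L * cin)
  col <- 1L
  for (c in seq_len(cin)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        P[, col] <- xp[dy + seq_len(h), dx + seq_len(w), c]
        col <- col + 1L
      }
    }
  }
  array(P %*% W, c(h, w, ncol(W)))
}

## column order of stub_weights must match conv2d_same: (channel, dx, dy)
## fastest-last; both iterate dy inside dx inside channel.

mean_pool2 <- function(x) {
  d <- dim(x)
  h <- d[1] %/% 2L; w <- d[2] %/% 2L
  x <- x[seq_len(2L * h), seq_len(2L * w), , drop = FALSE]
  0.25 * (x[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
          x[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
          x[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE] +
          x[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE])
}

#' Build a frozen feature extractor from a backbone specification
#'
#' The returned handle never updates parameters: extracting features from
#' the same image at any time yields bit-identical vectors. Pretrained
#' VGG16 / Inception v3 / EfficientNet-B4 weights are not bundled with the
#' package; requesting them fails with an instruction to use the stub
#' backbone (the tap registry still fixes their feature dimensions, see
#' [feature_dimension()]).
#'
#' @param spec a [backbone_spec()].
#' @return a `backbone_handle`.
#' @export
build_backbone <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$name != "stub") {
    stop_histocad("pretrained weights for '", spec$name, "' are not bundled; ",
                  "use backbone_spec(\"stub\") for a self-contained extractor ",
                  "or supply the architecture's weights through a future ",
                  "weights-file loader")
  }
  structure(list(spec = spec,
                 weights = stub_weights(spec$channels_at_taps, spec$seed)),
            class = "backbone_handle")
}

#' Extract a pooled multi-tap feature vector from one normalized image
#'
#' Runs the frozen forward pass; at each tapped map the spatial mean is
#' taken per channel (global average pooling) and the pooled vectors are
#' concatenated in tap order.
#'
#' @param handle a `backbone_handle` from [build_backbone()].
#' @param img normalized array `[input_size, input_size, 3]` (see
#'   [normalize_image()]).
#' @return numeric vector of length [feature_dimension()] of the handle's
#'   spec.
#' @export
extract_features <- function(handle, img) {
  stopifnot(inherits(handle, "backbone_handle"))
  s <- handle$spec$input_size
  d <- dim(img)
  if (d[1] != s || d[2] != s) {
    stop_histocad("input is ", d[1], "x", d[2], " but the backbone expects ",
                  s, "x", s)
  }
  x <- img
  feats <- vector("list", length(handle$weights))
  for (k in seq_along(handle$weights)) {
    x <- conv2d_same(x, handle$weights[[k]])
    x[x < 0] <- 0                      # ReLU
    feats[[k]] <- colMeans(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))  # GAP
    if (k < length(handle$weights)) x <- mean_pool2(x)
  }
  unlist(feats, use.names = FALSE)
}

#' Extract features for a whole manifest (training replicates + test crops)
#'
#' For every image: `repeats` augmented training draws (per the configured
#' strategy), plus the deterministic test-time center crop and ten-crop
#' features. Each draw's seed derives from `seed`, the image id and the
#' replicate index, so features are independent of processing order and of
#' the fold a case later lands in — augmentation never leaks fold
#' information.
#'
#' @param manifest a `dataset_manifest`.
#' @param handle a `backbone_handle`.
#' @param cfg an [augmentation_config()] with `target_size` equal to the
#'   backbone input size.
#' @param seed master seed for the augmentation draws.
#' @param stats normalization statistics, ImageNet by default.
#' @param cache_dir optional directory: the feature set is stored there
#'   keyed by a fingerprint of (manifest records, backbone spec,
#'   augmentation config, seed) and reused on identical calls, so features
#'   are generated and stored once, before any classifier training.
#' @return list with `train` (matrix `(n_images * repeats) x F` plus
#'   `train_meta` data frame), `center` (`n x F`), `ten` (`n x 10 x F`
#'   array), and the manifest's `image_id`, `case_id`, `label` vectors.
#' @export
extract_dataset_features <- function(manifest, handle, cfg, seed,
                                     stats = imagenet_stats(),
                                     cache_dir = NULL) {
  validate_manifest(manifest)
  cache_file <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- object_hash(list(records = manifest$records, spec = handle$spec,
                           cfg = unclass(cfg), seed = seed, stats = stats))
    cache_file <- file.path(cache_dir, paste0("features-", fp, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  if (cfg$target_size != handle$spec$input_size) {
    stop_histocad("augmentation target_size (", cfg$target_size,
                  ") must equal backbone input_size (", handle$spec$input_size, ")")
  }
  r <- manifest$records
  n <- nrow(r)
  Fdim <- feature_dimension(handle$spec)
  train <- matrix(NA_real_, n * cfg$repeats, Fdim)
  meta <- data.frame(image_id = rep(r$image_id, each = cfg$repeats),
                     replicate = rep(seq_len(cfg$repeats), n),
                     stringsAsFactors = FALSE)
  center <- matrix(NA_real_, n, Fdim)
  ten <- array(NA_real_, c(n, 10L, Fdim))
  aug_fun <- if (cfg$strategy == "base") base_augment else advanced_augment
  for (i in seq_len(n)) {
    img <- read_image(manifest_image_path(manifest, i))
    for (rep_i in seq_len(cfg$repeats)) {
      a <- aug_fun(img, cfg, derive_seed(seed, "aug", r$image_id[i], rep_i))
      train[(i - 1L) * cfg$repeats + rep_i, ] <-
        extract_features(handle, normalize_image(a, stats))
    }
    center[i, ] <- extract_features(
      handle, normalize_image(test_time_crops(img, cfg, "center_crop")$center, stats))
    tc <- test_time_crops(img, cfg, "ten_crop")
    for (j in seq_len(10L)) {
      ten[i, j, ] <- extract_features(handle, normalize_image(tc[[j]], stats))
    }
  }
  out <- list(train = train, train_meta = meta, center = center, ten = ten,
              crop_ids = c("center", "TL", "TR", "BL", "BR",
                           "center_f", "TL_f", "TR_f", "BL_f", "BR_f"),
              image_id = r$image_id, case_id = r$case_id, label = r$label,
              feature_dim = Fdim)
  if (!is.null(cache_file)) saveRDS(out, cache_file)
  out
}
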
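## augmentation: the two training strategies (base / advanced), ImageNet
## normalization, and the deterministic center-/ten-crop test transforms.

#' ImageNet per-channel normalization statistics
#'
#' The canonical mean/sd on the unit scale, used to normalize images before
#' feature extraction; overridable wherever a `stats` argument is accepted.
#' @return list with `mean` and `sd` RGB triples.
#' @export
imagenet_stats <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

#' Configuration of the training augmentation transforms
#'
#' `base`: resize the shorter edge to `resize_edge` (aspect preserved,
#' bilinear), take a uniform random `target_size`-square crop, rotate by a
#' random multiple of 90 degrees and vertically flip with probability
#' `vflip_prob`. `advanced`: take a crop of random area fraction in
#' `scale_range` of the original image with aspect ratio log-uniform in
#' `aspect_range`, resize it to `target_size` square, apply the same
#' rotation/flip, then scale brightness, contrast and saturation each by an
#' independent factor uniform in `1 +/- jitter_fraction`.
#'
#' @param strategy `"base"` or `"advanced"`.
#' @param target_size output edge in px; must equal the backbone input size
#'   (224 VGG16, 299 Inception v3, 380 EfficientNet-B4, 96 stub).
#' @param repeats augmentation multiplier: number of independent draws kept
#'   per training image (1 or 6 in the reference experiments).
#' @param resize_edge shorter-edge length before cropping (base strategy and
#'   the test-time pipeline).
#' @param scale_range crop area fraction interval (advanced).
#' @param aspect_range aspect ratio interval, sampled log-uniformly (advanced).
#' @param jitter_fraction brightness/contrast/saturation jitter half-width.
#' @param rotation_set degrees to draw the rotation from.
#' @param vflip_prob vertical flip probability.
#' @param seed base seed for augmentation draws.
#' @return a validated `augmentation_config` object.
#' @export
augmentation_config <- function(strategy = c("base", "advanced"),
                                target_size = 96L,
                                repeats = 1L,
                                resize_edge = 512L,
                                scale_range = c(0.08, 1.0),
                                aspect_range = c(3 / 4, 4 / 3),
                                jitter_fraction = 0.20,
                                rotation_set = c(0L, 90L, 180L, 270L),
                                vflip_prob = 0.5,
                                seed = 1L) {
  strategy <- match.arg(strategy)
  if (target_size > resize_edge) {
    stop_histocad("target_size (", target_size, ") must be <= resize_edge (",
                  resize_edge, ")")
  }
  if (scale_range[1] <= 0 || scale_range[2] > 1 || scale_range[1] > scale_range[2]) {
    stop_histocad("scale_range must be an interval within (0, 1]")
  }
  if (jitter_fraction < 0 || jitter_fraction >= 1) {
    stop_histocad("jitter_fraction must be in [0, 1)")
  }
  if (!all(rotation_set %% 90 == 0)) {
    stop_histocad("rotation_set must contain multiples of 90 degrees")
  }
  structure(list(strategy = strategy, target_size = as.integer(target_size),
                 repeats = as.integer(repeats), resize_edge = as.integer(resize_edge),
                 scale_range = scale_range, aspect_range = aspect_range,
                 jitter_fraction = jitter_fraction,
                 rotation_set = as.integer(rotation_set),
                 vflip_prob = vflip_prob, seed = as.integer(seed)),
            class = "augmentation_config")
}

apply_rot_flip <- function(img, cfg) {
  rot <- cfg$rotation_set[sample.int(length(cfg$rotation_set), 1L)]
  img <- rotate90k(img, rot %/% 90L)
  if (stats::runif(1) < cfg$vflip_prob) img <- flip_vertical(img)
  img
}

#' Base-strategy training augmentation
#'
#' Resize shorter edge, uniform random crop, random 90-degree rotation,
#' random vertical flip. Deterministic given `seed`.
#'
#' @param img array `[H, W, 3]`, 0..255.
#' @param cfg an [augmentation_config()].
#' @param seed integer seed for this draw.
#' @param origin optional `c(top, left)` 0-based crop origin override
#'   (bypasses the random origin; for reproducibility checks).
#' @return array `[target_size, target_size, 3]`.
#' @export
base_augment <- function(img, cfg, seed, origin = NULL) {
  if (min(dim(img)[1:2]) < 8) stop_histocad("image too small to augment")
  img <- resize_shorter_edge(img, cfg$resize_edge)
  d <- dim(img); t <- cfg$target_size
  with_seed(seed, {
    if (is.null(origin)) {
      top  <- sample.int(d[1] - t + 1L, 1L) - 1L
      left <- sample.int(d[2] - t + 1L, 1L) - 1L
    } else {
      top <- origin[1]; left <- origin[2]
    }
    apply_rot_flip(crop_at(img, top, left, t), cfg)
  })
}

## brightness/contrast/saturation scalings on the 0..255 scale
scale_brightness <- function(img, f) clip255(img * f)
scale_contrast <- function(img, f) {
  lum <- mean(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  clip255(lum + f * (img - lum))
}
scale_saturation <- function(img, f) {
  ## HSV saturation scaling: for fixed hue and value V = max channel,
  ## channels are affine in S, so c' = V + f * (c - V) scales S by f.
  v <- pmax(img[, , 1], img[, , 2], img[, , 3])
  out <- img
  for (c in 1:3) out[, , c] <- v + f * (img[, , c] - v)
  clip255(out)
}

#' Advanced-strategy training augmentation
#'
#' Random-area crop (resized to the target square), 90-degree rotation and
#' vertical flip, then brightness/contrast/saturation jitter, in that fixed
#' order. Crop dimensions are rounded up and clamped to the frame, which
#' guarantees the realized pixel-area fraction stays within `scale_range`.
#' The realized crop-area fraction and the three jitter factors are attached
#' as attributes `crop_area_fraction` and `jitter_factors`.
#'
#' @inheritParams base_augment
#' @return array `[target_size, target_size, 3]`.
#' @export
advanced_augment <- function(img, cfg, seed) {
  d <- dim(img)
  if (min(d[1:2]) < 8) stop_histocad("image too small to augment")
  with_seed(seed, {
    u <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    a <- exp(stats::runif(1, log(cfg$aspect_range[1]), log(cfg$aspect_range[2])))
    area <- u * d[1] * d[2]
    ch <- min(d[1], ceiling(sqrt(area / a)))
    cw <- min(d[2], ceiling(sqrt(area * a)))
    ## ceiling+clamp keeps ch * cw in [area, H * W]: if one side is clamped
    ## the other side's ceiling still covers the requested area.
    if (ch * cw < area) { ch <- min(d[1], ceiling(area / cw)); cw <- min(d[2], ceiling(area / ch)) }
    top  <- sample.int(d[1] - ch + 1L, 1L) - 1L
    left <- sample.int(d[2] - cw + 1L, 1L) - 1L
    out <- crop_at(img, top, left, ch, cw)
    out <- resize_bilinear(out, cfg$target_size, cfg$target_size)
    out <- apply_rot_flip(out, cfg)
    f <- stats::runif(3, 1 - cfg$jitter_fraction, 1 + cfg$jitter_fraction)
    out <- scale_saturation(scale_contrast(scale_brightness(out, f[1]), f[2]), f[3])
    attr(out, "crop_area_fraction") <- (ch * cw) / (d[1] * d[2])
    attr(out, "jitter_factors") <- stats::setNames(f, c("brightness", "contrast", "saturation"))
    out
  })
}

#' Normalize an 8-bit RGB image with per-channel statistics
#'
#' Channels are scaled to `[0, 1]`, then centred and scaled per channel:
#' `(x - mean) / sd`.
#'
#' @param img array `[H, W, 3]`, 0..255.
#' @param stats list with `mean` and `sd` triples; ImageNet by default.
#' @return real-valued array `[H, W, 3]`.
#' @export
normalize_image <- function(img, stats = imagenet_stats()) {
  if (any(stats$sd <= 0)) stop_histocad("normalization sd must be > 0")
  out <- img / 255
  for (c in 1:3) out[, , c] <- (out[, , c] - stats$mean[c]) / stats$sd[c]
  out
}

#' Center crop and ten-crop test transforms
#'
#' `center_crop()` takes the central `size`-square window. `ten_crops()`
#' returns the center and four corner crops plus the horizontal flips of
#' those five, in the fixed order `center, TL, TR, BL, BR, center_f, TL_f,
#' TR_f, BL_f, BR_f`. Both error on undersized images. Crop offsets use a
#' top-left origin and half-open pixel intervals; the centre offset is
#' `floor((dim - size) / 2)`.
#'
#' @param img array `[H, W, 3]`.
#' @param size crop edge in px.
#' @return `center_crop()`: one array; `ten_crops()`: a named list of 10.
#' @export
center_crop <- function(img, size) {
  d <- dim(img)
  if (d[1] < size || d[2] < size) {
    stop_histocad("image ", d[1], "x", d[2], " smaller than crop size ", size)
  }
  crop_at(img, (d[1] - size) %/% 2L, (d[2] - size) %/% 2L, size)
}

#' @rdname center_crop
#' @export
ten_crops <- function(img, size) {
  d <- dim(img)
  if (d[1] < size || d[2] < size) {
    stop_histocad("image ", d[1], "x", d[2], " smaller than crop size ", size)
  }
  five <- list(center = center_crop(img, size),
               TL = crop_at(img, 0L, 0L, size),
               TR = crop_at(img, 0L, d[2] - size, size),
               BL = crop_at(img, d[1] - size, 0L, size),
               BR = crop_at(img, d[1] - size, d[2] - size, size))
  flips <- lapply(five, flip_horizontal)
  names(flips) <- paste0(names(five), "_f")
  c(five, flips)
}

## Test-time pipeline: resize shorter edge, then deterministic crop(s).
test_time_crops <- function(img, cfg, strategy = c("center_crop", "ten_crop")) {
  strategy <- match.arg(strategy)
  img <- resize_shorter_edge(img, cfg$resize_edge)
  if (strategy == "center_crop") list(center = center_crop(img, cfg$target_size))
  else ten_crops(img, cfg$target_size)
}
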
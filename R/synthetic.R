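## synthetic_histology: H&E-like fixture images with a tunable class effect
## (nucleus density) and case-level stain shifts, so that grouped
## cross-validation is consequential on generated data.

#' Parameters for the synthetic H&E generator
#'
#' Defaults are the package's reference fixture: 20 cases per class with 8
#' images each at 96 x 96 px, benign nucleus rate 20 versus malignant 120,
#' and a per-case RGB stain shift with sd 8 (8-bit scale). The palette is
#' H&E-like — pink eosin background, purple hematoxylin nuclei — with no
#' claim of morphological realism: the generator reproduces the statistical
#' structure that matters (class-dependent texture, images nested in
#' single-label cases, case-level appearance shifts), not tissue.
#'
#' @param n_cases_per_class cases (patients/slides) per class.
#' @param images_per_case images per case.
#' @param image_size `c(width, height)` in px, at least 64 x 64.
#' @param nucleus_rate named vector `c(benign =, malignant =)`: Poisson mean
#'   nucleus count per image.
#' @param nucleus_radius named vector `c(mean =, sd =)` of the per-axis
#'   nucleus radius in px (truncated normal, > 1 px).
#' @param stain_shift_sd sd (8-bit scale) of the per-case RGB tint emulating
#'   staining variability between slides.
#' @param background_rgb,nucleus_rgb 8-bit colour triples (eosin background,
#'   hematoxylin nuclei).
#' @param noise_sd sd of independent Gaussian pixel noise (8-bit scale).
#' @param seed master seed for the generator.
#' @return a validated `synthetic_params` object.
#' @export
synthetic_params <- function(n_cases_per_class = 20L,
                             images_per_case = 8L,
                             image_size = c(96L, 96L),
                             nucleus_rate = c(benign = 20, malignant = 120),
                             nucleus_radius = c(mean = 3, sd = 0.8),
                             stain_shift_sd = 8,
                             background_rgb = c(230, 180, 200),
                             nucleus_rgb = c(90, 60, 140),
                             noise_sd = 3,
                             seed = 1L) {
  stopifnot(n_cases_per_class >= 1, images_per_case >= 1)
  if (any(image_size < 64)) stop_histocad("image_size must be at least 64 x 64")
  if (any(nucleus_rate < 0)) stop_histocad("nucleus rates must be >= 0")
  if (nucleus_radius[["mean"]] <= 0 || nucleus_radius[["sd"]] < 0) {
    stop_histocad("nucleus_radius mean must be > 0 and sd >= 0")
  }
  if (stain_shift_sd < 0) stop_histocad("stain_shift_sd must be >= 0")
  stopifnot(all(c("benign", "malignant") %in% names(nucleus_rate)))
  structure(list(n_cases_per_class = as.integer(n_cases_per_class),
                 images_per_case = as.integer(images_per_case),
                 image_size = as.integer(image_size),
                 nucleus_rate = nucleus_rate,
                 nucleus_radius = nucleus_radius,
                 stain_shift_sd = stain_shift_sd,
                 background_rgb = background_rgb,
                 nucleus_rgb = nucleus_rgb,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

## radius draws truncated at > 1 px by rejection (deterministic under seed)
rtrunc_radius <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  r <- stats::rnorm(n, mean, sd)
  while (any(r <= 1)) {
    i <- r <= 1
    r[i] <- stats::rnorm(sum(i), mean, sd)
  }
  r
}

#' Generate one synthetic H&E image
#'
#' The background is `background_rgb + case_tint`; `N ~ Poisson(rate[label])`
#' elliptical nuclei with truncated-normal radii and uniform centres/
#' orientations are painted in `nucleus_rgb`; independent Gaussian pixel
#' noise is added everywhere and the result is clipped to `[0, 255]` and
#' quantized to 8 bits. Bit-identical for identical `(label, case_tint,
#' params, seed)`.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param case_tint length-3 RGB offset shared by all images of a case.
#' @param params a [synthetic_params()] object.
#' @param seed integer seed for this image's draws.
#' @return array `[height, width, 3]`, 0..255; the number of nuclei drawn is
#'   attached as attribute `n_nuclei`.
#' @export
generate_image <- function(label, case_tint, params, seed) {
  label <- match.arg(label, c("benign", "malignant"))
  w <- params$image_size[1]; h <- params$image_size[2]
  with_seed(seed, {
    n <- stats::rpois(1L, params$nucleus_rate[[label]])
    cx <- stats::runif(n, 0, w); cy <- stats::runif(n, 0, h)
    rx <- rtrunc_radius(n, params$nucleus_radius[["mean"]], params$nucleus_radius[["sd"]])
    ry <- rtrunc_radius(n, params$nucleus_radius[["mean"]], params$nucleus_radius[["sd"]])
    th <- stats::runif(n, 0, pi)
    img <- array(0, c(h, w, 3L))
    for (c in 1:3) img[, , c] <- params$background_rgb[c] + case_tint[c]
    if (n > 0) {
      for (k in seq_len(n)) {
        rmax <- max(rx[k], ry[k])
        ys <- max(1L, floor(cy[k] - rmax)):min(h, ceiling(cy[k] + rmax))
        xs <- max(1L, floor(cx[k] - rmax)):min(w, ceiling(cx[k] + rmax))
        if (!length(ys) || !length(xs)) next
        dy <- matrix(ys - 0.5 - cy[k], length(ys), length(xs))
        dx <- matrix(xs - 0.5 - cx[k], length(ys), length(xs), byrow = TRUE)
        u <-  cos(th[k]) * dx + sin(th[k]) * dy
        v <- -sin(th[k]) * dx + cos(th[k]) * dy
        mask <- (u / rx[k])^2 + (v / ry[k])^2 <= 1
        for (c in 1:3) {
          ch <- img[ys, xs, c]
          ch[mask] <- params$nucleus_rgb[c]
          img[ys, xs, c] <- ch
        }
      }
    }
    img <- img + stats::rnorm(h * w * 3L, 0, params$noise_sd)
    img <- round(clip255(img))
    attr(img, "n_nuclei") <- n
    img
  })
}

#' Generate a case-structured synthetic dataset on disk
#'
#' Writes `2 * n_cases_per_class` case directories in the CMTD layout
#' (`<label>_<case_id>/image_NN.png`) under `out_dir`, draws one RGB tint
#' per case with sd `stain_shift_sd`, and returns the manifest obtained by
#' scanning the tree back in (so the generator is exercised through the same
#' reader real archives use). Regeneration under the same params is
#' byte-identical.
#'
#' @param params a [synthetic_params()] object.
#' @param out_dir output directory (created if needed).
#' @return a `dataset_manifest` with layout `"synthetic"`.
#' @export
generate_dataset <- function(params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_histocad("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".histocad_write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop_histocad("output directory is not writable: ", out_dir)
  unlink(probe)

  wdig <- max(2L, nchar(as.character(params$images_per_case)))
  for (label in c("benign", "malignant")) {
    for (ci in seq_len(params$n_cases_per_class)) {
      case_id <- sprintf("%s%02d", substr(label, 1, 1), ci)
      tint <- with_seed(derive_seed(params$seed, "tint", case_id),
                        stats::rnorm(3L, 0, params$stain_shift_sd))
      cdir <- file.path(out_dir, paste0(label, "_", case_id))
      dir.create(cdir, showWarnings = FALSE)
      for (ii in seq_len(params$images_per_case)) {
        img <- generate_image(label, tint, params,
                              derive_seed(params$seed, "image", case_id, ii))
        write_image_png(img, file.path(cdir, sprintf("image_%0*d.png", wdig, ii)))
      }
    }
  }
  m <- scan_cmtd_layout(out_dir)
  m$layout <- "synthetic"
  m
}
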
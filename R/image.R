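## In-memory images are numeric arrays [rows (H), cols (W), 3] on the 8-bit
## scale 0..255. EBImage stores width-first, so readers/writers transpose.

#' Read an RGB image (JPEG or PNG) as an H x W x 3 array on the 0..255 scale
#'
#' @param path file path to an 8-bit RGB JPEG or PNG image.
#' @return numeric array `[height, width, 3]`, values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_histocad("image file does not exist: ", path)
  img <- try(suppressWarnings(EBImage::readImage(path)), silent = TRUE)
  if (inherits(img, "try-error")) {
    stop_histocad("cannot decode image file: ", path)
  }
  a <- as.array(img)
  if (length(dim(a)) == 2L) {           # grayscale -> replicate channels
    a <- array(rep(a, 3L), c(dim(a), 3L))
  }
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(a)[3] != 3L) stop_histocad("not an RGB image: ", path)
  aperm(a, c(2L, 1L, 3L)) * 255
}

#' Write an H x W x 3 array (0..255 scale) as an 8-bit PNG
#'
#' Pixel values are clipped and rounded to 8 bits, so output files are
#' byte-identical across runs for identical inputs.
#'
#' @param img numeric array `[height, width, 3]` on the 0..255 scale.
#' @param path destination `.png` path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(round(clip255(img)) / 255, path)
  invisible(path)
}

#' Bilinear resize of an RGB array
#'
#' Uses half-pixel-centre coordinate mapping (source position
#' `(i + 0.5) * scale - 0.5`), the convention of the common imaging
#' libraries' bilinear mode.
#'
#' @param img array `[H, W, 3]`.
#' @param new_h,new_w target height and width in pixels.
#' @return array `[new_h, new_w, 3]`.
#' @export
resize_bilinear <- function(img, new_h, new_w) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  if (new_h == h && new_w == w) return(img)
  src <- function(n_out, n_in) {
    p <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
    p <- pmin(pmax(p, 0), n_in - 1)
    i0 <- floor(p)
    list(i0 = as.integer(i0) + 1L,
         i1 = as.integer(pmin(i0 + 1, n_in - 1)) + 1L,
         t  = p - i0)
  }
  ry <- src(new_h, h)
  rx <- src(new_w, w)
  ty <- matrix(ry$t, new_h, new_w)
  tx <- matrix(rx$t, new_h, new_w, byrow = TRUE)
  out <- array(0, c(new_h, new_w, 3L))
  for (c in 1:3) {
    a00 <- img[ry$i0, rx$i0, c]; a01 <- img[ry$i0, rx$i1, c]
    a10 <- img[ry$i1, rx$i0, c]; a11 <- img[ry$i1, rx$i1, c]
    out[, , c] <- (1 - ty) * ((1 - tx) * a00 + tx * a01) +
                  ty       * ((1 - tx) * a10 + tx * a11)
  }
  out
}

#' Resize so that the shorter edge equals `edge`, preserving aspect ratio
#' @param img array `[H, W, 3]`.
#' @param edge target length of the shorter edge in pixels.
#' @export
resize_shorter_edge <- function(img, edge) {
  d <- dim(img)
  if (min(d[1:2]) == edge) return(img)
  s <- edge / min(d[1:2])
  resize_bilinear(img, max(round(d[1] * s), edge), max(round(d[2] * s), edge))
}

## Exact dihedral operations (no interpolation).
rotate90k <- function(img, k) {
  k <- (as.integer(k) %% 4L)
  if (k == 0L) return(img)
  for (i in seq_len(k)) {  # 90 degrees counter-clockwise per step
    img <- aperm(img, c(2L, 1L, 3L))[dim(img)[2]:1, , , drop = FALSE]
  }
  img
}

flip_vertical   <- function(img) img[dim(img)[1]:1, , , drop = FALSE]
flip_horizontal <- function(img) img[, dim(img)[2]:1, , drop = FALSE]

## Crop with top-left origin (0-based offsets), half-open pixel intervals.
crop_at <- function(img, top, left, size_h, size_w = size_h) {
  d <- dim(img)
  if (top < 0 || left < 0 || top + size_h > d[1] || left + size_w > d[2]) {
    stop_histocad("crop window [", top, ",", left, "] + ", size_h, "x", size_w,
                  " exceeds image ", d[1], "x", d[2])
  }
  img[(top + 1):(top + size_h), (left + 1):(left + size_w), , drop = FALSE]
}
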
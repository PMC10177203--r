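## dataset_io: case-structured image archives -> a canonical manifest.

MANIFEST_COLS <- c("image_id", "path", "case_id", "label",
                   "magnification", "width_px", "height_px")
IMAGE_EXT_RE <- "\\.(jpe?g|png)$"

new_manifest <- function(records, root, layout) {
  records <- records[order(records$path), , drop = FALSE]
  rownames(records) <- NULL
  m <- structure(list(records = records, root = root, layout = layout),
                 class = "dataset_manifest")
  validate_manifest(m)
  m
}

#' Validate a dataset manifest
#'
#' Checks the structural invariants every downstream stage relies on:
#' unique image ids, labels restricted to benign/malignant, and exactly one
#' label per case (a case is one histological slide / patient — the grouping
#' unit that must never straddle a train/test split).
#'
#' @param manifest a `dataset_manifest`.
#' @return the manifest, invisibly; errors on violation.
#' @export
validate_manifest <- function(manifest) {
  r <- manifest$records
  miss <- setdiff(MANIFEST_COLS, names(r))
  if (length(miss)) {
    stop_histocad("manifest is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(r$image_id)) {
    stop_histocad("duplicate image_id values: ",
                  paste(unique(r$image_id[duplicated(r$image_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(r$label), c("benign", "malignant"))
  if (length(bad)) stop_histocad("unknown labels: ", paste(bad, collapse = ", "))
  lab_per_case <- tapply(r$label, r$case_id, function(x) length(unique(x)))
  if (any(lab_per_case > 1)) {
    stop_histocad("case(s) with more than one label: ",
                  paste(names(lab_per_case)[lab_per_case > 1], collapse = ", "))
  }
  invisible(manifest)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  r <- x$records
  cat("dataset_manifest (", x$layout, " layout)\n", sep = "")
  cat("  root:  ", x$root, "\n", sep = "")
  cat("  images:", nrow(r), " cases:", length(unique(r$case_id)),
      " (benign:", length(unique(r$case_id[r$label == "benign"])),
      ", malignant:", length(unique(r$case_id[r$label == "malignant"])), ")\n")
  invisible(x)
}

manifest_image_path <- function(manifest, i) {
  file.path(manifest$root, manifest$records$path[i])
}

record_one_image <- function(root, rel_path, case_id, label, magnification) {
  full <- file.path(root, rel_path)
  img <- read_image(full)  # errors if undecodable
  ## relative path sans extension: unique by construction in any layout
  data.frame(image_id = sub(IMAGE_EXT_RE, "", rel_path, ignore.case = TRUE),
             path = rel_path, case_id = case_id, label = label,
             magnification = as.integer(magnification),
             width_px = dim(img)[2], height_px = dim(img)[1],
             stringsAsFactors = FALSE)
}

#' Scan a CMTD-style archive into a manifest
#'
#' Expects one directory per case under `root`, named
#' `<label>_<case_id>` with label `benign` or `malignant`, each containing
#' the case's JPEG/PNG images (e.g. `malignant_m07/image_03.jpg`). Every
#' image is decoded to verify readability and record its pixel size.
#' Output ordering is lexicographic by relative path, independent of
#' filesystem enumeration order.
#'
#' @param root archive root directory.
#' @param magnification recorded magnification for all images (the canine
#'   mammary tumour archive is single-magnification, 400x).
#' @return a `dataset_manifest` with layout `"cmtd"`.
#' @export
scan_cmtd_layout <- function(root, magnification = 400L) {
  if (!dir.exists(root)) stop_histocad("dataset root does not exist: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(dirs)) stop_histocad("no case directories under: ", root)
  recs <- list()
  for (d in dirs) {
    m <- regmatches(d, regexec("^(benign|malignant)_(.+)$", d))[[1]]
    if (length(m) != 3L) {
      stop_histocad("case directory does not follow <label>_<case_id> convention: ",
                    file.path(root, d))
    }
    label <- m[2]; case_id <- m[3]
    files <- sort(list.files(file.path(root, d), pattern = IMAGE_EXT_RE,
                             ignore.case = TRUE))
    for (f in files) {
      recs[[length(recs) + 1L]] <-
        record_one_image(root, file.path(d, f), case_id, label, magnification)
    }
  }
  if (!length(recs)) stop_histocad("no images found under: ", root)
  new_manifest(do.call(rbind, recs), root, "cmtd")
}

#' Scan a BreakHis-style archive into a manifest
#'
#' Follows the published BreakHis convention
#' `<label>/<subtype>/<patient>/<NNN>X/<file>` (extra intermediate
#' directories such as the `SOB` method level are tolerated): the label
#' directory must start with `benign` or `malignant`, the image's immediate
#' parent directory encodes the magnification (`40X`, `100X`, `200X`,
#' `400X`) and its grandparent is the patient code used as `case_id`.
#'
#' @param root archive root directory.
#' @param magnification optional integer; keep only images at this
#'   magnification.
#' @return a `dataset_manifest` with layout `"breakhis"`.
#' @export
scan_breakhis_layout <- function(root, magnification = NULL) {
  if (!dir.exists(root)) stop_histocad("dataset root does not exist: ", root)
  files <- sort(list.files(root, pattern = IMAGE_EXT_RE, recursive = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop_histocad("no images found under: ", root)
  recs <- list()
  for (f in files) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1]]
    if (length(parts) < 4L) {
      stop_histocad("path too shallow for the BreakHis convention: ", f)
    }
    lab <- tolower(parts[1])
    label <- if (startsWith(lab, "benign")) "benign"
             else if (startsWith(lab, "malignant")) "malignant"
             else stop_histocad("top-level directory is not benign/malignant: ", f)
    magdir <- parts[length(parts) - 1L]
    mm <- regmatches(magdir, regexec("^([0-9]+)X$", magdir, ignore.case = TRUE))[[1]]
    if (length(mm) != 2L) {
      stop_histocad("cannot parse magnification from path component '",
                    magdir, "' in: ", f)
    }
    mag <- as.integer(mm[2])
    if (!is.null(magnification) && mag != magnification) next
    patient <- parts[length(parts) - 2L]
    recs[[length(recs) + 1L]] <- record_one_image(root, f, patient, label, mag)
  }
  if (!length(recs)) {
    stop_histocad("no images matched under: ", root,
                  if (!is.null(magnification)) paste0(" at magnification ", magnification))
  }
  new_manifest(do.call(rbind, recs), root, "breakhis")
}

#' Read / write a manifest CSV
#'
#' The CSV is the layout-agnostic escape hatch: UTF-8, header row, columns
#' `image_id, path, case_id, label, magnification, width_px, height_px`.
#' A write-then-read round trip reproduces the manifest exactly, and
#' rewriting a read manifest reproduces the file byte for byte.
#'
#' @param path CSV file path.
#' @param root dataset root that image `path`s are relative to; defaults to
#'   the CSV's directory.
#' @return a `dataset_manifest` with layout `"flat-csv"`.
#' @export
read_manifest <- function(path, root = dirname(path)) {
  if (!file.exists(path)) stop_histocad("manifest file does not exist: ", path)
  r <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(MANIFEST_COLS, names(r))
  if (length(miss)) {
    stop_histocad("manifest CSV missing columns: ", paste(miss, collapse = ", "))
  }
  r <- r[, MANIFEST_COLS]
  for (cc in c("magnification", "width_px", "height_px")) r[[cc]] <- as.integer(r[[cc]])
  new_manifest(r, root, "flat-csv")
}

#' @rdname read_manifest
#' @param manifest a `dataset_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest$records[, MANIFEST_COLS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
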
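#' Read a grayscale image from PNG, TIFF or DICOM
#'
#' The level count R is inferred from the stored bit depth: 8-bit files give
#' R = 256, 16-bit files R = 65536. DICOM pixel data (single-frame,
#' MONOCHROME2, little-endian) are rescaled by the stored slope/intercept
#' and then rounded and clamped to `[0, R-1]`.
#'
#' @param path file to read.
#' @param format one of `"png"`, `"tiff"`, `"dicom"`; inferred from the file
#'   extension when `NULL`.
#' @return a [GrayImage].
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeGrayImage(GrayImage(matrix(0:255, 16, 16)), f)
#' img <- readGrayImage(f)
#' nLevels(img)
#' @export
readGrayImage <- function(path, format = NULL) {
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path)
  format <- if (is.null(format)) .guessFormat(path) else match.arg(tolower(format), c("png", "tiff", "dicom"))
  switch(format,
    png = .readPng(path),
    tiff = .readTiff(path),
    dicom = readDicomImage(path)
  )
}

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = "png",
    tif = , tiff = "tiff",
    dcm = , dicom = "dicom",
    stop("cannot infer image format from extension '", ext, "' for ", path,
         "; pass format explicitly")
  )
}

.readPng <- function(path) {
  arr <- tryCatch(png::readPNG(path), error = function(e)
    stop("unreadable PNG file: ", path, " (", conditionMessage(e), ")"))
  if (length(dim(arr)) == 3) {
    # gray stored with an alpha or palette expansion collapses fine; true
    # color does not
    if (dim(arr)[3] >= 3 &&
        !(all(arr[, , 1] == arr[, , 2]) && all(arr[, , 2] == arr[, , 3])))
      stop("multi-channel PNG input: ", path,
           "; convert to grayscale before reading")
    arr <- arr[, , 1]
  }
  bits <- .pngBitDepth(path)
  R <- 2^bits
  GrayImage(round(arr * (R - 1)), levels = R)
}

# bit depth byte of the IHDR chunk (offset 24 past the 8-byte signature)
.pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26) stop("truncated PNG file: ", path)
  as.integer(hdr[25])
}

.readTiff <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e)
    stop("unreadable TIFF file: ", path, " (", conditionMessage(e), ")"))
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3 &&
        !(all(img[, , 1] == img[, , 2]) && all(img[, , 2] == img[, , 3])))
      stop("multi-channel TIFF input: ", path,
           "; convert to grayscale before reading")
    img <- img[, , 1]
  }
  GrayImage(img, levels = 2^bits)
}

#' Write a grayscale image to PNG or TIFF
#'
#' 8-bit images (R = 256) are written at 8 bits, 16-bit images (R = 65536)
#' at 16 bits, for both formats; the round trip through [readGrayImage()] is
#' pixel-identical. DICOM writing is not supported.
#'
#' @param img a [GrayImage] with R of 256 or 65536.
#' @param path destination file (`.png`, `.tif`/`.tiff`).
#' @param format `"png"` or `"tiff"`; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path, format = NULL) {
  stopifnot(is(img, "GrayImage"))
  R <- nLevels(img)
  if (!R %in% c(256, 65536))
    stop("only 8-bit (R = 256) and 16-bit (R = 65536) images can be written")
  format <- if (is.null(format)) .guessFormat(path) else match.arg(tolower(format), c("png", "tiff"))
  px <- pixels(img)
  if (format == "png") {
    if (R == 256) png::writePNG(px / 255, path)
    else .write_png16(px, path)
  } else if (format == "tiff") {
    tiff::writeTIFF(px / (R - 1), path,
                    bits.per.sample = if (R == 256) 8L else 16L)
  } else {
    stop("DICOM writing is not supported; use PNG or TIFF")
  }
  invisible(path)
}

#' Read a binary lesion mask from an 8-bit PNG
#'
#' Foreground is any value above 127 (masks are conventionally stored as
#' 0/255).
#'
#' @param path PNG file.
#' @return a [BinaryMask].
#' @export
readMask <- function(path) {
  img <- .readPng(path)
  BinaryMask((pixels(img) > 127) * 1L)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a [BinaryMask].
#' @param path destination PNG.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  png::writePNG(pixels(mask) * 1.0, path)
  invisible(path)
}

#' Standardize an image to a fixed square size
#'
#' Non-square inputs are first padded to a square with level 0 (black, the
#' mammogram background) on the bottom/right so the aspect ratio is
#' preserved, then resampled bilinearly to `side x side` and rounded back to
#' integer levels. An image already at the target size is returned
#' unchanged, making the operation idempotent.
#'
#' @param img a [GrayImage].
#' @param side output side length in pixels (default 1024, the working
#'   resolution used for full-size mammograms).
#' @return a `side x side` [GrayImage] with the same level count.
#' @export
standardizeImage <- function(img, side = 1024) {
  stopifnot(is(img, "GrayImage"), side >= 2, side == round(side))
  px <- pixels(img)
  if (nrow(px) == side && ncol(px) == side) return(img)
  R <- nLevels(img)
  sq <- max(nrow(px), ncol(px))
  if (nrow(px) != sq || ncol(px) != sq) {
    pad <- matrix(0, sq, sq)
    pad[seq_len(nrow(px)), seq_len(ncol(px))] <- px
    px <- pad
  }
  out <- EBImage::resize(EBImage::Image(px / (R - 1)), w = side, h = side,
                         filter = "bilinear")
  out <- floor(EBImage::imageData(out) * (R - 1) + 0.5)
  out <- pmin(pmax(out, 0), R - 1)
  GrayImage(matrix(out, side, side), levels = R)
}

.MANIFEST_COLS <- c("case_id", "laterality", "view", "label")

#' Read and validate a cohort manifest
#'
#' The manifest is comma-delimited UTF-8 with header
#' `case_id,laterality,view,label,image_path[,mask_path,split]`. Validation
#' enforces the case-record invariants: `(case_id, laterality, view)` unique,
#' one label per case, laterality in \{L, R\}, view in \{CC, MLO\}, label in
#' \{benign, malignant\}. All offending rows are reported together, not just
#' the first.
#'
#' @param path CSV file.
#' @return a `data.frame` of case records.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  validateManifest(df)
  df
}

#' Validate a manifest data frame
#'
#' @param df data frame with at least `case_id`, `laterality`, `view`,
#'   `label` columns.
#' @return `TRUE` invisibly; stops with a message listing every violation
#'   otherwise.
#' @export
validateManifest <- function(df) {
  missing <- setdiff(.MANIFEST_COLS, names(df))
  if (length(missing))
    stop("manifest is missing required columns: ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(invisible(TRUE))
  errs <- character()
  bad <- !df$laterality %in% c("L", "R")
  if (any(bad))
    errs <- c(errs, paste0("invalid laterality in rows: ",
                           paste(which(bad), collapse = ", ")))
  bad <- !df$view %in% c("CC", "MLO")
  if (any(bad))
    errs <- c(errs, paste0("invalid view in rows: ",
                           paste(which(bad), collapse = ", ")))
  bad <- !df$label %in% c("benign", "malignant")
  if (any(bad))
    errs <- c(errs, paste0("invalid label in rows: ",
                           paste(which(bad), collapse = ", ")))
  key <- paste(df$case_id, df$laterality, df$view, sep = "|")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup))
    errs <- c(errs, paste0("duplicate (case_id, laterality, view): ",
                           paste(unique(key[dup]), collapse = "; ")))
  nlab <- tapply(df$label, df$case_id, function(x) length(unique(x)))
  conflict <- names(nlab)[nlab > 1]
  if (length(conflict))
    errs <- c(errs, paste0("conflicting labels within case(s): ",
                           paste(conflict, collapse = ", ")))
  if (length(errs))
    stop("manifest validation failed:\n  ", paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

#' Write a cohort manifest
#'
#' @param df manifest data frame.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
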
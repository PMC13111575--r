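#' Read a single-frame grayscale DICOM image
#'
#' A minimal reader for uncompressed little-endian DICOM (explicit or
#' implicit VR, transfer syntaxes 1.2.840.10008.1.2 and 1.2.840.10008.1.2.1),
#' single-frame MONOCHROME2 only. Pixel values are rescaled by the stored
#' Rescale Slope/Intercept, rounded, and clamped to `[0, R-1]` with R
#' inferred from Bits Allocated (8 -> 256, 16 -> 65536).
#'
#' @param path DICOM file.
#' @return a [GrayImage].
#' @export
readDicomImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file does not exist: ", path)
  n <- file.size(path)
  b <- readBin(path, "raw", n = n)
  if (n < 136 || rawToChar(b[129:132]) != "DICM")
    stop("unreadable DICOM file (no DICM magic): ", path)
  pos <- 133L  # first byte after the 128-byte preamble + "DICM"

  u16 <- function(at) as.integer(b[at]) + 256L * as.integer(b[at + 1L])
  u32 <- function(at) {
    as.numeric(b[at]) + 256 * as.numeric(b[at + 1L]) +
      65536 * as.numeric(b[at + 2L]) + 16777216 * as.numeric(b[at + 3L])
  }

  explicit <- TRUE  # file meta group is always explicit VR little endian
  transferSyntax <- "1.2.840.10008.1.2.1"
  elems <- list()
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (group != 0x0002 && explicit && transferSyntax == "1.2.840.10008.1.2")
      explicit <- FALSE
    if (explicit || group == 0x0002) {
      vr <- rawToChar(b[(pos + 4L):(pos + 5L)])
      if (vr %in% longVRs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    if (identical(vr, "SQ") || len == 4294967295)
      stop("unsupported DICOM element (sequence or undefined length) in ", path)
    start <- pos + hdr
    if (start + len - 1 > n) stop("truncated DICOM file: ", path)
    tag <- sprintf("%04x,%04x", group, elem)
    val <- if (len > 0) b[start:(start + len - 1L)] else raw(0)
    elems[[tag]] <- val
    if (tag == "0002,0010")
      transferSyntax <- gsub("[^0-9.]", "", rawToChar(val))
    pos <- start + len
    if (tag == "7fe0,0010") break
  }
  if (!transferSyntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported DICOM transfer syntax '", transferSyntax,
         "' (only uncompressed little endian is readable): ", path)

  getU16 <- function(tag, default = NULL) {
    v <- elems[[tag]]
    if (is.null(v)) return(default)
    as.integer(v[1]) + 256L * as.integer(v[2])
  }
  getStr <- function(tag, default = NULL) {
    v <- elems[[tag]]
    if (is.null(v)) return(default)
    trimws(rawToChar(v))
  }

  photometric <- getStr("0028,0004", "MONOCHROME2")
  if (toupper(photometric) != "MONOCHROME2")
    stop("unsupported photometric interpretation '", photometric,
         "' (MONOCHROME2 only): ", path)
  samples <- getU16("0028,0002", 1L)
  if (samples != 1L)
    stop("multi-channel DICOM input: ", path, "; convert to grayscale before reading")
  frames <- getStr("0028,0008")
  if (!is.null(frames) && as.integer(frames) > 1L)
    stop("multi-frame DICOM is not supported: ", path)
  rows <- getU16("0028,0010"); cols <- getU16("0028,0011")
  bits <- getU16("0028,0100", 16L)
  pixrep <- getU16("0028,0103", 0L)
  slope <- as.numeric(getStr("0028,1053", "1"))
  intercept <- as.numeric(getStr("0028,1052", "0"))
  pd <- elems[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pd))
    stop("DICOM file lacks image dimensions or pixel data: ", path)
  if (!bits %in% c(8L, 16L))
    stop("unsupported Bits Allocated (", bits, "); only 8 and 16 are readable")

  if (bits == 8L) {
    v <- as.integer(pd[seq_len(rows * cols)])
  } else {
    con <- rawConnection(pd)
    on.exit(close(con))
    v <- readBin(con, "integer", n = rows * cols, size = 2L,
                 signed = pixrep == 1L, endian = "little")
    if (pixrep == 0L) v <- ifelse(v < 0, v + 65536L, v)  # guard 16-bit unsigned
  }
  R <- 2^bits
  v <- pmin(pmax(floor(v * slope + intercept + 0.5), 0), R - 1)
  GrayImage(matrix(v, nrow = rows, ncol = cols, byrow = TRUE), levels = R)
}
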
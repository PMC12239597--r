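# Minimal baseline TIFF I/O: uncompressed grayscale, 8- or 16-bit,
# multi-page, little-endian. This covers the interchange format used for
# synthetic videos; it is not a general TIFF library.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_bytes = 279L)

#' Write a video stack as a multi-page TIFF
#'
#' Baseline uncompressed grayscale TIFF (PhotometricInterpretation
#' BlackIsZero), one strip per page, little-endian.
#'
#' @param video a `video_stack` (see [video_meta()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(video, path) {
  stopifnot(inherits(video, "video_stack"))
  meta <- video$meta
  nr <- meta$shape_px[1]; nc <- meta$shape_px[2]
  bps <- meta$bit_depth
  bytes_px <- bps / 8
  data_size <- nr * nc * bytes_px
  pad <- data_size %% 2            # word-align the next IFD
  n_entries <- 8L
  ifd_size <- 2L + 12L * n_entries + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) {
    x <- as.numeric(x)
    lo <- x %% 65536; hi <- x %/% 65536
    w2(lo); w2(hi)                  # avoid signed 32-bit overflow
  }
  entry <- function(tag, type, count, value) { w2(tag); w2(type); w4(count); w4(value) }

  writeChar("II", con, eos = NULL); w2(42L); w4(8L)
  off <- 8
  for (f in seq_len(meta$n_frames)) {
    data_off <- off + ifd_size
    next_ifd <- if (f < meta$n_frames) data_off + data_size + pad else 0
    w2(n_entries)
    entry(TIFF_TAGS["width"], 4L, 1L, nc)
    entry(TIFF_TAGS["length"], 4L, 1L, nr)
    entry(TIFF_TAGS["bits"], 3L, 1L, bps)
    entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)
    entry(TIFF_TAGS["strip_offsets"], 4L, 1L, data_off)
    entry(TIFF_TAGS["rows_per_strip"], 4L, 1L, nr)
    entry(TIFF_TAGS["strip_bytes"], 4L, 1L, data_size)
    w4(next_ifd)
    px <- as.vector(t(video$frames[, , f]))    # row-major
    if (bps == 8) {
      writeBin(as.raw(px), con)
    } else {
      writeBin(as.integer(ifelse(px > 32767, px - 65536, px)), con,
               size = 2, endian = "little")
    }
    if (pad) writeBin(as.raw(0), con)
    off <- data_off + data_size + pad
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the subset written by [write_tiff()]: little-endian, baseline
#' uncompressed grayscale, 8 or 16 bits per sample, any number of strips.
#'
#' @param path TIFF file.
#' @param pixel_size_um,frame_interval_s calibration to attach to the
#'   returned stack (TIFF carries no authoritative physical units here).
#' @return a `video_stack`.
#' @export
read_tiff <- function(path, pixel_size_um = 0.1, frame_interval_s = 1 / 15) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || u16(3L) != 42L)
    abort_param("malformed TIFF ", path, ": not a little-endian TIFF (offset 0)")
  frames <- list()
  off <- u32(5L)
  while (off != 0) {
    n <- u16(off + 1)
    tags <- list()
    for (k in seq_len(n)) {
      e <- off + 2 + 12 * (k - 1)
      tag <- u16(e + 1); type <- u16(e + 3); count <- u32(e + 5)
      val <- if (count == 1L) {
        if (type == 3L) u16(e + 9) else u32(e + 9)
      } else {           # value array stored at an offset
        ptr <- u32(e + 9)
        if (type == 3L) vapply(seq_len(count), function(j) u16(ptr + 1 + 2 * (j - 1)), integer(1))
        else vapply(seq_len(count), function(j) u32(ptr + 1 + 4 * (j - 1)), numeric(1))
      }
      tags[[as.character(tag)]] <- val
    }
    g <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    if ((g(TIFF_TAGS["compression"], 1L)) != 1L)
      abort_param("malformed TIFF ", path, ": compressed data at IFD offset ", off)
    nc <- g(TIFF_TAGS["width"]); nr <- g(TIFF_TAGS["length"])
    bps <- g(TIFF_TAGS["bits"], 8L)[1]
    offs <- g(TIFF_TAGS["strip_offsets"]); cnts <- g(TIFF_TAGS["strip_bytes"])
    bytes <- unlist(lapply(seq_along(offs), function(s)
      raw[(offs[s] + 1):(offs[s] + cnts[s])]))
    px <- if (bps == 8) as.integer(bytes)
          else as.integer(bytes[c(TRUE, FALSE)]) + 256L * as.integer(bytes[c(FALSE, TRUE)])
    frames[[length(frames) + 1L]] <- matrix(px, nrow = nr, ncol = nc, byrow = TRUE)
    off <- u32(off + 2 + 12 * n + 1)
  }
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  arr <- array(0L, dim = c(nr, nc, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  bit_depth <- if (bps > 8) 16L else 8L
  video_stack(video_meta(pixel_size_um, frame_interval_s, length(frames),
                         c(nr, nc), bit_depth), arr)
}
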
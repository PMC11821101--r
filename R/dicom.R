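# Minimal reader for uncompressed little-endian monochrome DICOM.
#
# Scope: Part-10 files (128-byte preamble + "DICM"), explicit- or
# implicit-VR little endian data sets, single-frame MONOCHROME pixel
# data with 8 or 16 bits allocated, unsigned. Compressed transfer
# syntaxes and big-endian files are rejected. This covers the plain
# secondary-capture style series produced by frame exporters; anything
# richer should be converted to PNG/TIFF upstream.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}

dcm_u32 <- function(raw, off) {
  dcm_u16(raw, off) + 65536 * dcm_u16(raw, off + 2L)
}

# VRs whose explicit-VR length field is 4 bytes after 2 reserved bytes.
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Walk a little-endian data set, returning a named list keyed by
# "gggg,eeee" with raw value fields. Stops after PixelData.
dcm_walk <- function(raw, off, explicit, end = length(raw)) {
  out <- list()
  while (off + 8L <= end) {
    group <- dcm_u16(raw, off)
    elem <- dcm_u16(raw, off + 2L)
    key <- sprintf("%04x,%04x", group, elem)
    if (explicit) {
      vr <- rawToChar(raw[(off + 5L):(off + 6L)])
      if (vr %in% LONG_VRS) {
        len <- dcm_u32(raw, off + 8L)
        hdr <- 12L
      } else {
        len <- dcm_u16(raw, off + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, off + 4L)
      hdr <- 8L
    }
    if (len == 4294967295) # undefined length => encapsulated/sequence
      cdkd_error("undefined-length DICOM elements are not supported",
                 "parse")
    if (off + hdr + len > end)
      cdkd_error(sprintf("truncated DICOM element %s", key), "parse")
    out[[key]] <- raw[seq.int(off + hdr + 1L, length.out = len)]
    off <- off + hdr + len
    if (key == "7fe0,0010") break
  }
  attr(out, "next_offset") <- off
  out
}

dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el[el != as.raw(0L)]))
}

dcm_us <- function(el) if (is.null(el)) NULL else dcm_u16(el, 0L)

read_one_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L ||
      rawToChar(raw[129:132]) != "DICM")
    cdkd_error(sprintf("%s is not a DICOM part-10 file", path), "parse")
  # File meta group (0002) is always explicit VR little endian.
  meta_len_el <- dcm_walk(raw, 132L, explicit = TRUE, end = 144L)
  meta_len <- dcm_u32(meta_len_el[["0002,0000"]], 0L)
  meta_end <- attr(meta_len_el, "next_offset") + meta_len
  meta <- dcm_walk(raw, 132L, explicit = TRUE, end = meta_end)
  ts <- dcm_str(meta[["0002,0010"]])
  if (is.null(ts)) ts <- TS_EXPLICIT_LE
  if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE))
    cdkd_error(sprintf(
      "unsupported DICOM transfer syntax %s in %s (only uncompressed little endian)",
      ts, path), "parse")
  ds <- dcm_walk(raw, meta_end, explicit = ts == TS_EXPLICIT_LE)

  rows <- dcm_us(ds[["0028,0010"]])
  cols <- dcm_us(ds[["0028,0011"]])
  bits_alloc <- dcm_us(ds[["0028,0100"]]) %||% 8L
  bits_stored <- dcm_us(ds[["0028,0101"]]) %||% bits_alloc
  px <- ds[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    cdkd_error(sprintf("DICOM file %s lacks Rows/Columns/PixelData", path),
               "parse")
  n <- rows * cols
  vals <- if (bits_alloc == 8L) {
    as.integer(px[seq_len(n)])
  } else if (bits_alloc == 16L) {
    lo <- as.integer(px[seq.int(1L, by = 2L, length.out = n)])
    hi <- as.integer(px[seq.int(2L, by = 2L, length.out = n)])
    lo + 256L * hi
  } else {
    cdkd_error(sprintf("unsupported BitsAllocated %d in %s",
                       bits_alloc, path), "parse")
  }
  inst <- dcm_str(ds[["0020,0013"]])
  list(pixels = matrix(as.numeric(vals), nrow = rows, ncol = cols,
                       byrow = TRUE),
       max_value = 2^bits_stored - 1,
       instance_number = if (is.null(inst) || inst == "") NA_real_
                         else as.numeric(inst))
}
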
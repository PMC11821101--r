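# Hand-constructed DICOM byte streams (explicit VR little endian),
# written field by field from the file-format layout so the package
# reader is tested against an independent construction.

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                    endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, as.raw(0L)) # even-length padding
  hdr <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    c(hdr, as.raw(c(0, 0)), dcm_raw_u32(length(value_raw)), value_raw)
  } else {
    c(hdr, dcm_raw_u16(length(value_raw)), value_raw)
  }
}

# Minimal single-frame monochrome DICOM: 8-bit pixels given as an
# integer matrix (row-major pixel order, as PixelData stores rows).
write_test_dicom <- function(pixels, path, instance_number = NULL) {
  meta_elements <- dcm_element(0x0002, 0x0010, "UI",
                               charToRaw("1.2.840.10008.1.2.1"))
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        dcm_raw_u32(length(meta_elements))),
            meta_elements)
  body <- raw(0)
  if (!is.null(instance_number))
    body <- c(body, dcm_element(0x0020, 0x0013, "IS",
                                charToRaw(as.character(instance_number))))
  body <- c(body,
            dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(nrow(pixels))),
            dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(ncol(pixels))),
            dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(8L)),
            dcm_element(0x0028, 0x0101, "US", dcm_raw_u16(8L)),
            dcm_element(0x7FE0, 0x0010, "OB",
                        as.raw(as.integer(t(pixels)))))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  invisible(path)
}
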
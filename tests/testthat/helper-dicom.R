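# Synthetic explicit-VR little-endian DICOM writer used to exercise the
# reader; writes only the tags the reader consumes.

write_test_dicom_slice <- function(path, pixels, z_mm, pixel_spacing = c(1, 1),
                                   thickness = 3, slope = 1,
                                   intercept = -1024) {
  stopifnot(is.matrix(pixels))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  tag <- function(group, elem, vr, value_raw) {
    u16(group); u16(elem)
    writeChar(vr, con, eos = NULL)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      u16(0)
      writeBin(length(value_raw), con, size = 4, endian = "little")
    } else {
      u16(length(value_raw))
    }
    writeBin(value_raw, con)
  }
  str_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))  # even length
    r
  }
  us_raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
  tag(0x0018, 0x0050, "DS", str_raw(format(thickness)))
  tag(0x0020, 0x0032, "DS",
      str_raw(sprintf("0\\0\\%s", format(z_mm))))
  tag(0x0028, 0x0010, "US", us_raw(nrow(pixels)))
  tag(0x0028, 0x0011, "US", us_raw(ncol(pixels)))
  tag(0x0028, 0x0030, "DS",
      str_raw(sprintf("%s\\%s", format(pixel_spacing[1]),
                      format(pixel_spacing[2]))))
  tag(0x0028, 0x0100, "US", us_raw(16))
  tag(0x0028, 0x0103, "US", us_raw(0))          # unsigned stored values
  tag(0x0028, 0x1052, "DS", str_raw(format(intercept)))
  tag(0x0028, 0x1053, "DS", str_raw(format(slope)))
  # pixel data, row-major (columns fastest)
  px <- as.integer(t(pixels))
  tag(0x7FE0, 0x0010, "OW", writeBin(px, raw(), size = 2, endian = "little"))
  invisible(path)
}
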
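# Minimal 8-bit grayscale BMP I/O (BITMAPINFOHEADER, 256-entry gray palette,
# bottom-up rows padded to 4 bytes). Matrices are [row = y, col = x] with
# row 1 at the top, matching the TIFF reader.

write_bmp8 <- function(px, file) {
  stopifnot(is.matrix(px), min(px) >= 0, max(px) <= 255)
  h <- nrow(px); w <- ncol(px)
  pad <- (4 - (w %% 4)) %% 4
  rowbytes <- w + pad
  datasize <- rowbytes * h
  offset <- 14L + 40L + 1024L
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(offset + datasize), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(offset), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")       # BI_RGB
  writeBin(as.integer(datasize), con, size = 4, endian = "little")
  writeBin(c(0L, 0L), con, size = 4, endian = "little") # ppm
  writeBin(c(256L, 0L), con, size = 4, endian = "little")
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
  writeBin(pal, con)
  padraw <- as.raw(rep(0, pad))
  for (r in h:1) { # bottom-up
    writeBin(as.raw(px[r, ]), con)
    if (pad > 0) writeBin(padraw, con)
  }
  invisible(file)
}

read_bmp8 <- function(file) {
  raw <- readBin(file, "raw", file.size(file))
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file: ", file,
                                        call. = FALSE)
  le32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  le16 <- function(i) sum(as.integer(raw[i + 0:1]) * 256^(0:1))
  offset <- le32(11)
  w <- le32(19); h <- le32(23)
  bits <- le16(29)
  if (bits != 8L) stop("only 8-bit BMP supported, got ", bits, "-bit",
                       call. = FALSE)
  pad <- (4 - (w %% 4)) %% 4
  rowbytes <- w + pad
  px <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    start <- offset + (r - 1L) * rowbytes
    px[h - r + 1L, ] <- as.integer(raw[start + seq_len(w)])
  }
  px
}
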
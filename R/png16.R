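# Minimal 16-bit grayscale PNG encoder. The installed PNG bindings only
# write 8-bit files, so label masks with more than 256 classes are encoded
# here directly: zlib stream via memCompress, CRC-32 computed in R.

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(crc32_env$table)) return(crc32_env$table)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256L)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L))
           else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  crc32_env$table <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    c <- bitwXor(bitwShiftR(c, 8L), tab[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

int_be <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_be(length(data)), body, int_be(crc32(body)))
}

# mat: integer matrix (rows x cols), values in [0, 65535]
png_write_gray16 <- function(mat, path) {
  h <- nrow(mat); w <- ncol(mat)
  if (max(mat) > 65535L || min(mat) < 0L)
    stopf("16-bit PNG values must lie in [0, 65535]")
  ihdr <- c(int_be(w), int_be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, deflate, none
  # scanlines: filter byte 0 + big-endian 16-bit samples, row by row
  vals <- as.integer(t(mat))
  samples <- as.raw(rbind(vals %/% 256L, vals %% 256L))
  rows <- matrix(samples, nrow = 2L * w)
  scan <- as.raw(rbind(raw(ncol(rows)), rows))  # prepend filter byte per row
  idat <- memCompress(as.vector(scan), type = "gzip")  # zlib stream
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}
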
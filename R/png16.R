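# Minimal 16-bit grayscale PNG writer. The `png` package reads 16-bit
# images but writes 8-bit only, and no other installed package writes
# PNG, so the encoder is authored here: IHDR/IDAT/IEND chunks, filter
# type 0 scanlines, and base R's memCompress for the IDAT stream
# (despite its "gzip" label it emits an RFC-1950 zlib stream, which is
# what PNG requires). Round trips are verified against png::readPNG in
# the test suite.

crc32_table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L  # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    c <- bitwXor(bitwShiftR(c, 8L),
                 crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

u32_bytes <- function(x) {
  # big-endian bytes of a 32-bit value given as double in [0, 2^32)
  x <- x %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

int32_bytes <- function(x) {
  # signed 32-bit integer (e.g. crc32 output) to unsigned big-endian
  u32_bytes(if (x < 0) x + 2^32 else x)
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_bytes(length(data)), body, int32_bytes(crc32(body)))
}

zlib_wrap <- function(data) memCompress(data, "gzip")

#' Write a matrix as a 16-bit grayscale PNG
#'
#' @param image numeric matrix of integer pixel values in `[0, 65535]`
#'   (rows are image rows).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_png16 <- function(image, path) {
  image <- round(as.matrix(image))
  if (any(!is.finite(image)) || any(image < 0) || any(image > 65535)) {
    stop("pixel values must be integers in [0, 65535]", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  ihdr <- c(u32_bytes(w), u32_bytes(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # bit depth 16, grayscale
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  vals <- as.vector(t(image))
  hi <- as.raw(vals %/% 256)
  lo <- as.raw(vals %% 256)
  sample_bytes <- as.vector(rbind(hi, lo))
  scan <- matrix(sample_bytes, nrow = 2L * w)
  raw_data <- as.raw(unlist(lapply(seq_len(h), function(r) {
    c(as.raw(0L), scan[, r])
  })))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_wrap(raw_data)),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}
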
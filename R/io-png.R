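# Minimal 8-bit grayscale PNG export (figures only; reading is not needed).
# memCompress(type = "gzip") emits the zlib-framed deflate stream PNG
# expects in IDAT; chunk CRC-32s are computed here (no image libraries).

# CRC-32 (IEEE 802.3) over a raw vector, implemented on doubles to avoid
# signed 32-bit overflow in R's bitwise integer operators
crc32_tab <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        odd <- c %% 2
        c <- floor(c / 2)
        if (odd) c <- bitwxor_dbl(c, 0xEDB88320)
      }
      t[n + 1] <- c
    }
    tab <<- t
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_tab()
  crc <- 4294967295
  for (b in as.integer(bytes)) {
    idx <- bitwxor_dbl(crc %% 256, b) + 1
    crc <- bitwxor_dbl(floor(crc / 256), tab[idx])
  }
  bitwxor_dbl(crc, 4294967295)
}

# XOR of two non-negative doubles < 2^32
bitwxor_dbl <- function(a, b) {
  r <- 0; p <- 1
  while (a > 0 || b > 0) {
    ra <- a %% 2; rb <- b %% 2
    if (ra != rb) r <- r + p
    a <- floor(a / 2); b <- floor(b / 2); p <- p * 2
  }
  r
}

u32_be <- function(x) {
  as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
           floor(x / 256) %% 256, x %% 256))
}

png_chunk <- function(type, payload) {
  body <- c(charToRaw(type), payload)
  c(u32_be(length(payload)), body, u32_be(crc32(body)))
}

#' Export an image or slice as an 8-bit grayscale PNG
#'
#' Intensities are clipped to \code{[0, 1]} and quantized to 8 bits (the
#' conversion applied before any figure export), then written as a minimal
#' single-channel PNG.
#'
#' @param image matrix, \code{em_volume} slice, or 3D array (slice \code{z}).
#' @param path output path.
#' @param z slice index for volumes.
#' @return \code{path}, invisibly.
#' @export
png_export <- function(image, path, z = 1L) {
  m <- if (inherits(image, "em_volume") || (is.array(image) && !is.matrix(image)))
    as_volume_data(image)[, , z] else image
  v <- round(pmin(pmax(m, 0), 1) * 255)
  ny <- nrow(v); nx <- ncol(v)
  scan <- as.raw(as.vector(rbind(0L, t(v))))        # filter byte 0 per row
  idat <- memCompress(scan, type = "gzip")          # zlib-wrapped deflate
  ihdr <- c(u32_be(nx), u32_be(ny), as.raw(c(8L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
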
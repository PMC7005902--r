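# Baseline TIFF I/O for grayscale volumes.
#
# Hand-written reader/writer for uncompressed baseline TIFF (the only image
# format dependency the package has): multi-page = z, 8/16-bit unsigned or
# 32-bit float samples, one channel. Run metadata travels as a JSON string
# in the ImageDescription tag of the first page, which keeps files readable
# by any baseline-conformant viewer. Output is little-endian; both byte
# orders are accepted on read.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `11` = 4L, `12` = 8L)

#' Write a volume as a multi-page grayscale TIFF
#'
#' Each z-slice becomes one page. \code{dtype = "float32"} (default) writes
#' samples losslessly; \code{"uint8"}/\code{"uint16"} quantize after
#' clipping to \code{[0, 1]} (explicit lossy export). A
#' \code{\link{run_record}} (or any list) is serialized as JSON into the
#' ImageDescription tag and restored by \code{\link{read_volume}}.
#'
#' @param volume an \code{em_volume} (or matrix / 3D array).
#' @param path output file path.
#' @param record optional \code{run_record} or list stored as metadata.
#' @param dtype on-disk sample type.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path, record = NULL,
                         dtype = c("float32", "uint8", "uint16")) {
  dtype <- match.arg(dtype)
  a <- as_volume_data(volume)
  ny <- dim(a)[1]; nx <- dim(a)[2]; nz <- dim(a)[3]
  bits <- switch(dtype, float32 = 32L, uint8 = 8L, uint16 = 16L)
  sfmt <- if (dtype == "float32") 3L else 1L
  bytes_per_px <- bits %/% 8L
  desc <- {
    meta <- list(format = "emrestore-tiff", version = 1L)
    if (!is.null(record)) meta$run_record <- unclass(record)
    charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  }
  desc <- c(desc, as.raw(0L))                       # NUL-terminated ASCII
  if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))

  strip_len <- ny * nx * bytes_per_px
  data_off <- 8L
  desc_off <- data_off + nz * strip_len
  ifd_off0 <- desc_off + length(desc)
  n_tags <- function(z) if (z == 1L) 11L else 10L
  ifd_len <- function(z) 2L + 12L * n_tags(z) + 4L
  ifd_offs <- ifd_off0 + c(0L, cumsum(vapply(seq_len(nz)[-nz], ifd_len, 1L)))[seq_len(nz)]

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_offs[1])
  for (z in seq_len(nz)) {
    m <- t(a[, , z])                                # row-major on disk
    if (dtype == "float32") {
      writeBin(as.numeric(m), con, size = 4, endian = "little")
    } else {
      maxv <- 2^bits - 1
      v <- as.integer(round(pmin(pmax(as.numeric(m), 0), 1) * maxv))
      if (dtype == "uint8") writeBin(as.raw(v), con)
      else {
        vv <- ifelse(v > 32767L, v - 65536L, v)     # reinterpret as signed
        writeBin(as.integer(vv), con, size = 2, endian = "little")
      }
    }
  }
  writeBin(desc, con)
  tag <- function(id, type, count, value) {         # value fits in 4 bytes
    w2(id); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (z in seq_len(nz)) {
    w2(n_tags(z))
    tag(256L, 4L, 1L, nx)                           # ImageWidth
    tag(257L, 4L, 1L, ny)                           # ImageLength
    tag(258L, 3L, 1L, bits)                         # BitsPerSample
    tag(259L, 3L, 1L, 1L)                           # Compression: none
    tag(262L, 3L, 1L, 1L)                           # Photometric: BlackIsZero
    if (z == 1L) tag(270L, 2L, length(desc), desc_off)  # ImageDescription
    tag(273L, 4L, 1L, data_off + (z - 1L) * strip_len)  # StripOffsets
    tag(277L, 3L, 1L, 1L)                           # SamplesPerPixel
    tag(278L, 4L, 1L, ny)                           # RowsPerStrip
    tag(279L, 4L, 1L, strip_len)                    # StripByteCounts
    tag(339L, 3L, 1L, sfmt)                         # SampleFormat
    w4(if (z < nz) ifd_offs[z + 1L] else 0L)        # next IFD
  }
  invisible(path)
}

#' Read a grayscale TIFF volume
#'
#' Reads uncompressed baseline grayscale TIFF (8/16-bit unsigned or 32-bit
#' float, multi-page, either byte order, one or more strips per page).
#' Integer samples are normalized to \code{[0, 1]}; float samples are taken
#' as stored. RGB/multichannel files are rejected. A JSON ImageDescription
#' written by \code{\link{write_volume}} is parsed back into the volume
#' metadata.
#'
#' @param path file path.
#' @return an \code{em_volume}; any embedded run record is available as
#'   \code{$metadata$run_record}.
#' @export
read_volume <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8) stop("not a TIFF file (too short)")
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
    else stop("not a TIFF file (bad byte-order mark)")
  rd_int <- function(off, size, n = 1L)             # off: 0-based
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n,
            size = size, signed = size == 4, endian = endian)
  rd_uint <- function(off, size, n = 1L) {
    if (size == 4L) {                               # unsigned 32-bit via wrap
      v <- readBin(raw_all[(off + 1):(off + 4L * n)], "integer", n = n,
                   size = 4, endian = endian)
      return(ifelse(v < 0, v + 2^32, v))
    }
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n,
            size = size, signed = FALSE, endian = endian)
  }
  if (rd_uint(2, 2) != 42L) stop("not a TIFF file (bad magic)")
  ifd_off <- rd_int(4, 4)
  slices <- list(); desc_json <- NULL
  while (ifd_off != 0L) {
    n_tags <- rd_uint(ifd_off, 2)
    tags <- list()
    for (t in seq_len(n_tags)) {
      base <- ifd_off + 2L + (t - 1L) * 12L
      id <- rd_uint(base, 2); type <- rd_uint(base + 2, 2)
      count <- rd_int(base + 4, 4)
      size <- TIFF_TYPE_SIZE[[as.character(type)]]
      if (is.null(size)) next
      val_off <- if (size * count > 4L) rd_int(base + 8, 4) else base + 8L
      value <- if (type == 2L) {
        seg <- raw_all[(val_off + 1):(val_off + count)]
        nul <- which(seg == as.raw(0L))
        if (length(nul)) seg <- seg[seq_len(nul[1] - 1L)]
        rawToChar(seg)
      } else if (type == 3L) rd_uint(val_off, 2, count)
      else if (type %in% c(1L, 4L)) rd_uint(val_off, if (type == 1L) 1 else 4, count)
      else NULL
      tags[[as.character(id)]] <- value
    }
    g <- function(id, default = NULL)
      if (!is.null(tags[[as.character(id)]])) tags[[as.character(id)]] else default
    nx <- g(256); ny <- g(257)
    bits <- g(258, 1L); comp <- g(259, 1L); photo <- g(262, 1L)
    spp <- g(277, 1L); sfmt <- g(339, 1L)
    if (comp != 1L) stop("compressed TIFF not supported")
    if (length(bits) > 1L || spp > 1L || photo > 1L)
      stop("multichannel/RGB TIFF rejected: grayscale only")
    offs <- g(273); cnts <- g(279)
    if (is.null(offs)) stop("missing strip offsets")
    strip_raw <- unlist(lapply(seq_along(offs), function(s)
      raw_all[(offs[s] + 1):(offs[s] + cnts[s])]))
    n_px <- ny * nx
    vals <- if (sfmt == 3L && bits == 32L) {
      readBin(strip_raw, "double", n = n_px, size = 4, endian = endian)
    } else if (bits == 8L) {
      as.integer(strip_raw[seq_len(n_px)]) / 255
    } else if (bits == 16L) {
      readBin(strip_raw, "integer", n = n_px, size = 2, signed = FALSE,
              endian = endian) / 65535
    } else stop(sprintf("unsupported sample layout: %d bits, format %d", bits, sfmt))
    slices[[length(slices) + 1L]] <- matrix(vals, ny, nx, byrow = TRUE)
    if (is.null(desc_json) && !is.null(g(270))) desc_json <- g(270)
    dt <- if (sfmt == 3L) "float" else if (bits == 8L) "uint8" else "uint16"
    ifd_off <- rd_int(ifd_off + 2L + 12L * n_tags, 4)
    if (ifd_off == 0L) attr(slices, "dtype") <- dt
  }
  if (!length(slices)) stop("no image pages found")
  meta <- list()
  if (!is.null(desc_json)) {
    parsed <- tryCatch(jsonlite::fromJSON(desc_json, simplifyVector = TRUE),
                       error = function(e) NULL)
    if (!is.null(parsed$run_record)) meta$run_record <- parsed$run_record
  }
  arr <- array(unlist(slices), dim = c(nrow(slices[[1]]), ncol(slices[[1]]),
                                       length(slices)))
  em_volume(arr, source_dtype = attr(slices, "dtype"), metadata = meta)
}
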
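# Minimal baseline TIFF codec: multi-page, single-channel, uncompressed,
# strip-organised, little- or big-endian. This covers exactly the label /
# intensity / probability movies the curation pipeline exchanges; anything
# fancier (compression, tiles, multi-sample pages) is rejected loudly rather
# than guessed at.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(rawToChar(magic), "II")) "little"
            else if (identical(rawToChar(magic), "MM")) "big"
            else stop_data("not a TIFF file: ", path)
  fortytwo <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (fortytwo != 42L) stop_data("not a TIFF file (bad magic): ", path)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
  pages <- list()
  while (ifd_off > 0) {
    seek(con, ifd_off)
    n <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(n)) {
      tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
      typ <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
      cnt <- readBin(con, "integer", 1, size = 4, endian = endian)
      valraw <- readBin(con, "raw", 4)
      tags[[as.character(tag)]] <- list(type = typ, count = cnt, raw = valraw)
    }
    ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
    pages[[length(pages) + 1L]] <- tags
  }
  decode_vals <- function(tg) {
    sz <- TIFF_TYPE_SIZE[[as.character(tg$type)]]
    total <- sz * tg$count
    if (total <= 4) {
      raw <- tg$raw[seq_len(total)]
    } else {
      off <- readBin(tg$raw, "integer", 1, size = 4, endian = endian)
      seek(con, off)
      raw <- readBin(con, "raw", total)
    }
    if (tg$type %in% c(3L, 8L))
      readBin(raw, "integer", tg$count, size = 2, signed = tg$type == 8L,
              endian = endian)
    else if (tg$type %in% c(4L, 9L))
      readBin(raw, "integer", tg$count, size = 4, endian = endian)
    else if (tg$type == 11L)
      readBin(raw, "double", tg$count, size = 4, endian = endian)
    else if (tg$type == 12L)
      readBin(raw, "double", tg$count, size = 8, endian = endian)
    else if (tg$type == 1L)
      as.integer(readBin(raw, "raw", tg$count))
    else raw
  }
  lapply(pages, function(tags) {
    gettag <- function(id, default = NULL) {
      tg <- tags[[as.character(id)]]
      if (is.null(tg)) return(default)
      decode_vals(tg)
    }
    w <- gettag(256); h <- gettag(257)
    if (is.null(w) || is.null(h)) stop_data("TIFF page without dimensions")
    bits <- gettag(258, 1L)
    comp <- gettag(259, 1L)
    if (comp != 1L) stop_data("compressed TIFF not supported (compression=",
                              comp, ")")
    spp <- gettag(277, 1L)
    if (spp != 1L)
      stop_data("multi-channel TIFF unsupported: SamplesPerPixel=", spp,
                " (channels unsupported)")
    if (!is.null(gettag(322))) stop_data("tiled TIFF not supported")
    fmt <- gettag(339, 1L)   # 1 uint, 2 int, 3 float
    offs <- gettag(273); cnts <- gettag(279)
    if (is.null(offs) || is.null(cnts)) stop_data("TIFF page without strips")
    raw <- raw(0)
    for (k in seq_along(offs)) {
      seek(con, offs[k])
      raw <- c(raw, readBin(con, "raw", cnts[k]))
    }
    npx <- as.numeric(w) * h
    v <- if (fmt == 3L) {
      if (!bits %in% c(32L, 64L)) stop_data("unsupported float depth ", bits)
      readBin(raw, "double", npx, size = bits / 8L, endian = endian)
    } else if (bits == 8L) {
      as.numeric(readBin(raw, "integer", npx, size = 1,
                         signed = fmt == 2L, endian = endian))
    } else if (bits == 16L) {
      as.numeric(readBin(raw, "integer", npx, size = 2,
                         signed = fmt == 2L, endian = endian))
    } else if (bits == 32L) {
      as.numeric(readBin(raw, "integer", npx, size = 4, endian = endian))
    } else stop_data("unsupported bit depth ", bits)
    if (length(v) < npx) stop_data("truncated TIFF strip data")
    list(data = matrix(v[seq_len(npx)], nrow = h, ncol = w, byrow = TRUE),
         sample_format = fmt, bits = bits)
  })
}

write_tiff_pages <- function(pages, path, bits, sample_format) {
  # pages: list of Y x X numeric matrices; single strip per page
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n_pages <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  bytes_px <- as.integer(bits / 8)
  strip_bytes <- as.integer(h * w * bytes_px)
  ifd_bytes <- 2L + 10L * 12L + 4L
  data_off <- 8L
  ifd0_off <- as.integer(data_off + n_pages * strip_bytes)
  writeBin(ifd0_off, con, size = 4, endian = "little")
  for (m in pages) {
    v <- as.vector(t(m))
    if (sample_format == 3L) writeBin(v, con, size = bytes_px, endian = "little")
    else writeBin(as.integer(v), con, size = bytes_px, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {   # SHORT, left-justified in the 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (p in seq_len(n_pages)) {
    writeBin(10L, con, size = 2, endian = "little")
    entry(256, 4, 1, w)
    entry(257, 4, 1, h)
    entry(258, 3, 1, bits)
    entry(259, 3, 1, 1)            # no compression
    entry(262, 3, 1, 1)            # BlackIsZero
    entry(273, 4, 1, data_off + (p - 1L) * strip_bytes)
    entry(277, 3, 1, 1)
    entry(278, 4, 1, h)
    entry(279, 4, 1, strip_bytes)
    entry(339, 3, 1, sample_format)
    nxt <- if (p < n_pages) as.integer(ifd0_off + p * ifd_bytes) else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }
  invisible(path)
}
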
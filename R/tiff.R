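# Minimal baseline TIFF support: uncompressed, little-endian, grayscale,
# one strip per page, 16-bit unsigned (raw data) or 32-bit float
# (reconstructions), multipage, with an ImageDescription JSON metadata
# string per page. No R TIFF package exists in the target environment,
# so the subset of the format the instrument model needs is implemented
# here and cross-validated against Python tifffile in the test suite.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write a multipage TIFF stack
#'
#' @param images list of numeric matrices (or a single matrix).
#' @param path output file.
#' @param bits 16 (unsigned integer) or 32 (IEEE float).
#' @param descriptions optional character vector, one JSON/text metadata
#'   string per page (stored as ImageDescription).
#' @return invisible `path`.
#' @export
write_tiff <- function(images, path, bits = 16L, descriptions = NULL) {
  if (is.matrix(images)) images <- list(images)
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L))), con)   # header, magic 42 LE
  writeBin(uint32_le(8L), con)                            # first IFD offset
  offset <- 8
  n <- length(images)
  for (i in seq_len(n)) {
    img <- images[[i]]
    h <- nrow(img); w <- ncol(img)
    desc <- if (!is.null(descriptions)) {
      d <- charToRaw(descriptions[i])
      if (length(d) %% 2 == 1) d <- c(d, as.raw(0)) else c(d, as.raw(c(0, 0)))
    } else NULL
    nd <- length(desc)
    ntags <- 10L + (!is.null(desc))
    ifd_len <- 2 + 12 * ntags + 4
    data_off <- offset + ifd_len + nd
    nbytes <- h * w * (bits / 8)
    entry <- function(tag, type, count, value)
      c(uint16_le(tag), uint16_le(type), uint32_le(count), value)
    entries <- list(
      entry(256L, 3L, 1L, c(uint16_le(w), uint16_le(0L))),
      entry(257L, 3L, 1L, c(uint16_le(h), uint16_le(0L))),
      entry(258L, 3L, 1L, c(uint16_le(bits), uint16_le(0L))),
      entry(259L, 3L, 1L, c(uint16_le(1L), uint16_le(0L))),   # none
      entry(262L, 3L, 1L, c(uint16_le(1L), uint16_le(0L))))   # BlackIsZero
    if (!is.null(desc))
      entries <- c(entries, list(entry(270L, 2L, nd, uint32_le_num(offset + ifd_len))))
    entries <- c(entries, list(
      entry(273L, 4L, 1L, uint32_le_num(data_off)),
      entry(277L, 3L, 1L, c(uint16_le(1L), uint16_le(0L))),
      entry(278L, 3L, 1L, c(uint16_le(h), uint16_le(0L))),
      entry(279L, 4L, 1L, uint32_le_num(nbytes)),
      entry(339L, 3L, 1L, c(uint16_le(if (bits == 32L) 3L else 1L),
                            uint16_le(0L)))))
    next_ifd <- if (i < n) data_off + nbytes else 0
    writeBin(uint16_le(ntags), con)
    for (e in entries) writeBin(e, con)
    writeBin(uint32_le_num(next_ifd), con)
    if (!is.null(desc)) writeBin(desc, con)
    v <- as.vector(t(img))                                  # row-major
    if (bits == 16L) {
      if (any(v < 0) || any(v > 65535)) stop("values outside unsigned 16-bit range")
      writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    }
    offset <- data_off + nbytes
  }
  invisible(path)
}

#' Read a multipage TIFF stack
#'
#' Supports the baseline subset this package writes (uncompressed
#' little-endian grayscale, 8/16-bit unsigned or 32-bit float, one or
#' more strips per page).
#'
#' @param path TIFF file.
#' @return list with `images` (list of matrices) and `descriptions`
#'   (character, NA where absent).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot open TIFF file '%s'", path))
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 8) stop("not a TIFF file")
  if (!identical(bytes[1:2], charToRaw("II")))
    stop("only little-endian TIFF supported")
  if (rd_uint16(bytes[3:4]) != 42L) stop("bad TIFF magic")
  ifd_off <- rd_uint32(bytes[5:8])
  images <- list(); descriptions <- character(0)
  while (ifd_off != 0) {
    ntags <- rd_uint16(bytes[ifd_off + 1:2])
    tags <- list()
    for (t in seq_len(ntags)) {
      base <- ifd_off + 2 + 12 * (t - 1)
      tag <- rd_uint16(bytes[base + 1:2])
      type <- rd_uint16(bytes[base + 3:4])
      count <- rd_uint32(bytes[base + 5:8])
      valraw <- bytes[base + 9:12]
      size <- c(1, 1, 2, 4, 8, 1, 1, 1, 4, 8, 4, 8)[type]
      inline <- size * count <= 4
      val <- if (type == 3L && inline) {
        vapply(seq_len(count), function(j) rd_uint16(valraw[(2 * j - 1):(2 * j)]), 0)
      } else if (type == 4L && inline) {
        rd_uint32(valraw)
      } else {
        off <- rd_uint32(valraw)
        if (type == 2L) {
          rawToChar(bytes[off + seq_len(count - 1)])
        } else if (type == 3L) {
          vapply(seq_len(count), function(j)
            rd_uint16(bytes[off + (2 * j - 1):(2 * j)]), 0)
        } else {
          vapply(seq_len(count), function(j)
            rd_uint32(bytes[off + (4 * j - 3):(4 * j)]), 0)
        }
      }
      tags[[as.character(tag)]] <- val
    }
    need <- function(id) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) stop(sprintf("missing required TIFF tag %d", id))
      v
    }
    w <- need(256L); h <- need(257L)
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    if (!is.null(tags[["259"]]) && tags[["259"]][1] != 1L)
      stop("compressed TIFF not supported")
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    offs <- need(273L); counts <- need(279L)
    buf <- raw(sum(counts))
    pos <- 0
    for (s in seq_along(offs)) {
      buf[pos + seq_len(counts[s])] <- bytes[offs[s] + seq_len(counts[s])]
      pos <- pos + counts[s]
    }
    v <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "numeric", n = w * h, size = 4L, endian = "little")
    } else if (bits == 16L) {
      readBin(buf, "integer", n = w * h, size = 2L, signed = FALSE,
              endian = "little")
    } else if (bits == 8L) {
      as.integer(buf[seq_len(w * h)])
    } else stop(sprintf("unsupported TIFF sample: %d bits format %d", bits, fmt))
    images[[length(images) + 1L]] <- matrix(v, h, w, byrow = TRUE)
    desc <- tags[["270"]]
    descriptions <- c(descriptions, if (is.null(desc)) NA_character_ else desc)
    ifd_off <- rd_uint32(bytes[ifd_off + 2 + 12 * ntags + 1:4])
  }
  list(images = images, descriptions = descriptions)
}

#' Read a multipage raw stack as SIM sets
#'
#' The page count must be a multiple of 9 per channel; page metadata
#' (ImageDescription JSON with channel/angle/phase/timestamp) written by
#' [write_raw_stack()] is used when present, otherwise supplied defaults
#' apply and pages are taken in angle-major order.
#'
#' @param path TIFF file from [write_raw_stack()] (or any compatible
#'   multipage 16-bit file).
#' @param channel_id,exposure_ms fallbacks when pages carry no metadata.
#' @return list of [raw_sim_set()].
#' @export
read_raw_stack <- function(path, channel_id = 1L, exposure_ms = 1) {
  tf <- read_tiff(path)
  n <- length(tf$images)
  if (n == 0 || n %% 9 != 0)
    stop(sprintf("page count %d is not a multiple of 9", n))
  meta <- lapply(tf$descriptions, function(d) {
    if (is.na(d)) NULL else tryCatch(jsonlite::fromJSON(d), error = function(e) NULL)
  })
  lapply(seq_len(n / 9), function(s) {
    idx <- (9 * (s - 1) + 1):(9 * s)
    m1 <- meta[[idx[1]]]
    ts <- vapply(idx, function(i)
      if (!is.null(meta[[i]]$timestamp_ns)) as.numeric(meta[[i]]$timestamp_ns)
      else NA_real_, 0)
    if (any(is.na(ts))) ts <- as.numeric(idx - 1)
    raw_sim_set(tf$images[idx],
                channel_id = if (!is.null(m1$channel_id)) m1$channel_id else channel_id,
                exposure_ms = if (!is.null(m1$exposure_ms)) m1$exposure_ms else exposure_ms,
                timestamps_ns = ts)
  })
}

#' Write raw SIM sets to a multipage 16-bit TIFF
#'
#' Pages are angle-major within each set; each page's ImageDescription
#' holds JSON metadata (channel, angle, phase, sequence and timestamp),
#' so the file round-trips losslessly through [read_raw_stack()].
#'
#' @param sets a [raw_sim_set()] or list of them (one channel).
#' @param path output file.
#' @return invisible `path`.
#' @export
write_raw_stack <- function(sets, path) {
  if (inherits(sets, "raw_sim_set")) sets <- list(sets)
  images <- list(); desc <- character(0)
  for (s in seq_along(sets)) {
    set <- sets[[s]]
    for (i in 1:9) {
      images[[length(images) + 1L]] <- set$frames[[i]]
      desc <- c(desc, jsonlite::toJSON(list(
        channel_id = set$channel_id, set_index = s - 1L,
        angle_index = (i - 1L) %/% 3L, phase_index = (i - 1L) %% 3L,
        exposure_ms = set$exposure_ms,
        timestamp_ns = set$timestamps_ns[i]), auto_unbox = TRUE, digits = NA))
    }
  }
  write_tiff(images, path, bits = 16L, descriptions = desc)
}

#' Write a reconstruction (and optional wide-field) as 32-bit float TIFF
#'
#' @param recon a [reconstruct_set()] result or a matrix.
#' @param path output file.
#' @param meta named list stored as JSON in the ImageDescription.
#' @param include_widefield also append the wide-field page (for a
#'   `reconstruct_set` result).
#' @return invisible `path`.
#' @export
write_reconstruction <- function(recon, path, meta = list(),
                                 include_widefield = FALSE) {
  imgs <- if (is.matrix(recon)) list(recon) else {
    c(list(recon$sim), if (include_widefield) list(recon$widefield))
  }
  desc <- vapply(seq_along(imgs), function(i) {
    m <- c(meta, list(page = if (i == 1) "sim" else "widefield"))
    as.character(jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA))
  }, "")
  write_tiff(imgs, path, bits = 32L, descriptions = desc)
}
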
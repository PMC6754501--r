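# Wire protocol for raw-frame transfer: fixed little-endian header +
# row-major uint16 payload (2 bytes per pixel), so a frame crosses the
# network exactly as the camera delivers it.
#
# Header layout (all little-endian):
#   bytes 1-4   magic "SIMF"
#   byte  5     version (1)
#   bytes 6-9   width  (uint32)
#   bytes 10-13 height (uint32)
#   bytes 14-15 channel_id (uint16)
#   bytes 16-19 sequence_index (uint32)
#   byte  20    angle_index (0-2)
#   byte  21    phase_index (0-2)
#   bytes 22-29 timestamp_ns (uint64, carried as R double; exact < 2^53)
#   payload     width*height uint16, row-major

WIRE_MAGIC <- charToRaw("SIMF")
WIRE_VERSION <- 1L
WIRE_HEADER_BYTES <- 29L

#' Encode a raw frame as a wire message
#'
#' @param image integer/numeric matrix with values in `[0, 65535]`.
#' @param channel_id,sequence_index,angle_index,phase_index frame
#'   bookkeeping (0-based indices for sequence/angle/phase).
#' @param timestamp_ns acquisition timestamp in ns (numeric; must be a
#'   non-negative integer value below 2^53).
#' @return raw vector (header + payload).
#' @export
encode_frame_message <- function(image, channel_id = 1L, sequence_index = 0L,
                                 angle_index = 0L, phase_index = 0L,
                                 timestamp_ns = 0) {
  v <- as.vector(t(image))                   # row-major
  if (any(v < 0) || any(v > 65535)) stop("pixels must fit unsigned 16-bit")
  header <- c(WIRE_MAGIC,
              as.raw(WIRE_VERSION),
              uint32_le(ncol(image)), uint32_le(nrow(image)),
              uint16_le(channel_id),
              uint32_le(sequence_index),
              as.raw(angle_index), as.raw(phase_index),
              uint64_le(timestamp_ns))
  payload <- writeBin(as.integer(round(v)), raw(), size = 2L,
                      endian = "little", useBytes = TRUE)
  c(header, payload)
}

#' Decode a wire message back to a frame
#'
#' Exact inverse of [encode_frame_message()]; corrupted magic, an
#' unsupported version or a truncated payload raise errors.
#'
#' @param bytes raw vector.
#' @return list: `image` (integer matrix), `channel_id`,
#'   `sequence_index`, `angle_index`, `phase_index`, `timestamp_ns`.
#' @export
decode_frame_message <- function(bytes) {
  if (length(bytes) < WIRE_HEADER_BYTES) stop("message shorter than header")
  if (!identical(bytes[1:4], WIRE_MAGIC)) stop("bad magic")
  version <- as.integer(bytes[5])
  if (version != WIRE_VERSION) stop(sprintf("unsupported version %d", version))
  width <- rd_uint32(bytes[6:9]); height <- rd_uint32(bytes[10:13])
  channel <- rd_uint16(bytes[14:15])
  seqi <- rd_uint32(bytes[16:19])
  ai <- as.integer(bytes[20]); pi_ <- as.integer(bytes[21])
  ts <- rd_uint64(bytes[22:29])
  need <- 2 * width * height
  if (length(bytes) - WIRE_HEADER_BYTES != need)
    stop(sprintf("payload length mismatch: have %d bytes, need %d",
                 length(bytes) - WIRE_HEADER_BYTES, need))
  px <- readBin(bytes[-(1:WIRE_HEADER_BYTES)], "integer", n = width * height,
                size = 2L, signed = FALSE, endian = "little")
  list(image = matrix(px, height, width, byrow = TRUE),
       channel_id = channel, sequence_index = seqi,
       angle_index = ai, phase_index = pi_, timestamp_ns = ts)
}

#' @noRd
uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

#' @noRd
uint32_le <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

#' @noRd
uint64_le <- function(x) {
  x <- round(as.numeric(x))   # ns values arrive as doubles; keep whole ns
  if (x < 0 || x >= 2^53) stop("timestamp must be an integer in [0, 2^53)")
  lo <- x %% 2^32
  hi <- (x - lo) / 2^32
  c(uint32_le_num(lo), uint32_le_num(hi))
}

# writeBin on a value >= 2^31 overflows int; assemble bytes manually
#' @noRd
uint32_le_num <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

#' @noRd
rd_uint16 <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])

#' @noRd
rd_uint32 <- function(b) sum(as.numeric(b) * c(1, 256, 65536, 16777216))

#' @noRd
rd_uint64 <- function(b) rd_uint32(b[1:4]) + 2^32 * rd_uint32(b[5:8])

#' Frame a message for a byte stream and read it back
#'
#' Stream transport prefixes each message with its uint32 length so
#' multiple messages (possibly split across several TCP links and
#' reassembled by sequence index) can share one connection.
#'
#' @param con a binary connection.
#' @param bytes message from [encode_frame_message()].
#' @return `read_framed_message` returns the raw message or NULL at end
#'   of stream.
#' @export
write_framed_message <- function(con, bytes) {
  writeBin(uint32_le(length(bytes)), con)
  writeBin(bytes, con)
  invisible(TRUE)
}

#' @rdname write_framed_message
#' @export
read_framed_message <- function(con) {
  lenb <- readBin(con, "raw", 4L)
  if (length(lenb) < 4L) return(NULL)
  n <- rd_uint32(lenb)
  out <- raw(0)
  tries <- 0L
  while (length(out) < n) {
    chunk <- readBin(con, "raw", n - length(out))
    if (!length(chunk)) {
      tries <- tries + 1L
      if (tries > 2000L) stop("stream ended inside a framed message")
      Sys.sleep(0.005)
      next
    }
    tries <- 0L
    out <- c(out, chunk)
  }
  out
}
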
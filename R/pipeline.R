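#' Stateful grouping of a frame stream into raw SIM sets
#'
#' Collects decoded frame messages per channel and emits a complete
#' 9-frame set whenever 9 consecutive sequence indices complete one
#' 3-angle x 3-phase cycle starting at angle 0 / phase 0. A gap in the
#' sequence numbering discards the affected partial set (counted, never
#' forwarded): reconstruction only ever sees complete sets.
#'
#' @return a `frame_grouper` environment; feed messages with
#'   [grouper_feed()] and read `grouper_stats()`.
#' @export
frame_grouper <- function() {
  env <- new.env(parent = emptyenv())
  env$channels <- list()
  env$discarded_sets <- 0L
  env$frames_in_partial <- 0L
  class(env) <- "frame_grouper"
  env
}

#' @rdname frame_grouper
#' @param grouper a [frame_grouper()].
#' @param msg decoded message (list with `image`, `channel_id`,
#'   `sequence_index`, `angle_index`, `phase_index`, `timestamp_ns`).
#' @return a [raw_sim_set()] when `msg` completes one, else `NULL`.
#' @export
grouper_feed <- function(grouper, msg) {
  key <- as.character(msg$channel_id)
  st <- grouper$channels[[key]]
  if (is.null(st)) st <- list(frames = list(), ts = numeric(0), last_seq = NA)
  pos_in_set <- msg$sequence_index %% 9L
  expected_pos <- 3L * msg$angle_index + msg$phase_index
  gap <- !is.na(st$last_seq) && msg$sequence_index != st$last_seq + 1L
  if (gap || pos_in_set != expected_pos) {
    if (length(st$frames) > 0) {
      grouper$discarded_sets <- grouper$discarded_sets + 1L
      grouper$frames_in_partial <- grouper$frames_in_partial + length(st$frames)
      st$frames <- list(); st$ts <- numeric(0)
    }
  }
  st$last_seq <- msg$sequence_index
  if (pos_in_set == 0L) { st$frames <- list(); st$ts <- numeric(0) }
  if (pos_in_set == length(st$frames)) {
    st$frames[[pos_in_set + 1L]] <- msg$image
    st$ts <- c(st$ts, msg$timestamp_ns)
  } else if (pos_in_set != 0L) {
    # mid-set frame without a started set: orphan, counts as partial
    grouper$frames_in_partial <- grouper$frames_in_partial + 1L
    grouper$channels[[key]] <- st
    return(NULL)
  }
  out <- NULL
  if (length(st$frames) == 9L) {
    out <- raw_sim_set(st$frames, channel_id = msg$channel_id,
                       exposure_ms = NA_real_, timestamps_ns = st$ts)
    st$frames <- list(); st$ts <- numeric(0)
  }
  grouper$channels[[key]] <- st
  out
}

#' @rdname frame_grouper
#' @export
grouper_stats <- function(grouper) {
  pending <- sum(vapply(grouper$channels, function(s) length(s$frames), 0L))
  list(discarded_sets = grouper$discarded_sets,
       frames_in_partial = grouper$frames_in_partial,
       frames_pending = pending)
}

#' Run the live reconstruction pipeline over a frame stream
#'
#' The real-time path of the instrument model: decode each incoming
#' frame message, group into 9-frame sets per channel, cache sets in a
#' per-channel ring buffer (drops whole sets under backlog, never
#' blocks the producer), reconstruct, optionally register channels onto
#' the reference channel, and hand results to a sink. Latency per set is
#' reported as sink time minus last-raw-frame timestamp using an
#' injectable clock (deterministic in tests). Optionally archives all
#' raw frames per channel to multipage TIFF for offline reprocessing.
#'
#' @param source list of encoded messages (raw vectors), list of decoded
#'   frame records, or a connection carrying framed messages.
#' @param params [illumination_params()] or list of them per channel;
#'   `NULL` refuses to start (run [fit_channel_params()] first).
#' @param otf [otf_model()] or per-channel list.
#' @param settings a [recon_settings()].
#' @param sink function(result) called per reconstructed set; result has
#'   `channel_id`, `sim`, `widefield`, `timestamp_ns`, `latency_ns`.
#' @param capacity ring-buffer capacity per channel, in sets.
#' @param registration optional list of `registration_transform` (or
#'   2 x 3 matrices) per channel; applied to the reconstructions.
#' @param consume_every consumer cadence: pop one set after every this
#'   many incoming messages (large values emulate a slow consumer and
#'   force backlog); remaining sets are drained at stream end.
#' @param clock function returning the current time in ns.
#' @param archive_dir if set, raw frames are archived per channel as
#'   16-bit multipage TIFF under this directory.
#' @return list: `n_reconstructed`, `drops` (sets evicted from ring
#'   buffers), `grouping` (see [grouper_stats()]), `latency_ns` vector,
#'   `archive_files`.
#' @export
run_live_pipeline <- function(source, params, otf,
                              settings = recon_settings(), sink = NULL,
                              capacity = 8L, registration = NULL,
                              consume_every = 1L,
                              clock = function() as.numeric(Sys.time()) * 1e9,
                              archive_dir = NULL) {
  if (is.null(params))
    stop("no illumination parameters: run fit_channel_params() (or load a parameter file) before starting the live pipeline")
  if (inherits(params, "illum_params")) params <- list(params)
  if (inherits(otf, "otf_model")) otf <- rep(list(otf), length(params))
  grouper <- frame_grouper()
  rings <- list()
  filters <- list()
  latency <- numeric(0)
  results <- 0L
  archive <- list()
  msg_count <- 0L
  process_one <- function() {
    for (key in names(rings)) {
      set <- ring_pop(rings[[key]])
      if (is_ring_empty(set)) next
      ch <- set$channel_id
      pr <- params[[min(ch, length(params))]]
      ot <- otf[[min(ch, length(otf))]]
      fkey <- as.character(ch)
      if (is.null(filters[[fkey]]))
        filters[[fkey]] <<- precompute_filters(pr, ot, settings)
      rec <- recon_with_filters(set, pr, ot, settings, filters[[fkey]])
      if (!is.null(registration) && !is.null(registration[[ch]])) {
        tr <- registration[[ch]]
        trm <- if (inherits(tr, "registration_transform")) tr$matrix else tr
        # reconstruction grid is 2x finer: same linear part, doubled shift
        trs <- cbind(trm[, 1:2], 2 * trm[, 3])
        rec$sim <- warp_affine(rec$sim, trs)
        rec$widefield <- warp_affine(rec$widefield, trm)
      }
      lat <- clock() - set$timestamps_ns[9]
      latency <<- c(latency, lat)
      results <<- results + 1L
      if (!is.null(sink))
        sink(list(channel_id = ch, sim = rec$sim, widefield = rec$widefield,
                  timestamp_ns = set$timestamps_ns[1], latency_ns = lat))
      return(invisible(TRUE))
    }
    invisible(FALSE)
  }
  handle_msg <- function(msg) {
    if (is.raw(msg)) msg <- decode_frame_message(msg)
    msg_count <<- msg_count + 1L
    key <- as.character(msg$channel_id)
    if (is.null(rings[[key]])) rings[[key]] <<- ring_buffer(capacity)
    if (!is.null(archive_dir)) {
      if (is.null(archive[[key]])) archive[[key]] <<- list()
      archive[[key]][[length(archive[[key]]) + 1L]] <<- msg$image
    }
    set <- grouper_feed(grouper, msg)
    if (!is.null(set)) ring_push(rings[[key]], set)
    if (msg_count %% consume_every == 0L) process_one()
  }
  if (inherits(source, "connection")) {
    repeat {
      bytes <- read_framed_message(source)
      if (is.null(bytes)) break
      handle_msg(bytes)
    }
  } else {
    for (msg in source) handle_msg(msg)
  }
  while (process_one()) NULL                  # drain; never deadlocks
  drops <- sum(vapply(rings, function(r) r$drop_count, 0L))
  files <- character(0)
  if (!is.null(archive_dir)) {
    dir.create(archive_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(archive)) {
      f <- file.path(archive_dir, sprintf("raw_channel_%s.tif", key))
      write_tiff(archive[[key]], f, bits = 16L)
      files <- c(files, f)
    }
  }
  list(n_reconstructed = results, drops = drops,
       grouping = grouper_stats(grouper), latency_ns = latency,
       archive_files = files)
}

#' Serve a synthetic frame stream over TCP
#'
#' Writes the encoded messages of [simulate_multichannel_sequence()] (or
#' any list of encoded/decodable messages) to a socket as length-framed
#' wire messages; the counterpart of consuming a connection in
#' [run_live_pipeline()].
#'
#' @param messages list of frame records or raw messages.
#' @param con a binary connection (e.g. an accepted socket).
#' @return number of messages written.
#' @export
serve_frame_stream <- function(messages, con) {
  n <- 0L
  for (msg in messages) {
    bytes <- if (is.raw(msg)) msg else
      encode_frame_message(msg$image, msg$channel_id, msg$sequence_index,
                           msg$angle_index, msg$phase_index, msg$timestamp_ns)
    write_framed_message(con, bytes)
    n <- n + 1L
  }
  flush(con)
  n
}
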
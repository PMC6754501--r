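#' Fixed-capacity ring buffer with overwrite-oldest policy
#'
#' Decouples the acquisition (producer) from the reconstruction
#' (consumer): pushes never block, and under backlog the oldest entry is
#' evicted and counted, so short reconstruction delays drop old frame
#' sets instead of stalling the camera stream. FIFO order; conservation
#' invariant `pushed = popped + dropped + occupancy` holds at all times.
#'
#' @param capacity maximum number of stored items (>= 1).
#' @return object of class `ring_buffer` (mutable environment).
#' @export
ring_buffer <- function(capacity) {
  capacity <- as.integer(capacity)
  if (capacity < 1L) stop("capacity must be at least 1")
  env <- new.env(parent = emptyenv())
  env$items <- vector("list", capacity)
  env$capacity <- capacity
  env$head <- 0L      # next slot to pop (0-based)
  env$count <- 0L
  env$pushed <- 0L
  env$popped <- 0L
  env$drop_count <- 0L
  class(env) <- "ring_buffer"
  env
}

#' @rdname ring_buffer
#' @param buf a `ring_buffer`.
#' @param item any R object.
#' @return `ring_push` returns `TRUE` if stored without eviction,
#'   `FALSE` if the oldest item was evicted.
#' @export
ring_push <- function(buf, item) {
  stopifnot(inherits(buf, "ring_buffer"))
  buf$pushed <- buf$pushed + 1L
  evicted <- FALSE
  if (buf$count == buf$capacity) {
    buf$head <- (buf$head + 1L) %% buf$capacity   # evict oldest
    buf$count <- buf$count - 1L
    buf$drop_count <- buf$drop_count + 1L
    evicted <- TRUE
  }
  slot <- (buf$head + buf$count) %% buf$capacity
  buf$items[[slot + 1L]] <- item
  buf$count <- buf$count + 1L
  !evicted
}

#' @rdname ring_buffer
#' @return `ring_pop` returns the oldest item, or the sentinel
#'   `ring_empty()` when the buffer holds nothing.
#' @export
ring_pop <- function(buf) {
  stopifnot(inherits(buf, "ring_buffer"))
  if (buf$count == 0L) return(ring_empty())
  item <- buf$items[[buf$head + 1L]]
  buf$items[buf$head + 1L] <- list(NULL)
  buf$head <- (buf$head + 1L) %% buf$capacity
  buf$count <- buf$count - 1L
  buf$popped <- buf$popped + 1L
  item
}

#' @rdname ring_buffer
#' @export
ring_empty <- function() structure(list(), class = "ring_empty")

#' @rdname ring_buffer
#' @param x object to test.
#' @export
is_ring_empty <- function(x) inherits(x, "ring_empty")

#' @rdname ring_buffer
#' @export
ring_stats <- function(buf) {
  list(capacity = buf$capacity, occupancy = buf$count,
       pushed = buf$pushed, popped = buf$popped,
       drop_count = buf$drop_count)
}

#' @export
format.ring_buffer <- function(x, ...) {
  sprintf("ring buffer %d/%d (pushed %d, popped %d, dropped %d)",
          x$count, x$capacity, x$pushed, x$popped, x$drop_count)
}

#' @export
print.ring_buffer <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
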
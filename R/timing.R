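#' Acquisition timing configuration
#'
#' Component times of the fast SIM instrument model. Defaults are the
#' printed hardware constants: the ferroelectric SLM needs 0.44 ms to
#' switch patterns, and the sCMOS readout requires delaying the SLM
#' sequence by 0.85 ms (256-line ROI) or 2.1 ms (512 lines); between
#' those anchors the delay is interpolated linearly in lines and below
#' them extrapolated, never below zero (a ROI of ~80 lines or fewer reads
#' out within the SLM switch itself).
#'
#' @param exposure_ms exposure per raw frame, per channel (scalar or one
#'   value per channel), ms.
#' @param n_channels number of simultaneously imaged color channels, 1-3.
#' @param roi_lines number of sensor lines read out.
#' @param slm_switch_ms SLM pattern switch time, ms.
#' @param pixel_size_um projected pixel size, µm.
#' @param interframe_delay_ms extra delay between SIM acquisitions
#'   (time-lapse), ms.
#' @param overhead_ms additional per-raw-frame overhead for calibrating
#'   the model against a measured instrument; default 0.
#' @return object of class `timing_config`.
#' @export
timing_config <- function(exposure_ms = 1, n_channels = 1L, roi_lines = 512L,
                          slm_switch_ms = 0.44, pixel_size_um = 0.08,
                          interframe_delay_ms = 0, overhead_ms = 0) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L || n_channels > 3L) stop("n_channels must be 1-3")
  exposure_ms <- rep_len(exposure_ms, n_channels)
  if (any(exposure_ms < 0) || slm_switch_ms < 0 || interframe_delay_ms < 0 ||
      overhead_ms < 0)
    stop("times must be non-negative")
  if (all(exposure_ms == 0) && slm_switch_ms == 0)
    stop("degenerate timing: zero exposure and zero SLM switch")
  if (roi_lines < 1L || roi_lines > 2160L) stop("roi_lines outside supported range")
  structure(list(exposure_ms = exposure_ms, n_channels = n_channels,
                 roi_lines = as.integer(roi_lines),
                 slm_switch_ms = slm_switch_ms,
                 pixel_size_um = pixel_size_um,
                 interframe_delay_ms = interframe_delay_ms,
                 overhead_ms = overhead_ms),
            class = "timing_config")
}

# Camera readout delay in ms for a ROI height, interpolated between the
# printed anchors (256 -> 0.85 ms, 512 -> 2.1 ms), clamped at 0 below
# ~80 lines where readout hides inside the SLM switch.
#' @noRd
readout_delay_ms <- function(lines) {
  d <- 0.85 + (lines - 256) * (2.1 - 0.85) / 256
  pmax(d, 0)
}

#' Plan an interleaved SIM acquisition cycle
#'
#' Builds the event schedule and achievable frame rates for one SIM frame
#' (9 raw frames per channel: 3 pattern angles x 3 phases, angle-major).
#' Single channel: each raw frame takes `exposure + slm_switch + readout`.
#' Multiple channels: the channels' raw frames are interleaved round-robin
#' in slots of `exposure + slm_switch`; a camera reads out while the other
#' channels expose, and a per-slot wait is added only if the readout does
#' not finish before that camera's next exposure slot.
#'
#' @param config a [timing_config()].
#' @return object of class `timing_plan`: `events` data frame
#'   (`t_start`, `t_end`, `device`, `state`), `sim_fps` (exact),
#'   `sim_fps_int` (floored, as printed), `raw_fps`, `cycle_ms`,
#'   `duty_cycle` per channel, `feasible`, and the `config`.
#' @export
plan_acquisition <- function(config) {
  stopifnot(inherits(config, "timing_config"))
  nch <- config$n_channels
  s <- config$slm_switch_ms + config$overhead_ms
  r <- readout_delay_ms(config$roi_lines)
  if (nch == 1L) {
    slot <- config$exposure_ms[1] + s + r
    wait <- 0
  } else {
    slot0 <- max(config$exposure_ms) + s
    # time from end of a channel's exposure to its next exposure start
    avail <- s + (nch - 1) * slot0
    wait <- max(0, (r - avail) / nch)
    slot <- slot0 + wait
  }
  cycle <- 9 * nch * slot + config$interframe_delay_ms
  sim_fps <- 1000 / cycle
  events <- build_events(config, slot, s, r)
  duty <- 9 * config$exposure_ms / cycle
  structure(list(events = events, sim_fps = sim_fps,
                 sim_fps_int = as.integer(floor(sim_fps)),
                 raw_fps = 9 * nch * sim_fps,
                 cycle_ms = cycle, slot_ms = slot, duty_cycle = duty,
                 feasible = TRUE, config = config),
            class = "timing_plan")
}

#' @noRd
build_events <- function(config, slot, s, r) {
  nch <- config$n_channels
  ev <- list()
  t <- 0
  for (frame in 0:(9L - 1L)) {
    for (ch in seq_len(nch)) {
      e <- config$exposure_ms[ch]
      ev[[length(ev) + 1L]] <- data.frame(
        t_start = c(t, t, t, t + e),
        t_end = c(t + e, t + e, t + e, t + e + min(s, slot - e)),
        device = c(sprintf("camera_%d", ch), sprintf("laser_%d", ch), "SLM", "SLM"),
        state = c("expose", "on", "expose", "switch"))
      ev[[length(ev) + 1L]] <- data.frame(
        t_start = t + e, t_end = t + e + r,
        device = sprintf("camera_%d", ch), state = "readout")
      t <- t + slot
    }
  }
  do.call(rbind, ev)
}

#' Field-of-view extent of a ROI
#'
#' @param lines number of sensor lines (>= 1).
#' @param pixel_size_um projected pixel size, µm.
#' @return field height in µm (`lines * pixel_size_um`).
#' @examples fov_extent(80, 0.08)  # 6.4 µm
#' @export
fov_extent <- function(lines, pixel_size_um = 0.08) {
  if (any(lines < 1) || any(pixel_size_um <= 0)) stop("nonpositive input")
  lines * pixel_size_um
}

#' Timestamps for a planned acquisition
#'
#' Per-raw-frame start times and per-SIM-frame completion times in
#' nanoseconds from `t0_ns`, strictly increasing.
#'
#' @param plan a feasible [plan_acquisition()] result.
#' @param n_sim_frames number of SIM frames.
#' @param t0_ns start time, ns.
#' @return list with `raw_ns` (matrix, one row per raw frame slot and
#'   columns per channel) and `sim_ns`.
#' @export
timestamp_series <- function(plan, n_sim_frames, t0_ns = 0) {
  stopifnot(inherits(plan, "timing_plan"), isTRUE(plan$feasible))
  nch <- plan$config$n_channels
  slot <- plan$slot_ms
  raw <- matrix(0, 9L * n_sim_frames, nch)
  k <- 0L
  for (f in seq_len(n_sim_frames)) {
    base <- t0_ns + (f - 1) * plan$cycle_ms * 1e6
    for (i in 0:8) for (ch in seq_len(nch))
      raw[(f - 1) * 9 + i + 1, ch] <- base + ((i * nch) + (ch - 1)) * slot * 1e6
  }
  sim <- t0_ns + seq_len(n_sim_frames) * plan$cycle_ms * 1e6
  list(raw_ns = raw, sim_ns = sim)
}

#' Time span of a frame series
#'
#' @param n_frames number of SIM frames.
#' @param sim_fps SIM frame rate (frames/s).
#' @return `n_frames / sim_fps` in seconds.
#' @examples span_seconds(107, 57.8)  # ~1.85 s
#' @export
span_seconds <- function(n_frames, sim_fps) {
  if (sim_fps <= 0) stop("sim_fps must be positive")
  n_frames / sim_fps
}

#' Frame-rate table over acquisition settings
#'
#' Applies [plan_acquisition()] over a grid of exposure times, channel
#' counts and ROI sizes, and tabulates the integer (floored) SIM frame
#' rates and duty cycles.
#'
#' @param exposures_ms exposure times, ms.
#' @param channels channel counts, each 1-3.
#' @param roi_lines ROI heights in lines.
#' @return data frame with columns `exposure_ms`, `channels`, `roi_lines`,
#'   `fov_um`, `sim_fps_int`, `sim_fps`, `duty_cycle`.
#' @export
frame_rate_table <- function(exposures_ms = c(0.5, 1, 2, 5, 10),
                             channels = 1:3,
                             roi_lines = c(256L, 512L)) {
  if (!length(exposures_ms) || !length(channels) || !length(roi_lines))
    stop("empty grid")
  g <- expand.grid(exposure_ms = exposures_ms, channels = channels,
                   roi_lines = roi_lines)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    p <- plan_acquisition(timing_config(exposure_ms = g$exposure_ms[i],
                                        n_channels = g$channels[i],
                                        roi_lines = g$roi_lines[i]))
    data.frame(exposure_ms = g$exposure_ms[i], channels = g$channels[i],
               roi_lines = g$roi_lines[i],
               fov_um = fov_extent(g$roi_lines[i], p$config$pixel_size_um),
               sim_fps_int = p$sim_fps_int, sim_fps = p$sim_fps,
               duty_cycle = p$duty_cycle[1])
  })
  do.call(rbind, rows)
}

#' @export
format.timing_plan <- function(x, ...) {
  sprintf("SIM timing plan: %d channel(s), cycle %.3f ms, %.2f SIM fps (%d), duty %.1f%%",
          x$config$n_channels, x$cycle_ms, x$sim_fps, x$sim_fps_int,
          100 * x$duty_cycle[1])
}

#' @export
print.timing_plan <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
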
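#' Illumination parameter set
#'
#' The per-angle description of the sinusoidal two-beam illumination:
#' pattern wave vector `p` (cycles/µm), starting phase of the first frame
#' of each angle (radians), the fixed phase step of 2π/3 between the
#' three frames of an angle, and the modulation depth `m` of the pattern.
#'
#' @param p 3 x 2 matrix of pattern wave vectors (cycles/µm), one row per
#'   angle.
#' @param start_phase numeric length 3, radians.
#' @param modulation pattern modulation depth in (0, 1].
#' @param cutoff optional detection cutoff (cycles/µm); when given,
#'   `|p| < cutoff` is enforced.
#' @param angle_sep_tol_deg tolerance on the nominal 60° angular spacing
#'   of the three pattern orientations.
#' @param scores optional per-angle estimation quality scores.
#' @return object of class `illum_params`.
#' @export
illumination_params <- function(p, start_phase = c(0, 0, 0), modulation = 1,
                                cutoff = NULL, angle_sep_tol_deg = 10,
                                scores = NULL) {
  p <- as.matrix(p)
  if (nrow(p) != 3 || ncol(p) != 2) stop("p must be a 3 x 2 matrix (3 angles)")
  if (length(start_phase) != 3) stop("start_phase must have length 3")
  if (modulation <= 0 || modulation > 1.5) stop("modulation must be in (0, 1.5]")
  if (!is.null(cutoff) && any(sqrt(rowSums(p^2)) >= cutoff))
    stop("pattern frequency |p| must be below the detection cutoff")
  th <- atan2(p[, 2], p[, 1]) * 180 / pi
  sep <- abs(((diff(th[c(1, 2, 3, 1)]) + 90) %% 180) - 90)
  if (any(abs(sep - 60) > angle_sep_tol_deg))
    warning(sprintf("pattern orientations deviate from 60-degree spacing by up to %.1f deg",
                    max(abs(sep - 60))))
  structure(list(p = p, start_phase = as.numeric(start_phase),
                 phase_step = 2 * pi / 3, modulation = modulation,
                 scores = scores),
            class = "illum_params")
}

#' Default illumination design for a channel
#'
#' Three pattern orientations 60° apart with `|p| = frac * k_c`, the
#' design point of the instrument model (`frac = 0.8` leaves side-band
#' overlap for background attenuation and yields a 1.8-fold support
#' extension).
#'
#' @param otf an [otf_model()].
#' @param frac pattern frequency as a fraction of the cutoff.
#' @param orientation_deg orientation of the first angle, degrees.
#' @param start_phase,modulation see [illumination_params()].
#' @export
default_illumination <- function(otf, frac = 0.8, orientation_deg = 13,
                                 start_phase = c(0, 0, 0), modulation = 1) {
  th <- (orientation_deg + c(0, 60, 120)) * pi / 180
  p <- frac * otf$cutoff * cbind(cos(th), sin(th))
  illumination_params(p, start_phase, modulation, cutoff = otf$cutoff)
}

#' Sinusoidal two-beam illumination map
#'
#' \eqn{I(r) = 1 + m \cos(2\pi p\cdot r + \phi)} evaluated at pixel
#' centres (0-based pixel coordinates times `pixel_size`). The mean over
#' an integer number of periods is 1.
#'
#' @param shape (rows, cols).
#' @param pixel_size µm.
#' @param p wave vector, length 2, cycles/µm.
#' @param phase radians.
#' @param m modulation depth in `[0, 1]`.
#' @return matrix of illumination intensities.
#' @export
sinusoidal_illumination <- function(shape, pixel_size, p, phase = 0, m = 1) {
  if (m < 0 || m > 1) stop("modulation m must lie in [0, 1]")
  x <- (0:(shape[1] - 1)) * pixel_size
  y <- (0:(shape[2] - 1)) * pixel_size
  arg <- 2 * pi * outer(p[1] * x, p[2] * y, `+`) + phase
  1 + m * cos(arg)
}

#' One channel's raw SIM frame set
#'
#' Container for the atomic reconstruction input: 9 frames ordered
#' angle-major (angle 1 phases 1-3, angle 2 phases 1-3, ...), with
#' acquisition metadata and strictly increasing per-frame timestamps.
#'
#' @param frames list of 9 numeric matrices of identical shape, values
#'   non-negative and 16-bit representable (<= 65535).
#' @param channel_id integer channel index.
#' @param exposure_ms exposure per raw frame.
#' @param timestamps_ns numeric length 9, strictly increasing.
#' @param meta free-form metadata list.
#' @export
raw_sim_set <- function(frames, channel_id = 1L, exposure_ms = 1,
                        timestamps_ns = as.numeric(0:8), meta = list()) {
  if (length(frames) != 9) stop("a raw SIM set holds exactly 9 frames")
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("frames must share one shape")
    if (any(f < 0) || any(f > 65535)) stop("frame values must be in [0, 65535]")
  }
  if (length(timestamps_ns) != 9 || any(diff(timestamps_ns) <= 0))
    stop("timestamps must be 9 strictly increasing values")
  structure(list(frames = frames, channel_id = as.integer(channel_id),
                 exposure_ms = exposure_ms, timestamps_ns = timestamps_ns,
                 meta = meta, shape = d),
            class = "raw_sim_set")
}

#' Simulate one raw SIM acquisition
#'
#' Forward model of the virtual microscope: the phantom is multiplied by
#' the sinusoidal illumination in sample space (fluorescence is
#' incoherent), blurred by the ideal OTF, scaled to photons, and passed
#' through an sCMOS-like camera: Poisson shot noise, Gaussian read noise,
#' a constant digital offset, clipping at zero and 16-bit quantization.
#' With `photons_scale = Inf` the camera is bypassed and the exact
#' noiseless floating-point frames are returned (no offset, no
#' quantization) for oracle tests.
#'
#' @param phantom a [make_phantom()] result (or plain matrix).
#' @param illum an [illumination_params()].
#' @param otf an [otf_model()] on the same grid.
#' @param photons_scale photons per unit phantom intensity, or `Inf` for
#'   noiseless mode.
#' @param read_noise_e Gaussian read noise s.d., counts.
#' @param offset camera digital baseline, counts.
#' @param seed RNG seed for the camera noise.
#' @param channel_id,exposure_ms,t0_ns metadata passed to the set.
#' @return a [raw_sim_set()]; `meta$truth` carries the simulation truth.
#' @export
simulate_raw_set <- function(phantom, illum, otf, photons_scale = Inf,
                             read_noise_e = 1.2, offset = 100, seed = 1L,
                             channel_id = 1L, exposure_ms = 1, t0_ns = 0) {
  img <- if (inherits(phantom, "phantom")) phantom$image else phantom
  if (!identical(dim(img), as.integer(otf$grid_shape)) &&
      !identical(dim(img), otf$grid_shape))
    stop("phantom and OTF grids disagree")
  if (read_noise_e < 0 || offset < 0) stop("negative noise parameters")
  noiseless <- is.infinite(photons_scale)
  set.seed(as.integer(seed))
  frames <- vector("list", 9)
  k <- 1L
  for (a in 1:3) {
    for (j in 0:2) {
      ph <- illum$start_phase[a] + j * illum$phase_step
      I <- sinusoidal_illumination(dim(img), otf$pixel_size, illum$p[a, ],
                                   ph, illum$modulation)
      em <- otf_blur(img * I, otf)
      em[em < 0] <- 0
      if (noiseless) {
        frames[[k]] <- em
      } else {
        counts <- stats::rpois(length(em), em * photons_scale) +
          stats::rnorm(length(em), 0, read_noise_e) + offset
        counts <- round(pmin(pmax(counts, 0), 65535))
        frames[[k]] <- matrix(counts, nrow(em), ncol(em))
      }
      k <- k + 1L
    }
  }
  ts <- t0_ns + (0:8) * exposure_ms * 1e6 + (0:8)
  raw_sim_set(frames, channel_id, exposure_ms, ts,
              meta = list(truth = list(illum = illum, otf = otf,
                                       photons_scale = photons_scale,
                                       phantom_kind = if (inherits(phantom, "phantom")) phantom$kind else "matrix",
                                       seed = seed)))
}

#' Simulate a timestamped multichannel frame stream
#'
#' Emits individual frames for `n_timepoints` SIM frames of 1-3 channels
#' in the interleaved acquisition order produced by [plan_acquisition()]:
#' within each of the nine pattern slots, one frame per channel in
#' round-robin order. Each channel's ground truth is warped by its
#' mis-registration affine before imaging; a per-timepoint drift
#' (translation, px) can be added on top.
#'
#' @param phantoms list of phantoms, one per channel.
#' @param illums list of [illumination_params()], one per channel.
#' @param otfs list of [otf_model()], one per channel.
#' @param n_timepoints number of SIM frames.
#' @param misregistration list of 2x3 affine matrices `[A | t]` mapping
#'   reference coordinates to the channel's coordinates (NULL = identity).
#' @param drift_px per-timepoint drift, `n_timepoints x 2` (px) or NULL.
#' @param photons_scale,read_noise_e,offset,seed camera model, see
#'   [simulate_raw_set()].
#' @param timing a [timing_config()]; defaults to 1 ms exposures.
#' @return list of frame records, each with fields `channel_id`,
#'   `sequence_index` (0-based per channel), `angle_index`, `phase_index`,
#'   `timepoint`, `timestamp_ns`, `image`.
#' @export
simulate_multichannel_sequence <- function(phantoms, illums, otfs,
                                           n_timepoints = 1L,
                                           misregistration = NULL,
                                           drift_px = NULL,
                                           photons_scale = Inf,
                                           read_noise_e = 1.2, offset = 100,
                                           seed = 1L, timing = NULL) {
  nch <- length(phantoms)
  if (nch < 1 || nch > 3) stop("channel count must be 1-3")
  stopifnot(length(illums) == nch, length(otfs) == nch)
  if (is.null(timing))
    timing <- timing_config(exposure_ms = 1, n_channels = nch,
                            roi_lines = nrow(if (inherits(phantoms[[1]], "phantom")) phantoms[[1]]$image else phantoms[[1]]))
  plan <- plan_acquisition(timing)
  ts <- timestamp_series(plan, n_timepoints)
  sets <- vector("list", nch)
  out <- list()
  for (tp in seq_len(n_timepoints)) {
    for (ch in seq_len(nch)) {
      img <- if (inherits(phantoms[[ch]], "phantom")) phantoms[[ch]]$image else phantoms[[ch]]
      tr <- if (!is.null(misregistration) && !is.null(misregistration[[ch]]))
        misregistration[[ch]] else cbind(diag(2), c(0, 0))
      if (!is.null(drift_px)) {
        tr <- tr + cbind(matrix(0, 2, 2), drift_px[tp, ])
      }
      warped <- if (all(tr == cbind(diag(2), c(0, 0)))) img else warp_affine(img, tr)
      warped[warped < 0] <- 0
      sets[[ch]] <- simulate_raw_set(warped, illums[[ch]], otfs[[ch]],
                                     photons_scale, read_noise_e, offset,
                                     seed = seed + 131L * tp + ch,
                                     channel_id = ch,
                                     exposure_ms = timing$exposure_ms[ch])
    }
    for (i in 0:8) {
      for (ch in seq_len(nch)) {
        out[[length(out) + 1L]] <- list(
          channel_id = ch,
          sequence_index = (tp - 1L) * 9L + i,
          angle_index = i %/% 3L, phase_index = i %% 3L,
          timepoint = tp - 1L,
          timestamp_ns = ts$raw_ns[(tp - 1L) * 9L + i + 1L, ch],
          image = sets[[ch]]$frames[[i + 1L]])
      }
    }
  }
  out
}

#' @export
format.raw_sim_set <- function(x, ...) {
  sprintf("raw SIM set: channel %d, %d x %d px, exposure %.3g ms",
          x$channel_id, x$shape[1], x$shape[2], x$exposure_ms)
}

#' @export
print.raw_sim_set <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
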
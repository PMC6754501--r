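#' Ideal two-dimensional incoherent optical transfer function model
#'
#' Bundles the optical constants of one detection channel (numerical
#' aperture, emission wavelength, projected pixel size) together with the
#' frequency grid on which the ideal incoherent 2D OTF is evaluated. The
#' diffraction cutoff is \eqn{k_c = 2 NA / \lambda} in cycles/µm; beyond it
#' the transfer value is exactly zero.
#'
#' @param na numerical aperture, in (0, 2).
#' @param em_wavelength emission wavelength in µm.
#' @param pixel_size projected pixel pitch in sample space, µm.
#' @param grid_shape integer vector (rows, cols) of the frequency grid;
#'   both even and at least 8.
#' @return An object of class `otf_model` with fields `na`,
#'   `em_wavelength`, `pixel_size`, `cutoff` (cycles/µm), `grid_shape`,
#'   and `kmag` (the per-pixel frequency-magnitude map, DC at corner).
#' @examples
#' m <- otf_model(1.33, 0.515, 0.08, c(64, 64))
#' m$cutoff   # 2 * 1.33 / 0.515
#' @export
otf_model <- function(na, em_wavelength, pixel_size, grid_shape = c(512L, 512L)) {
  kc <- diffraction_cutoff(na, em_wavelength)
  kmag <- make_frequency_grid(grid_shape, pixel_size)
  structure(list(na = na, em_wavelength = em_wavelength,
                 pixel_size = pixel_size, cutoff = kc,
                 grid_shape = as.integer(grid_shape), kmag = kmag),
            class = "otf_model")
}

#' Spatial-frequency magnitude grid
#'
#' Per-pixel magnitude of the spatial frequency, in cycles/µm, laid out in
#' the unshifted FFT convention: the DC bin sits at `[1, 1]` and the most
#' negative (Nyquist) frequency, of magnitude `1/(2 * pixel_size)`, in the
#' middle of each axis. This layout matches `stats::fft` and is used by
#' every module; a centred view is only ever produced for display.
#'
#' @param shape integer (rows, cols); both even, at least 8.
#' @param pixel_size pixel pitch in µm, positive.
#' @return matrix of frequency magnitudes (cycles/µm).
#' @export
make_frequency_grid <- function(shape, pixel_size) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 8L) || any(shape %% 2L != 0L))
    stop("grid shape must be two even integers >= 8")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive")
  fx <- fft_freq(shape[1], pixel_size)
  fy <- fft_freq(shape[2], pixel_size)
  sqrt(outer(fx^2, fy^2, `+`))
}

#' Incoherent diffraction cutoff frequency
#'
#' @param na numerical aperture, in (0, 2).
#' @param em_wavelength emission wavelength, µm.
#' @return cutoff `2 * na / em_wavelength` in cycles/µm.
#' @export
diffraction_cutoff <- function(na, em_wavelength) {
  if (!is.numeric(na) || na <= 0 || na >= 2)
    stop("na must lie in (0, 2)")
  if (!is.numeric(em_wavelength) || em_wavelength <= 0)
    stop("em_wavelength must be positive")
  2 * na / em_wavelength
}

#' Ideal incoherent 2D OTF value
#'
#' The autocorrelation of a circular pupil:
#' \deqn{O(k) = (2/\pi)(\arccos\rho - \rho\sqrt{1 - \rho^2}),\quad
#'   \rho = k / k_c,} zero for \eqn{\rho \ge 1}. Real, in `[0, 1]`,
#' radially symmetric and monotonically non-increasing.
#'
#' @param model an `otf_model`, or a numeric cutoff (cycles/µm).
#' @param k frequency magnitude(s), cycles/µm, non-negative. Defaults to
#'   the model's own frequency grid.
#' @return transfer values, same shape as `k`.
#' @export
ideal_otf_2d <- function(model, k = NULL) {
  kc <- if (inherits(model, "otf_model")) model$cutoff else model
  if (is.null(k)) k <- model$kmag
  if (any(k < 0)) stop("k must be non-negative")
  rho <- pmin(k / kc, 1)
  v <- (2 / pi) * (acos(rho) - rho * sqrt(pmax(1 - rho^2, 0)))
  v[k >= kc] <- 0
  if (!is.null(dim(k))) dim(v) <- dim(k)
  v
}

#' Point-spread function of an OTF model
#'
#' Inverse transform of the ideal OTF on the model's grid, returned as a
#' centred (peak mid-image), unit-sum real image. The ideal incoherent
#' OTF is an autocorrelation, so its transform is non-negative up to
#' numerical round-off.
#'
#' @param model an `otf_model`.
#' @return real matrix of `model$grid_shape`, summing to 1.
#' @export
psf_from_otf <- function(model) {
  stopifnot(inherits(model, "otf_model"))
  otf <- ideal_otf_2d(model)
  psf <- Re(ifft2(otf))
  psf <- fftshift2(psf)
  psf[psf < 0] <- 0
  psf / sum(psf)
}

# Convolution of a real image with the model OTF (frequency-domain,
# periodic boundaries). Used by the virtual microscope and tests.
#' @noRd
otf_blur <- function(img, model) {
  Re(ifft2(fft2(img) * ideal_otf_2d(model)))
}
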
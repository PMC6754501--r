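# Internal Fourier helpers. Everything in the package uses the base-R fft()
# convention: X(k) = sum_r x(r) exp(-2i*pi*k*r/n), DC in the [1,1] bin,
# unnormalised forward transform.

#' @noRd
fft2 <- function(x) stats::fft(x)

#' @noRd
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# DFT sample frequencies in cycles per unit, matching numpy.fft.fftfreq.
#' @noRd
fft_freq <- function(n, d = 1) {
  i <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1))
  i / (n * d)
}

# Swap quadrants so DC moves from corner to centre (and back).
#' @noRd
fftshift2 <- function(x) {
  d <- dim(x)
  x[c((floor(d[1] / 2) + 1):d[1], 1:floor(d[1] / 2)),
    c((floor(d[2] / 2) + 1):d[2], 1:floor(d[2] / 2))]
}

#' @noRd
ifftshift2 <- function(x) {
  d <- dim(x)
  x[c((d[1] - floor(d[1] / 2) + 1):d[1], 1:(d[1] - floor(d[1] / 2))),
    c((d[2] - floor(d[2] / 2) + 1):d[2], 1:(d[2] - floor(d[2] / 2)))]
}

# Zero-pad a DC-at-corner spectrum onto a grid `factor` times larger.
# Total flux (DC value) is preserved; the real-space field is the
# trigonometric interpolation of the input on the finer grid, up to the
# pixel-count scale handled by the caller's inverse transform.
#' @noRd
pad_spectrum <- function(spec, factor = 2L) {
  d <- dim(spec)
  out <- matrix(0 + 0i, d[1] * factor, d[2] * factor)
  sh <- fftshift2(spec)
  r0 <- floor((d[1] * factor - d[1]) / 2)
  c0 <- floor((d[2] * factor - d[2]) / 2)
  out[(r0 + 1):(r0 + d[1]), (c0 + 1):(c0 + d[2])] <- sh
  ifftshift2(out)
}

# Trigonometric (Fourier) upsampling of a real image by an integer factor.
#' @noRd
fourier_upsample <- function(img, factor = 8L) {
  sp <- pad_spectrum(fft2(img), factor)
  Re(ifft2(sp)) * factor^2
}

# Full width at half maximum of an isolated peak in `img`, in physical
# units (pixel_size per pixel). The peak neighbourhood is trig-upsampled,
# then the half-max crossings of the row/column profiles through the peak
# are located by linear interpolation; x/y widths are averaged.
#' @noRd
measure_fwhm <- function(img, pixel_size, halfwin = 24L, factor = 8L) {
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  d <- dim(img)
  halfwin <- min(halfwin, pk[1] - 1, d[1] - pk[1], pk[2] - 1, d[2] - pk[2])
  if (halfwin < 4) stop("peak too close to the image border for FWHM")
  cut <- img[(pk[1] - halfwin):(pk[1] + halfwin),
             (pk[2] - halfwin):(pk[2] + halfwin)]
  up <- fourier_upsample(cut - min(cut), factor)
  pku <- which(up == max(up), arr.ind = TRUE)[1, ]
  width1d <- function(prof, ctr) {
    half <- prof[ctr] / 2
    lo <- ctr
    while (lo > 1 && prof[lo] > half) lo <- lo - 1
    hi <- ctr
    while (hi < length(prof) && prof[hi] > half) hi <- hi + 1
    if (lo == 1 || hi == length(prof)) return(NA_real_)
    xlo <- lo + (half - prof[lo]) / (prof[lo + 1] - prof[lo])
    xhi <- hi - 1 + (prof[hi - 1] - half) / (prof[hi - 1] - prof[hi])
    xhi - xlo
  }
  wx <- width1d(up[, pku[2]], pku[1])
  wy <- width1d(up[pku[1], ], pku[2])
  mean(c(wx, wy), na.rm = TRUE) * pixel_size / factor
}
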
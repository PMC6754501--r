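#' Separate the object-spectrum bands of one pattern angle
#'
#' Each raw frame of an angle mixes three copies of the object spectrum:
#' \deqn{\tilde D_j(k) = O(k)\,[S(k) + \tfrac{m}{2} e^{i\phi_j} S(k-p)
#'   + \tfrac{m}{2} e^{-i\phi_j} S(k+p)]}
#' with \eqn{\phi_j} the pattern phase of frame j. Given the three phase
#' frames this is a 3x3 linear system per frequency, solved by one exact
#' matrix inversion. Separation uses a provisional modulation
#' (default 1), so for data of true modulation m and start phase
#' \eqn{\phi_0} the returned side bands carry a factor
#' \eqn{m e^{\pm i\phi_0}} that the parameter fit recovers later.
#'
#' @param frames list of 3 matrices (the phases of one angle).
#' @param phases 3 pattern phases (radians), distinct mod 2π. Defaults to
#'   `c(0, 2, 4) * pi / 3` relative steps.
#' @param m modulation used in the mixing matrix (provisional 1).
#' @return object of class `band_set_entry`: complex matrices `b0`,
#'   `b_plus`, `b_minus` (frequency domain, DC at corner, each still at
#'   its acquisition position), and the `phases`/`m` used.
#' @export
separate_bands <- function(frames, phases = c(0, 2 * pi / 3, 4 * pi / 3), m = 1) {
  if (length(frames) != 3) stop("band separation needs exactly 3 frames")
  if (length(phases) != 3) stop("need 3 phases")
  M <- mixing_matrix(phases, m)
  # distinct phases mod 2pi <=> Vandermonde-type mixing matrix invertible
  z <- exp(1i * phases)
  if (min(abs(c(z[1] - z[2], z[1] - z[3], z[2] - z[3]))) < 1e-8)
    stop("degenerate phases: the band mixing matrix is singular")
  Minv <- solve(M)
  D <- lapply(frames, fft2)
  bands <- vector("list", 3)
  for (b in 1:3) {
    bands[[b]] <- Minv[b, 1] * D[[1]] + Minv[b, 2] * D[[2]] + Minv[b, 3] * D[[3]]
  }
  structure(list(b0 = bands[[1]], b_plus = bands[[2]], b_minus = bands[[3]],
                 phases = phases, m = m),
            class = "band_set_entry")
}

# Rows: frames j; columns: bands (0, +1, -1); entries c_b e^{i b phi_j}.
#' @noRd
mixing_matrix <- function(phases, m = 1) {
  cb <- c(1, m / 2, m / 2)
  t(vapply(phases, function(ph) cb * exp(1i * c(0, 1, -1) * ph), complex(3)))
}

# Rebuild the Fourier data of the 3 frames from separated bands (the
# forward remix); used by the round-trip invariant test.
#' @noRd
remix_bands <- function(bands) {
  M <- mixing_matrix(bands$phases, bands$m)
  lapply(1:3, function(j)
    M[j, 1] * bands$b0 + M[j, 2] * bands$b_plus + M[j, 3] * bands$b_minus)
}

#' Coarse (integer-bin) pattern wave-vector search
#'
#' Finds the integer-bin shift that maximizes the magnitude of the
#' normalized cross-correlation between the +1 side band and the zero
#' band, restricted to an annulus of shift radii (the pattern frequency
#' cannot sit at DC nor beyond the detection cutoff). The correlation of
#' the two band arrays peaks at the pattern wave vector because the
#' shifted side band overlaps the zero band over the OTF-support overlap.
#'
#' @param band0,band1 complex matrices from [separate_bands()] (`b0` and
#'   `b_plus`).
#' @param otf an [otf_model()] matching the band grid.
#' @param annulus search radii as fractions of the cutoff,
#'   default `c(0.2, 1.0)`.
#' @param min_score normalized score below which the result is flagged.
#' @param otf_min OTF support threshold for the band compensation
#'   (whitening) applied before correlating; without it the side band's
#'   complex bandpass blur suppresses the true correlation peak.
#' @return list: `p_bins` (integer shift, bins, length 2), `p` (cycles/µm),
#'   `score` (normalized, 0-1), `ok` (score >= min_score).
#' @export
estimate_k_coarse <- function(band0, band1, otf, annulus = c(0.2, 1.0),
                              min_score = 0.2, otf_min = 0.15) {
  d <- dim(band0)
  O <- ideal_otf_2d(otf)
  if (!identical(dim(O), d)) stop("band and OTF grids disagree")
  mask <- O > otf_min
  b0c <- band0; b0c[!mask] <- 0; b0c[mask] <- b0c[mask] / O[mask]
  b1c <- band1; b1c[!mask] <- 0; b1c[mask] <- b1c[mask] / O[mask]
  e0 <- sum(Mod(b0c)^2); e1 <- sum(Mod(b1c)^2)
  if (e0 == 0 || e1 == 0) stop("all-zero band")
  # C(q) = sum_k conj(B0c(k)) B1c(k+q) for every integer-bin shift q at
  # once, via the product field of the compensated bands. The shifted
  # side band differs from the zero band by the ramp e^{2 pi i p.r}, so
  # |C| peaks at q = p. Sparse scenes carry a speckle background of
  # relative height ~1/sqrt(number of emitters); the score threshold
  # flags unreliable peaks.
  g <- ifft2(b1c) * Conj(ifft2(b0c))
  C <- fft2(g) * length(g)
  cc <- Mod(C) / sqrt(e0 * e1)
  df <- 1 / (d[1] * otf$pixel_size)           # bin width, cycles/µm
  fx <- fft_freq(d[1]) * d[1]; fy <- fft_freq(d[2]) * d[2]
  qmag <- df * sqrt(outer(fx^2, fy^2, `+`))
  sel <- qmag >= annulus[1] * otf$cutoff & qmag <= annulus[2] * otf$cutoff
  if (!any(sel)) stop("empty search annulus")
  cc[!sel] <- -Inf
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  p_bins <- c(fx[pk[1]], fy[pk[2]])
  score <- cc[pk[1], pk[2]]
  list(p_bins = p_bins, p = p_bins * df, score = score, ok = score >= min_score)
}

#' Sub-bin refinement of the pattern wave vector, phase and modulation
#'
#' Both bands are compensated by the ideal OTF over its support (above
#' `otf_min`), transformed to real space, and the complex overlap
#' correlation under a continuous shift `q` (bins) is evaluated as a
#' single fractional-frequency Fourier sum
#' \eqn{C(q) = \sum_r b_1(r)\,\overline{b_0}(r)\, e^{-2\pi i q\cdot r/N}},
#' i.e. a phase-ramp multiplication in real space. `|C|` is maximized on
#' a shrinking 2D grid bracket around the coarse candidate; at the
#' optimum the complex correlation factor against the zero band yields
#' the starting phase (argument) and modulation depth (magnitude).
#'
#' @param band0,band1 complex matrices from [separate_bands()].
#' @param otf an [otf_model()].
#' @param coarse_p coarse estimate in bins (from [estimate_k_coarse()]).
#' @param otf_min OTF support threshold for band compensation.
#' @param tol_bins bracket size at convergence.
#' @param max_iter maximum bracket-shrink iterations.
#' @return list: `p_bins`, `p` (cycles/µm), `phase` (radians), `m`
#'   (clipped to (0, 1.5], with a warning above 1), `corr` (complex
#'   factor), `iterations`.
#' @export
refine_k_subpixel <- function(band0, band1, otf, coarse_p, otf_min = 0.15,
                              tol_bins = 1e-3, max_iter = 30L) {
  d <- dim(band0)
  O <- ideal_otf_2d(otf)
  mask <- O > otf_min
  b0c <- band0; b0c[!mask] <- 0; b0c[mask] <- b0c[mask] / O[mask]
  b1c <- band1; b1c[!mask] <- 0; b1c[mask] <- b1c[mask] / O[mask]
  r0 <- ifft2(b0c); r1 <- ifft2(b1c)
  G <- r1 * Conj(r0)                       # product field; C(q) = DFT_q(G)
  ex <- function(q, n) exp(-2i * pi * q * (0:(n - 1)) / n)
  Cq <- function(q) {
    # separable fractional-frequency sum: rows then columns
    drop(crossprod(ex(q[1], d[1]), G %*% ex(q[2], d[2])))
  }
  q <- as.numeric(coarse_p)
  span <- 1.0
  it <- 0L
  while (span > tol_bins && it < max_iter) {
    it <- it + 1L
    grid <- expand.grid(dx = seq(-span, span, length.out = 5),
                        dy = seq(-span, span, length.out = 5))
    vals <- vapply(seq_len(nrow(grid)),
                   function(i) Mod(Cq(q + c(grid$dx[i], grid$dy[i]))), 0)
    best <- which.max(vals)
    q <- q + c(grid$dx[best], grid$dy[best])
    span <- span / 2
  }
  if (span > tol_bins)
    stop(sprintf("subpixel refinement did not converge: span %.2g bins after %d iterations",
                 span, it))
  # Complex correlation factor, weighted by the OTF product rather than
  # OTF-compensated (no small-O division, so detector noise at the edge
  # of the support is not amplified). With B1 = m e^{i phi} O S(k-p) and
  # B0 = O S the weighted numerator and denominator carry identical
  # |S|^2 O(k)^2 O(k+q)^2 weights, so the ratio is exactly m e^{i phi}
  # for noiseless data.
  df <- 1 / (d[1] * otf$pixel_size)
  kshift <- shifted_kmag(d, otf$pixel_size, q * df)
  Oshift <- ideal_otf_2d(otf, kshift)
  Gw <- ifft2(band1 * O) * Conj(ifft2(band0 * O))
  num <- drop(crossprod(ex(q[1], d[1]), Gw %*% ex(q[2], d[2]))) * length(band0)
  # noise power per bin, measured where the OTF carries no signal, and
  # subtracted from the denominator (plain |B0 Oshift|^2 is biased up
  # by the noise power under the weights)
  outside <- O == 0
  n0 <- if (any(outside)) mean(Mod(band0[outside])^2) else 0
  denom <- sum(Mod(band0 * Oshift)^2) - n0 * sum(Oshift[!outside]^2)
  if (denom <= 0) stop("empty band overlap region")
  corr <- num / denom
  m <- Mod(corr)
  if (m > 1) warning(sprintf("estimated modulation depth %.3f > 1; clipping at 1.5", m))
  m <- min(m, 1.5)
  list(p_bins = q, p = q * df, phase = Arg(corr), m = m, corr = corr,
       iterations = it)
}

# |k + p0| on the unshifted frequency grid for a continuous offset p0
# (cycles/µm); used to evaluate displaced analytic OTFs.
#' @noRd
shifted_kmag <- function(d, pixel_size, p0) {
  fx <- fft_freq(d[1], pixel_size) + p0[1]
  fy <- fft_freq(d[2], pixel_size) + p0[2]
  sqrt(outer(fx^2, fy^2, `+`))
}

#' Fit all illumination parameters of a channel
#'
#' Runs band separation (provisional modulation 1), coarse and sub-bin
#' wave-vector estimation for each of the three pattern angles of a raw
#' set, and assembles the resulting [illumination_params()] with
#' per-angle quality scores attached.
#'
#' @param raw a [raw_sim_set()].
#' @param otf an [otf_model()] on the raw grid.
#' @param min_score coarse-score threshold; angles below it are flagged
#'   with a warning.
#' @param annulus coarse search annulus, fractions of the cutoff.
#' @return an [illumination_params()] with `scores` set; modulation is
#'   the mean of the per-angle estimates, per-angle values in
#'   `attr(, "per_angle")`.
#' @export
fit_channel_params <- function(raw, otf, min_score = 0.2, annulus = c(0.2, 1.0)) {
  stopifnot(inherits(raw, "raw_sim_set"))
  p <- matrix(0, 3, 2)
  phase <- numeric(3); mm <- numeric(3); score <- numeric(3)
  details <- vector("list", 3)
  for (a in 1:3) {
    fr <- raw$frames[(3 * a - 2):(3 * a)]
    # remove each frame's mean: the camera baseline (and the scene DC)
    # otherwise dominates the DC bin and biases the modulation estimate
    fr <- lapply(fr, function(x) x - mean(x))
    bands <- separate_bands(fr)
    coarse <- estimate_k_coarse(bands$b0, bands$b_plus, otf, annulus, min_score)
    if (!coarse$ok)
      warning(sprintf("angle %d: coarse correlation score %.3f below threshold %.3f",
                      a, coarse$score, min_score))
    fine <- refine_k_subpixel(bands$b0, bands$b_plus, otf, coarse$p_bins)
    p[a, ] <- fine$p
    phase[a] <- fine$phase
    mm[a] <- fine$m
    score[a] <- coarse$score
    details[[a]] <- fine
  }
  out <- illumination_params(p, start_phase = phase,
                             modulation = min(mean(mm), 1.5),
                             cutoff = otf$cutoff, scores = score,
                             angle_sep_tol_deg = 180)
  attr(out, "per_angle") <- list(m = mm, details = details)
  out
}

#' Serialize illumination parameters to a text file
#'
#' Writes (and [read_illumination_params()] reads back) the per-channel
#' parameter sets as JSON: wave vectors in cycles/µm and grid bins,
#' phases, modulation and scores, mirroring a calibration-sample
#' workflow where parameters are estimated once on beads and reused.
#'
#' @param params an [illumination_params()] or list of them (one per
#'   channel).
#' @param path output file.
#' @param pixel_size,grid_n optional geometry to also record bins.
#' @export
write_illumination_params <- function(params, path, pixel_size = NULL,
                                      grid_n = NULL) {
  if (inherits(params, "illum_params")) params <- list(params)
  ser <- lapply(params, function(pr) {
    x <- list(p = unname(pr$p), start_phase = pr$start_phase,
              modulation = pr$modulation, scores = pr$scores)
    if (!is.null(pixel_size) && !is.null(grid_n))
      x$p_bins <- unname(pr$p * grid_n * pixel_size)
    x
  })
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_illumination_params
#' @export
read_illumination_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(if (is.data.frame(raw)) nrow(raw) else length(raw)), function(i) {
    x <- if (is.data.frame(raw)) raw[i, ] else raw[[i]]
    illumination_params(matrix(unlist(x$p), 3, 2),
                        start_phase = unlist(x$start_phase),
                        modulation = x$modulation,
                        scores = unlist(x$scores),
                        angle_sep_tol_deg = 180)
  })
}
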
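#' Affine channel registration from bead fiducials
#'
#' Multicolor channels of the instrument model are imaged on separate
#' cameras and are therefore mis-registered by (approximately) an affine
#' transform. A shared bead calibration image per channel provides
#' fiducials: bead centroids are detected in both images, matched by
#' nearest neighbour after removing the coarse shift, and a least-squares
#' affine fit maps reference coordinates to moving-image coordinates.
#'
#' @param reference,moving bead images (matrices).
#' @param threshold_q intensity quantile separating beads from background.
#' @param min_sep_px minimum peak separation when detecting beads.
#' @param max_match_px maximum residual distance for a centroid match
#'   after coarse-shift removal.
#' @return object of class `registration_transform`: 2 x 3 matrix
#'   `[A | t]` with `moving = A %*% ref + t` (0-based pixel coords),
#'   `rms_residual` (px) and `n_matches`.
#' @export
estimate_registration_affine <- function(reference, moving,
                                         threshold_q = 0.985,
                                         min_sep_px = 6, max_match_px = 6) {
  c0 <- detect_bead_centroids(reference, threshold_q, min_sep_px)
  c1 <- detect_bead_centroids(moving, threshold_q, min_sep_px)
  if (nrow(c0) < 3 || nrow(c1) < 3)
    stop("need at least 3 bead centroids in each image")
  shift <- coarse_shift(reference, moving)
  # match each reference centroid to the nearest moving centroid
  pairs <- lapply(seq_len(nrow(c0)), function(i) {
    pred <- c0[i, ] + shift
    d2 <- (c1[, 1] - pred[1])^2 + (c1[, 2] - pred[2])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_match_px) c(i, j) else NULL
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 3) stop("fewer than 3 matched beads")
  X <- c0[pairs[, 1], , drop = FALSE]
  Y <- c1[pairs[, 2], , drop = FALSE]
  if (abs(stats::cor(X[, 1], X[, 2])) > 0.999)
    stop("matched beads are collinear; affine fit is degenerate")
  M <- cbind(X, 1)
  fit <- qr.solve(M, Y)                     # 3 x 2
  tr <- t(fit)                              # 2 x 3, [A | t]
  res <- Y - M %*% fit
  rms <- sqrt(mean(rowSums(res^2)))
  structure(list(matrix = tr, rms_residual = rms, n_matches = nrow(pairs)),
            class = "registration_transform")
}

# Sub-pixel bead centroids: local maxima above an intensity quantile,
# separated by min_sep_px, refined by an iterative Gaussian-weighted
# centre of mass (low truncation bias for symmetric spots). Returns an
# n x 2 matrix of 0-based (x, y) = (row, col) coordinates.
#' @noRd
detect_bead_centroids <- function(img, threshold_q = 0.985, min_sep_px = 6,
                                  sigma_px = 1.5, halfwin = 5L) {
  bg <- stats::median(img)
  # quantile threshold, floored at 20% of the peak height above background
  # so PSF ring sidelobes of bright beads are not picked up as beads
  thr <- max(stats::quantile(img, threshold_q), bg + 0.2 * (max(img) - bg))
  d <- dim(img)
  cand <- which(img > thr, arr.ind = TRUE)
  cand <- cand[order(img[cand], decreasing = TRUE), , drop = FALSE]
  picked <- matrix(numeric(0), 0, 2)
  h <- halfwin
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (p[1] <= h || p[2] <= h || p[1] > d[1] - h || p[2] > d[2] - h) next
    w <- img[(p[1] - 1):(p[1] + 1), (p[2] - 1):(p[2] + 1)]
    if (img[p[1], p[2]] < max(w)) next       # not a local max
    if (nrow(picked) > 0) {
      dmin <- min(sqrt((picked[, 1] - (p[1] - 1))^2 + (picked[, 2] - (p[2] - 1))^2))
      if (dmin < min_sep_px) next
    }
    win <- pmax(img[(p[1] - h):(p[1] + h), (p[2] - h):(p[2] + h)] - bg, 0)
    xs <- (p[1] - 1 - h):(p[1] - 1 + h)      # 0-based coords of window rows
    ys <- (p[2] - 1 - h):(p[2] - 1 + h)
    cx <- p[1] - 1; cy <- p[2] - 1
    for (it in 1:15) {
      g <- exp(-(outer((xs - cx)^2, (ys - cy)^2, `+`)) / (2 * sigma_px^2))
      wg <- win * g
      s <- sum(wg)
      if (s <= 0) break
      nx <- sum(outer(xs, rep(1, 2 * h + 1)) * wg) / s
      ny <- sum(outer(rep(1, 2 * h + 1), ys) * wg) / s
      if (abs(nx - cx) < 1e-4 && abs(ny - cy) < 1e-4) { cx <- nx; cy <- ny; break }
      cx <- nx; cy <- ny
    }
    picked <- rbind(picked, c(cx, cy))
  }
  picked
}

# Integer-pixel shift between two images by phase correlation.
#' @noRd
coarse_shift <- function(reference, moving) {
  X <- fft2(reference); Y <- fft2(moving)
  cc <- Re(ifft2(Conj(X) * Y))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ] - 1L
  d <- dim(reference)
  pk[1] <- if (pk[1] > d[1] / 2) pk[1] - d[1] else pk[1]
  pk[2] <- if (pk[2] > d[2] / 2) pk[2] - d[2] else pk[2]
  as.numeric(pk)
}

#' Apply an affine transform to an image
#'
#' Inverse warping with bilinear interpolation: output pixel `u` (0-based)
#' samples the input at `A %*% u + t`. Out-of-image samples are 0.
#'
#' @param img matrix.
#' @param transform 2 x 3 matrix `[A | t]` or a `registration_transform`.
#' @return warped matrix, same shape.
#' @export
warp_affine <- function(img, transform) {
  tr <- if (inherits(transform, "registration_transform")) transform$matrix else transform
  stopifnot(is.matrix(tr), nrow(tr) == 2, ncol(tr) == 3)
  d <- dim(img)
  u <- rep(0:(d[1] - 1), d[2])
  v <- rep(0:(d[2] - 1), each = d[1])
  sx <- tr[1, 1] * u + tr[1, 2] * v + tr[1, 3]
  sy <- tr[2, 1] * u + tr[2, 2] * v + tr[2, 3]
  bilinear_sample(img, sx, sy, d)
}

#' @noRd
bilinear_sample <- function(img, sx, sy, outdim) {
  d <- dim(img)
  i0 <- floor(sx); j0 <- floor(sy)
  fx <- sx - i0; fy <- sy - j0
  val <- numeric(length(sx))
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di; jj <- j0 + dj
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2]
    w <- (if (di == 0) 1 - fx else fx) * (if (dj == 0) 1 - fy else fy)
    idx <- ii[ok] + 1L + jj[ok] * d[1]
    val[ok] <- val[ok] + w[ok] * img[idx]
  }
  matrix(val, outdim[1], outdim[2])
}

#' Apply a registration transform to an image
#'
#' Warps the moving image onto the reference frame using the transform
#' estimated by [estimate_registration_affine()] (inverse warping with
#' bilinear interpolation).
#'
#' @param image matrix (the moving channel's image).
#' @param transform `registration_transform` or 2 x 3 matrix.
#' @return registered matrix, same shape.
#' @export
apply_registration <- function(image, transform) {
  warp_affine(image, transform)
}

#' Invert a registration transform
#' @param transform `registration_transform` or 2 x 3 matrix.
#' @return 2 x 3 matrix of the inverse affine map.
#' @export
invert_affine <- function(transform) {
  tr <- if (inherits(transform, "registration_transform")) transform$matrix else transform
  A <- tr[, 1:2]; t <- tr[, 3]
  Ai <- solve(A)
  cbind(Ai, -Ai %*% t)
}

#' @export
format.registration_transform <- function(x, ...) {
  sprintf("affine registration: %d matches, rms residual %.4f px",
          x$n_matches, x$rms_residual)
}

#' @export
print.registration_transform <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
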
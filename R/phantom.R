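#' Synthetic ground-truth phantoms
#'
#' Deterministic (seeded) test scenes for the virtual microscope, in
#' photons/pixel at unit exposure. `bead_clusters` emulates the standard
#' multicolor calibration sample: a thin layer of closely packed
#' sub-diffraction beads whose separation is invisible in wide-field but
#' resolvable by SIM. Sub-pixel emitter/bead centres are recorded in the
#' return value so tests can measure against the truth.
#'
#' @param kind one of `"points"`, `"bead_clusters"`, `"lines"`,
#'   `"siemens_star"`.
#' @param shape (rows, cols), both at least 64.
#' @param seed integer RNG seed; identical seeds give identical phantoms.
#' @param n number of points (kind `points`) or clusters
#'   (`bead_clusters`) or lines.
#' @param pixel_size µm per pixel; used to convert bead diameters.
#' @param bead_diameter_um bead diameter in µm (default 0.2, the standard
#'   calibration microsphere).
#' @param beads_per_cluster beads per cluster.
#' @param centers optional n x 2 matrix of point centres in pixel units
#'   (0-based), overriding random placement for kind `points`.
#' @param intensity peak intensity scale (photons/pixel at unit exposure).
#' @return object of class `phantom`: list with `image` (non-negative
#'   matrix), `kind`, `seed`, and `truth` (data frame of centres
#'   `x`, `y` in 0-based pixels and `diameter_px`).
#' @export
make_phantom <- function(kind = c("points", "bead_clusters", "lines", "siemens_star"),
                         shape = c(256L, 256L), seed = 1L, n = 10L,
                         pixel_size = 0.08, bead_diameter_um = 0.2,
                         beads_per_cluster = 4L, centers = NULL,
                         intensity = 1) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (any(shape < 64L)) stop("phantom shape must be at least 64 x 64")
  img <- matrix(0, shape[1], shape[2])
  truth <- NULL
  rng <- local({ set.seed(as.integer(seed)); NULL })
  set.seed(as.integer(seed))
  if (kind == "points") {
    if (is.null(centers)) {
      centers <- cbind(stats::runif(n, shape[1] * 0.2, shape[1] * 0.8),
                       stats::runif(n, shape[2] * 0.2, shape[2] * 0.8))
    }
    for (i in seq_len(nrow(centers)))
      img <- img + splat_point(shape, centers[i, 1], centers[i, 2]) * intensity
    truth <- data.frame(x = centers[, 1], y = centers[, 2], diameter_px = 0)
  } else if (kind == "bead_clusters") {
    d_px <- bead_diameter_um / pixel_size
    cx <- stats::runif(n, shape[1] * 0.15, shape[1] * 0.85)
    cy <- stats::runif(n, shape[2] * 0.15, shape[2] * 0.85)
    xs <- ys <- numeric(0)
    for (i in seq_len(n)) {
      # closely packed: centres ~1 bead diameter apart around the cluster seat
      ang <- stats::runif(beads_per_cluster, 0, 2 * pi)
      rad <- d_px * (0.5 + stats::runif(beads_per_cluster, 0, 0.8))
      xs <- c(xs, cx[i] + rad * cos(ang))
      ys <- c(ys, cy[i] + rad * sin(ang))
    }
    for (i in seq_along(xs))
      img <- img + draw_disk(shape, xs[i], ys[i], d_px / 2) * intensity
    truth <- data.frame(x = xs, y = ys, diameter_px = d_px)
  } else if (kind == "lines") {
    for (i in seq_len(n)) {
      ang <- stats::runif(1, 0, pi)
      off <- stats::runif(1, -shape[1] / 3, shape[1] / 3)
      x <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1])
      y <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1])
      d <- abs((x - shape[1] / 2) * cos(ang) + (y - shape[2] / 2) * sin(ang) - off)
      img <- img + intensity * exp(-d^2 / (2 * 0.75^2))
    }
    truth <- data.frame(x = numeric(0), y = numeric(0), diameter_px = numeric(0))
  } else { # siemens_star
    x <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1]) - shape[1] / 2
    y <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1]) - shape[2] / 2
    th <- atan2(y, x)
    r <- sqrt(x^2 + y^2)
    img <- intensity * (0.5 + 0.5 * cos(n * th)) * (r > 4 & r < min(shape) * 0.45)
    truth <- data.frame(x = numeric(0), y = numeric(0), diameter_px = numeric(0))
  }
  structure(list(image = img, kind = kind, seed = as.integer(seed), truth = truth),
            class = "phantom")
}

# Bilinear sub-pixel splat of a unit-flux point source; cx, cy 0-based.
#' @noRd
splat_point <- function(shape, cx, cy) {
  img <- matrix(0, shape[1], shape[2])
  i0 <- floor(cx); j0 <- floor(cy)
  fx <- cx - i0; fy <- cy - j0
  for (di in 0:1) for (dj in 0:1) {
    i <- i0 + di + 1L; j <- j0 + dj + 1L
    if (i >= 1 && i <= shape[1] && j >= 1 && j <= shape[2]) {
      w <- (if (di == 0) 1 - fx else fx) * (if (dj == 0) 1 - fy else fy)
      img[i, j] <- img[i, j] + w
    }
  }
  img
}

# Anti-aliased disk of radius r px centred at sub-pixel (cx, cy), 0-based.
#' @noRd
draw_disk <- function(shape, cx, cy, r) {
  i0 <- max(1L, floor(cx - r - 2) + 1L); i1 <- min(shape[1], ceiling(cx + r + 2) + 1L)
  j0 <- max(1L, floor(cy - r - 2) + 1L); j1 <- min(shape[2], ceiling(cy + r + 2) + 1L)
  img <- matrix(0, shape[1], shape[2])
  if (i0 > i1 || j0 > j1) return(img)
  xi <- (i0:i1) - 1; yj <- (j0:j1) - 1
  d <- sqrt(outer((xi - cx)^2, (yj - cy)^2, `+`))
  img[i0:i1, j0:j1] <- pmin(pmax(r - d + 0.5, 0), 1)  # 1-px soft edge
  img
}
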
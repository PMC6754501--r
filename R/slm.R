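#' Binary phase-grating bitmap for a pixelated SLM
#'
#' The SLM acts as an electronically defined binary optical phase
#' grating: each pixel is on or off by thresholding the signed distance
#' to the nearest grating line. The grating normal is a rational-slope
#' integer vector `(u, v)`, so phase steps of `period / 3` are realized
#' as exact (or tolerance-checked) translations on the pixel grid.
#'
#' @param slm_shape (rows, cols) of the SLM, default 1024 x 1280.
#' @param normal integer 2-vector (u, v), the grating line normal
#'   (coprime); orientation angle is `atan2(v, u)`.
#' @param period_px grating period along the normal, SLM pixels (>= 2,
#'   possibly non-integer).
#' @param phase_step_index 0, 1 or 2: translates the pattern by
#'   `phase_step_index * period_px / 3` along the normal.
#' @param phase_tol_px tolerance for realizing `period/3` as a pixel-grid
#'   translation.
#' @return logical matrix (`TRUE` = on).
#' @export
binary_grating_pattern <- function(slm_shape = c(1024L, 1280L), normal = c(1L, 0L),
                                   period_px, phase_step_index = 0L,
                                   phase_tol_px = 0.05) {
  if (period_px < 2) stop("grating period must be at least 2 SLM pixels")
  shift <- realize_phase_shift(normal, period_px, phase_step_index, phase_tol_px)
  L <- sqrt(sum(normal^2))
  x <- 0:(slm_shape[1] - 1)
  y <- 0:(slm_shape[2] - 1)
  # signed distance along the grating normal, in px
  t <- outer(normal[1] * x, normal[2] * y, `+`) / L
  ((t - shift) %% period_px) < period_px / 2
}

# Nearest representable translation along the (u, v) normal realizing a
# phase step of j * period / 3; errors if it deviates more than tol.
#' @noRd
realize_phase_shift <- function(normal, period_px, j, tol) {
  if (j == 0) return(0)
  L <- sqrt(sum(normal^2))
  want <- j * period_px / 3
  # achievable shifts are integer multiples of 1/L (projections of
  # integer pixel translations onto the normal), modulo the period
  n <- round(want * L)
  got <- n / L
  err <- min(abs(got - want), abs(got - want + period_px), abs(got - want - period_px))
  if (err > tol)
    stop(sprintf("phase step %d unrealizable: nearest pixel-grid shift deviates %.3f px (tol %.3f)",
                 j, err, tol))
  got
}

#' Diffraction-order positions and intensities of a grating
#'
#' A binary phase grating of period `P` diffracts wavelength `lambda`
#' into orders at `n * lambda / P` along the grating normal (normalized
#' Fourier-plane units, nm/px by default). Relative intensities come
#' from the discrete Fourier transform of the realized (pixel-rounded)
#' phase bitmap (+1/-1 field), so rounding-induced spurious orders are
#' captured; an ideal 50 percent duty grating has vanishing even orders.
#'
#' @param bitmap logical matrix from [binary_grating_pattern()], or NULL
#'   to use the ideal analytic intensities.
#' @param normal,period_px grating geometry (needed with or without
#'   bitmap).
#' @param wavelength_nm illumination wavelength.
#' @param max_order highest order to report.
#' @return data frame: `order`, `pos_x`, `pos_y` (normalized units),
#'   `intensity` (relative, order +1 = 1).
#' @export
predicted_spot_positions <- function(bitmap = NULL, normal, period_px,
                                     wavelength_nm, max_order = 7L) {
  L <- sqrt(sum(normal^2))
  unit <- normal / L
  orders <- setdiff(-max_order:max_order, 0L)
  pos <- wavelength_nm / period_px * outer(orders, unit)
  inten <- if (is.null(bitmap)) {
    # Fourier series of an ideal 50% duty binary +/-1 grating
    ifelse(orders %% 2 == 0, 0, (2 / (pi * abs(orders)))^2)
  } else {
    field <- ifelse(bitmap, 1, -1)
    P <- Mod(fft2(field))^2
    d <- dim(bitmap)
    vapply(orders, function(n) {
      # frequency of order n in cycles/px along the normal
      f <- n / period_px * unit
      if (any(abs(f) >= 0.5))            # beyond the SLM pixel Nyquist:
        return(ifelse(n %% 2 == 0, 0, (2 / (pi * abs(n)))^2))  # analytic
      bin <- round(f * d) %% d
      # sum a 3x3 neighbourhood: off-grid orders spread over bins
      ii <- (bin[1] + (-1:1)) %% d[1] + 1
      jj <- (bin[2] + (-1:1)) %% d[2] + 1
      sum(P[ii, jj])
    }, 0)
  }
  i1 <- inten[orders == 1L]
  if (i1 > 0) inten <- inten / i1
  data.frame(order = orders, pos_x = pos[, 1], pos_y = pos[, 2],
             intensity = inten)
}

#' Fourier-plane order-selection mask
#'
#' Hole positions in normalized Fourier-plane units (same units as
#' [predicted_spot_positions()]); holes come in point-symmetric ±1 pairs
#' and never sit at DC (the zeroth order is always blocked in two-beam
#' mode).
#'
#' @param hole_positions n x 2 matrix.
#' @param hole_radius acceptance radius, same units.
#' @return object of class `fourier_mask`.
#' @export
fourier_mask <- function(hole_positions, hole_radius) {
  hp <- as.matrix(hole_positions)
  if (nrow(hp) == 0) stop("empty mask")
  if (any(sqrt(rowSums(hp^2)) < hole_radius))
    stop("mask holes must exclude the zeroth order (DC)")
  # symmetry: every hole's point reflection is also a hole
  for (i in seq_len(nrow(hp))) {
    dd <- sqrt(rowSums((hp + matrix(hp[i, ], nrow(hp), 2, byrow = TRUE))^2))
    if (min(dd) > 1e-6 * max(1, max(abs(hp))))
      stop("mask holes must be symmetric in +/-1 pairs")
  }
  structure(list(hole_positions = hp, hole_radius = hole_radius),
            class = "fourier_mask")
}

#' Mask transmission score for a diffraction pattern
#'
#' @param spots data frame from [predicted_spot_positions()].
#' @param mask a [fourier_mask()].
#' @return list: `wanted_fraction` (±1 intensity inside holes / total ±1
#'   intensity) and `leakage_fraction` (other orders inside holes / total
#'   other-order intensity).
#' @export
score_mask_transmission <- function(spots, mask) {
  stopifnot(inherits(mask, "fourier_mask"))
  inside <- vapply(seq_len(nrow(spots)), function(i) {
    d <- sqrt((mask$hole_positions[, 1] - spots$pos_x[i])^2 +
              (mask$hole_positions[, 2] - spots$pos_y[i])^2)
    any(d <= mask$hole_radius)
  }, TRUE)
  pm1 <- abs(spots$order) == 1L
  wanted <- if (sum(spots$intensity[pm1]) > 0)
    sum(spots$intensity[pm1 & inside]) / sum(spots$intensity[pm1]) else 0
  other <- sum(spots$intensity[!pm1])
  leakage <- if (other > 0) sum(spots$intensity[!pm1 & inside]) / other else 0
  list(wanted_fraction = wanted, leakage_fraction = leakage)
}

#' Multicolor SLM pattern search
#'
#' Finds binary grating sets for up to three wavelengths whose ±1
#' diffraction orders pass one stationary Fourier mask: for each of the
#' three pattern orientations (rational-slope normals near 0°/60°/120°),
#' the grating period of each color is adjusted so all colors' ±1 spots
#' coincide at the target radius (`pos = lambda / period`), all three
#' phase steps are realizable on the pixel grid, and every spurious
#' order of every color clears every hole by a margin. Selects the
#' feasible set with maximal spurious-order clearance. Equal spot radii
#' across colors imply equal relative resolution improvement for every
#' channel by construction.
#'
#' @param wavelengths_nm 1-3 wavelengths.
#' @param target_spot_radius desired ±1 spot radius, normalized units
#'   (nm/px); sets the SIM pattern frequency and hence the resolution
#'   gain.
#' @param radius_tolerance acceptable deviation of a spot from its hole
#'   centre, same units.
#' @param period_search period grid step (px) around the nominal
#'   `lambda / target_spot_radius`, searched within ± `period_window`.
#' @param period_window half-width of the period search, px.
#' @param slm_shape SLM pixel dimensions.
#' @param slope_max maximum |u|,|v| of rational normals enumerated.
#' @param orient_tol_deg acceptance window around 0/60/120 degrees.
#' @param phase_tol_px phase-step realizability tolerance.
#' @param wanted_min,leakage_max acceptance thresholds on the
#'   full-bitmap DFT mask transmission.
#' @return list: `pattern_set` (an `slm_pattern_set`), `mask`
#'   (a [fourier_mask()]), `report` (per color/angle scores and the
#'   per-color resolution-gain equality), or an error of class
#'   `slm_infeasible` naming the tightest constraint.
#' @export
multicolor_pattern_search <- function(wavelengths_nm,
                                      target_spot_radius = 100,
                                      radius_tolerance = 2,
                                      period_search = 0.05,
                                      period_window = 0.6,
                                      slm_shape = c(1024L, 1280L),
                                      slope_max = 8L,
                                      orient_tol_deg = 8,
                                      phase_tol_px = 0.05,
                                      wanted_min = 0.95,
                                      leakage_max = 0.01) {
  nw <- length(wavelengths_nm)
  if (nw < 1 || nw > 3) stop("1-3 wavelengths")
  normals <- enumerate_normals(slope_max, orient_tol_deg)
  fail <- list(orient = 0L, period = 0L, phase = 0L, radius = 0L)
  chosen <- vector("list", 3)
  for (ai in 1:3) {
    target_deg <- c(0, 60, 120)[ai]
    cand_normals <- normals[abs(ang_diff(normals$deg, target_deg)) <= orient_tol_deg, ]
    if (nrow(cand_normals) == 0) { fail$orient <- fail$orient + 1L; next }
    best <- NULL
    for (ni in seq_len(nrow(cand_normals))) {
      nrm <- c(cand_normals$u[ni], cand_normals$v[ni])
      sel <- vector("list", nw)
      ok <- TRUE
      worst_clear <- Inf; worst_dev <- 0
      for (wi in seq_len(nw)) {
        lam <- wavelengths_nm[wi]
        nominal <- lam / target_spot_radius
        periods <- seq(nominal - period_window, nominal + period_window,
                       by = period_search)
        periods <- periods[periods >= 2]
        if (!length(periods)) { fail$period <- fail$period + 1L; ok <- FALSE; break }
        pbest <- NULL
        for (P in periods) {
          dev <- abs(lam / P - target_spot_radius)
          if (dev > radius_tolerance) { next }
          realizable <- !inherits(try(realize_phase_shift(nrm, P, 1L, phase_tol_px),
                                      silent = TRUE), "try-error") &&
                        !inherits(try(realize_phase_shift(nrm, P, 2L, phase_tol_px),
                                      silent = TRUE), "try-error")
          if (!realizable) { fail$phase <- fail$phase + 1L; next }
          if (is.null(pbest) || dev < pbest$dev) pbest <- list(P = P, dev = dev)
        }
        if (is.null(pbest)) { fail$radius <- fail$radius + 1L; ok <- FALSE; break }
        sel[[wi]] <- pbest
        worst_dev <- max(worst_dev, pbest$dev)
      }
      if (!ok) next
      # spurious-order clearance (analytic positions; DFT check later)
      clear <- min(vapply(seq_len(nw), function(wi) {
        sp <- predicted_spot_positions(NULL, nrm, sel[[wi]]$P, wavelengths_nm[wi])
        oth <- sp[abs(sp$order) != 1L & sp$intensity > 1e-9, ]
        if (!nrow(oth)) return(Inf)
        min(abs(sqrt(oth$pos_x^2 + oth$pos_y^2) - target_spot_radius))
      }, 0))
      score <- clear - worst_dev
      if (is.null(best) || score > best$score)
        best <- list(normal = nrm, sel = sel, score = score, clear = clear)
    }
    chosen[[ai]] <- best
  }
  if (any(vapply(chosen, is.null, TRUE))) {
    tight <- names(fail)[which.max(unlist(fail))]
    stop(structure(class = c("slm_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "no feasible multicolor pattern set; tightest constraint: %s (orientation misses: %d, period range: %d, phase realizability: %d, radius tolerance: %d)",
                     tight, fail$orient, fail$period, fail$phase, fail$radius),
                     call = sys.call())))
  }
  # assemble bitmaps, mask, verification scores
  holes <- do.call(rbind, lapply(1:3, function(ai) {
    u <- chosen[[ai]]$normal / sqrt(sum(chosen[[ai]]$normal^2))
    rbind(target_spot_radius * u, -target_spot_radius * u)
  }))
  mask <- fourier_mask(holes, radius_tolerance)
  patterns <- list(); periods <- list(); report <- list()
  for (wi in seq_len(nw)) {
    for (ai in 1:3) {
      P <- chosen[[ai]]$sel[[wi]]$P
      nrm <- chosen[[ai]]$normal
      bms <- lapply(0:2, function(j)
        binary_grating_pattern(slm_shape, nrm, P, j, phase_tol_px))
      key <- sprintf("w%d_a%d", wi, ai)
      patterns[[key]] <- bms
      periods[[key]] <- P
      spots <- predicted_spot_positions(bms[[1]], nrm, P, wavelengths_nm[wi])
      sc <- score_mask_transmission(spots, mask)
      report[[key]] <- c(list(wavelength_nm = wavelengths_nm[wi], angle = ai,
                              period_px = P, normal = nrm), sc)
      if (sc$wanted_fraction < wanted_min || sc$leakage_fraction > leakage_max)
        warning(sprintf("%s: transmission %.3f / leakage %.4f outside targets",
                        key, sc$wanted_fraction, sc$leakage_fraction))
    }
  }
  gains <- target_spot_radius / wavelengths_nm  # pattern freq in 1/px, equal radius
  pattern_set <- structure(
    list(slm_shape = as.integer(slm_shape), patterns = patterns,
         periods = periods,
         normals = lapply(chosen, `[[`, "normal"),
         wavelengths_nm = wavelengths_nm,
         phase_offsets = lapply(1:3, function(ai)
           vapply(0:2, function(j) realize_phase_shift(chosen[[ai]]$normal,
                                                       chosen[[ai]]$sel[[1]]$P, j,
                                                       phase_tol_px), 0))),
    class = "slm_pattern_set")
  list(pattern_set = pattern_set, mask = mask, report = report,
       spot_radius = target_spot_radius,
       resolution_gain_equal = TRUE)
}

# Coprime integer normals with orientation within tol of 0/60/120 deg.
#' @noRd
enumerate_normals <- function(slope_max, orient_tol_deg) {
  g <- expand.grid(u = -slope_max:slope_max, v = 0:slope_max)
  g <- g[!(g$u == 0 & g$v == 0), ]
  keep <- mapply(function(u, v) {
    if (v == 0) u == 1 else {
      gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
      gcd(abs(u), v) == 1
    }
  }, g$u, g$v)
  g <- g[keep, ]
  g$deg <- atan2(g$v, g$u) * 180 / pi
  near <- vapply(g$deg, function(d)
    min(abs(ang_diff(d, c(0, 60, 120)))), 0) <= orient_tol_deg
  g[near, ]
}

#' @noRd
ang_diff <- function(a, b) ((a - b + 90) %% 180) - 90

#' Export an SLM pattern set and mask to disk
#'
#' One 1-bit PBM (portable bitmap, plain text) image per (wavelength,
#' angle, phase) in acquisition running order, plus a text table of mask
#' hole centres and radii. [read_pattern_bitmap()] round-trips the
#' bitmaps.
#'
#' @param pattern_set an `slm_pattern_set`.
#' @param mask a [fourier_mask()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
export_pattern_set <- function(pattern_set, mask, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (wi in seq_along(pattern_set$wavelengths_nm)) {
    for (ai in 1:3) {
      key <- sprintf("w%d_a%d", wi, ai)
      for (j in 1:3) {
        f <- file.path(dir, sprintf("pattern_%03.0fnm_a%d_p%d.pbm",
                                    pattern_set$wavelengths_nm[wi], ai, j - 1))
        write_pbm(pattern_set$patterns[[key]][[j]], f)
        files <- c(files, f)
      }
    }
  }
  mf <- file.path(dir, "mask_holes.tsv")
  utils::write.table(
    data.frame(x = mask$hole_positions[, 1], y = mask$hole_positions[, 2],
               radius = mask$hole_radius),
    mf, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, mf)
  invisible(files)
}

#' @noRd
write_pbm <- function(bitmap, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P1", sprintf("%d %d", ncol(bitmap), nrow(bitmap))), con)
  apply(ifelse(bitmap, 1L, 0L), 1, function(row)
    writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' @rdname export_pattern_set
#' @param path a PBM file written by [export_pattern_set()].
#' @export
read_pattern_bitmap <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  stopifnot(lines[1] == "P1")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
  matrix(vals == 1L, dims[2], dims[1], byrow = TRUE)
}
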
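test_that("phantoms: determinism, truth bookkeeping, kinds, preconditions", {
  a <- make_phantom("bead_clusters", c(128L, 128L), seed = 7, n = 5)
  b <- make_phantom("bead_clusters", c(128L, 128L), seed = 7, n = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$image >= 0) && all(is.finite(a$image)))
  # 0.2 um beads at 0.08 um pixels are 2.5 px disks in the truth table
  expect_equal(unique(a$truth$diameter_px), 2.5)
  p <- make_phantom("points", c(128L, 128L), centers = rbind(c(40.3, 70.6)))
  expect_equal(p$truth$x, 40.3)
  expect_equal(p$truth$y, 70.6)
  expect_equal(sum(p$image), 1)              # unit flux splat
  expect_error(make_phantom("vortex", c(128L, 128L)))
  expect_error(make_phantom("points", c(32L, 32L)), "at least 64")
  for (kind in c("lines", "siemens_star"))
    expect_true(all(make_phantom(kind, c(64L, 64L))$image >= 0))
})

test_that("sinusoidal illumination: closed form, unit mean, bounds", {
  I0 <- sinusoidal_illumination(c(64L, 64L), 0.08, c(2, 1), 0.3, 0)
  expect_true(all(I0 == 1))                  # m = 0: uniform
  I1 <- sinusoidal_illumination(c(64L, 64L), 0.08, c(2, 1), 0, 1)
  expect_equal(I1[1, 1], 2)                  # peak at r = 0, phi = 0
  # integer number of periods across the FOV -> mean exactly 1
  p <- c(6 / (256 * 0.08), 10 / (256 * 0.08))
  I2 <- sinusoidal_illumination(c(256L, 256L), 0.08, p, 1.1, 0.77)
  expect_equal(mean(I2), 1, tolerance = 1e-6)
  expect_error(sinusoidal_illumination(c(64L, 64L), 0.08, c(1, 0), 0, 1.2),
               "\\[0, 1\\]")
})

test_that("raw set simulation: frame count, order, noiseless oracle", {
  rs <- fix_raw256()
  expect_s3_class(rs, "raw_sim_set")
  expect_length(rs$frames, 9)
  expect_true(all(diff(rs$timestamps_ns) > 0))
  # m = 0 (uniform illumination): all 9 frames equal the wide-field blur
  il0 <- illumination_params(fix_p_true(), modulation = 1e-9,
                             angle_sep_tol_deg = 180)
  il0$modulation <- 0
  rs0 <- simulate_raw_set(fix_scene256(), il0, fix_otf256())
  wf <- simflow:::otf_blur(fix_scene256()$image, fix_otf256())
  wf[wf < 0] <- 0
  for (f in rs0$frames) expect_rel_equal(f, wf, 1e-12)
  # zero phantom + read noise -> frames are offset + noise, mean ~ offset
  z <- matrix(0, 256, 256)
  rsz <- simulate_raw_set(z, fix_illum(), fix_otf256(), photons_scale = 1000,
                          read_noise_e = 1.5, offset = 100, seed = 3)
  expect_equal(mean(rsz$frames[[1]]), 100, tolerance = 0.5)
  expect_error(simulate_raw_set(matrix(0, 64, 64), fix_illum(), fix_otf256()),
               "grids disagree")
  expect_error(simulate_raw_set(fix_scene256(), fix_illum(), fix_otf256(),
                                read_noise_e = -1), "negative")
})

test_that("point-source modulation: peak varies cosinusoidally with phase", {
  otf <- fix_otf128()
  ph <- make_phantom("points", c(128L, 128L), centers = rbind(c(64, 64)))
  il <- illumination_params(fix_p_true(), start_phase = c(0.3, 0, 0),
                            modulation = 1, angle_sep_tol_deg = 180)
  rs <- simulate_raw_set(ph, il, otf)
  peaks <- vapply(rs$frames[1:3], function(f) f[65, 65], 0)
  # I(r0) = 1 + cos(2 pi p.r0 + phi_j); solve the expected three values
  r0 <- c(64, 64) * 0.08
  phis <- 0.3 + 2 * pi * sum(fix_p_true()[1, ] * r0) + c(0, 2, 4) * pi / 3
  base <- simflow:::otf_blur(ph$image, otf)[65, 65]
  expect_rel_equal(peaks, base * (1 + cos(phis)), 0.01)
})

test_that("sum of 9 noiseless frames = 9 x wide-field (cosine cancellation)", {
  rs <- fix_raw256()
  s <- Reduce(`+`, rs$frames)
  wf <- simflow:::otf_blur(fix_scene256()$image, fix_otf256())
  wf[wf < 0] <- 0
  expect_rel_equal(s, 9 * wf, 1e-6)
})

test_that("Poisson mode: frame mean scales linearly with photons_scale", {
  means <- vapply(c(200, 400, 800), function(sc) {
    rs <- simulate_raw_set(fix_scene256(), fix_illum(), fix_otf256(),
                           photons_scale = sc, read_noise_e = 1.2,
                           offset = 100, seed = 42)
    mean(rs$frames[[1]]) - 100
  }, 0)
  fitted <- stats::lm(means ~ c(200, 400, 800))
  slope_rel <- stats::coef(fitted)[2] * 400 / means[2]
  expect_equal(unname(slope_rel), 1, tolerance = 0.02)
  # full determinism under a fixed seed
  a <- simulate_raw_set(fix_scene256(), fix_illum(), fix_otf256(),
                        photons_scale = 500, seed = 9)
  b <- simulate_raw_set(fix_scene256(), fix_illum(), fix_otf256(),
                        photons_scale = 500, seed = 9)
  expect_identical(a$frames, b$frames)
})

test_that("multichannel sequence: order, counts, misregistration truth", {
  otf <- fix_otf128()
  ph <- make_phantom("points", c(128L, 128L),
                     centers = rbind(c(50, 60), c(80, 40), c(64, 90)))
  il <- default_illumination(otf)
  msgs <- simulate_multichannel_sequence(list(ph), list(il), list(otf),
                                         n_timepoints = 2L)
  expect_length(msgs, 18)
  expect_equal(vapply(msgs, `[[`, 0L, "sequence_index"), 0:17)
  expect_true(all(diff(vapply(msgs, `[[`, 0, "timestamp_ns")) > 0))
  # identity misregistration: channels pixel-aligned
  msgs2 <- simulate_multichannel_sequence(list(ph, ph), list(il, il),
                                          list(otf, otf), 1L)
  i1 <- msgs2[[1]]$image; i2 <- msgs2[[2]]$image
  expect_equal(i1, i2, tolerance = 1e-12)
  # 3 px shift on channel 2 moves bead centroids by 3 px
  tr <- cbind(diag(2), c(3, 0))
  msgs3 <- simulate_multichannel_sequence(list(ph, ph), list(il, il),
                                          list(otf, otf), 1L,
                                          misregistration = list(NULL, tr))
  wf1 <- Reduce(`+`, lapply(msgs3[seq(1, 18, 2)], `[[`, "image")) / 9
  wf2 <- Reduce(`+`, lapply(msgs3[seq(2, 18, 2)], `[[`, "image")) / 9
  c1 <- simflow:::detect_bead_centroids(wf1, min_sep_px = 10)
  c2 <- simflow:::detect_bead_centroids(wf2, min_sep_px = 10)
  ord1 <- order(c1[, 2]); ord2 <- order(c2[, 2])
  d <- c1[ord1, 1] - c2[ord2, 1]
  expect_equal(mean(d), 3, tolerance = 0.1)
  expect_error(simulate_multichannel_sequence(rep(list(ph), 4),
                                              rep(list(il), 4),
                                              rep(list(otf), 4)),
               "1-3")
})
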
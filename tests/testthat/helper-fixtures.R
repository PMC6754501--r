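# Shared fixtures, built once per test run. Estimation-grade scenes are
# dense (many emitters) so the wave-vector correlation is not speckle
# limited; geometry mirrors the instrument defaults (80 nm pixels,
# NA 1.33, 515 nm emission) at a reduced 256 grid for speed.

fixture_env <- new.env()

fix_otf256 <- function() {
  if (is.null(fixture_env$otf256))
    fixture_env$otf256 <- otf_model(1.33, 0.515, 0.08, c(256L, 256L))
  fixture_env$otf256
}

fix_otf128 <- function() {
  if (is.null(fixture_env$otf128))
    fixture_env$otf128 <- otf_model(1.33, 0.515, 0.08, c(128L, 128L))
  fixture_env$otf128
}

# off-grid wave vectors, ~60 deg apart, |p| ~ 0.67 k_c
fix_p_true <- function() rbind(c(1.6, 3.1), c(-2.9, 1.73), c(1.33, -3.05))

fix_illum <- function(modulation = 0.8, start_phase = c(1.0, 0.4, -0.7)) {
  illumination_params(fix_p_true(), start_phase = start_phase,
                      modulation = modulation,
                      cutoff = fix_otf256()$cutoff, angle_sep_tol_deg = 180)
}

fix_scene256 <- function() {
  if (is.null(fixture_env$scene256))
    fixture_env$scene256 <- make_phantom("lines", c(256L, 256L), seed = 5, n = 30)
  fixture_env$scene256
}

fix_raw256 <- function() {
  if (is.null(fixture_env$raw256))
    fixture_env$raw256 <- simulate_raw_set(fix_scene256(), fix_illum(),
                                           fix_otf256())
  fixture_env$raw256
}

fix_otf512 <- function() {
  if (is.null(fixture_env$otf512))
    fixture_env$otf512 <- otf_model(1.33, 0.515, 0.08, c(512L, 512L))
  fixture_env$otf512
}

fix_raw512 <- function() {
  if (is.null(fixture_env$raw512)) {
    scene <- make_phantom("lines", c(512L, 512L), seed = 5, n = 60)
    il <- illumination_params(fix_p_true(), start_phase = c(1.0, 0.4, -0.7),
                              modulation = 0.8, cutoff = fix_otf512()$cutoff,
                              angle_sep_tol_deg = 180)
    fixture_env$raw512 <- simulate_raw_set(scene, il, fix_otf512())
  }
  fixture_env$raw512
}

# wrap angle differences to (-pi, pi]
wrap_angle <- function(x) ((x + pi) %% (2 * pi)) - pi

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), rel_tol)
}
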
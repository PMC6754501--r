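test_that("TIFF writer/reader round-trips 16-bit and float pages", {
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  set.seed(1)
  imgs <- list(matrix(sample(0:65535, 40 * 32, TRUE), 32, 40),
               matrix(sample(0:65535, 40 * 32, TRUE), 32, 40))
  write_tiff(imgs, path, 16L, c('{"p":0}', '{"p":1}'))
  back <- read_tiff(path)
  expect_identical(back$images,
                   lapply(imgs, function(m) matrix(as.integer(m), 32, 40)))
  expect_identical(back$descriptions, c('{"p":0}', '{"p":1}'))
  m <- matrix(rnorm(30), 5, 6)
  write_tiff(m, path, 32L)
  expect_equal(read_tiff(path)$images[[1]], m, tolerance = 1e-6)
  expect_error(write_tiff(matrix(-1, 4, 4), path, 16L), "range")
  expect_error(read_tiff(tempfile()), "cannot")
})

test_that("our TIFF files agree with the Python tifffile oracle", {
  path <- tempfile(fileext = ".tif")
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, csv)))
  set.seed(2)
  img <- matrix(sample(0:65535, 24 * 16, TRUE), 16, 24)
  write_tiff(list(img), path, 16L, "oracle-page")
  out <- system2("python", c("-c", shQuote(sprintf(
    "import tifffile, numpy as np\na = tifffile.imread('%s')\nnp.savetxt('%s', a, fmt='%%d', delimiter=',')\nprint(tifffile.TiffFile('%s').pages[0].description)",
    path, csv, path))), stdout = TRUE, stderr = TRUE)
  oracle <- as.matrix(utils::read.csv(csv, header = FALSE))
  dimnames(oracle) <- NULL
  expect_identical(oracle, matrix(as.integer(img), 16, 24))
  expect_true(any(grepl("oracle-page", out)))
  # and we read tifffile's own output
  py <- tempfile(fileext = ".tif")
  on.exit(unlink(py), add = TRUE)
  system2("python", c("-c", shQuote(sprintf(
    "import tifffile, numpy as np\ntifffile.imwrite('%s', np.arange(12, dtype=np.uint16).reshape(3, 4))",
    py))))
  expect_identical(read_tiff(py)$images[[1]], matrix(0:11, 3, 4, byrow = TRUE))
})

test_that("raw stacks round-trip with metadata; page counts validated", {
  otf <- fix_otf128()
  ph <- make_phantom("bead_clusters", c(128L, 128L), seed = 3, n = 8)
  il <- default_illumination(otf)
  sets <- lapply(1:3, function(i)
    simulate_raw_set(ph, il, otf, photons_scale = 500, seed = i,
                     channel_id = 2L, t0_ns = i * 1e8))
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_raw_stack(sets, path)
  back <- read_raw_stack(path)
  expect_length(back, 3)                     # 27 pages -> 3 SIM sets
  for (i in 1:3) {
    expect_identical(back[[i]]$frames,
                     lapply(sets[[i]]$frames, function(m)
                       matrix(as.integer(m), 128, 128)))
    expect_identical(back[[i]]$channel_id, 2L)
    expect_equal(back[[i]]$timestamps_ns, sets[[i]]$timestamps_ns)
  }
  # 17 pages is not a raw stack
  write_tiff(rep(list(matrix(0, 8, 8)), 17), path, 16L)
  expect_error(read_raw_stack(path), "multiple of 9")
})

test_that("reconstruction TIFFs carry metadata and float pages", {
  otf <- fix_otf128()
  ph <- make_phantom("points", c(128L, 128L), centers = rbind(c(64, 64)))
  il <- default_illumination(otf)
  rec <- reconstruct_set(simulate_raw_set(ph, il, otf), il, otf)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_reconstruction(rec, path, meta = list(seed = 7), include_widefield = TRUE)
  back <- read_tiff(path)
  expect_length(back$images, 2)
  expect_identical(dim(back$images[[1]]), c(256L, 256L))
  expect_identical(dim(back$images[[2]]), c(128L, 128L))
  meta <- jsonlite::fromJSON(back$descriptions[1])
  expect_identical(meta$seed, 7L)
  expect_identical(meta$page, "sim")
  expect_equal(back$images[[1]], rec$sim, tolerance = 1e-6)
})

test_that("config: defaults validate, unknown keys rejected with location", {
  cfg <- run_config()
  expect_s3_class(cfg, "run_config")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$optics$na, cfg$optics$na)
  expect_identical(simflow:::config_hash(back), simflow:::config_hash(cfg))
  expect_error(run_config(optics = list(na = 1.33, typo_key = 1)),
               "unknown configuration key.*optics.*typo_key")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$surprise <- 1
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_error(read_config(path), "top level.*surprise")
  expect_error(run_config(optics = list(na = 2.5)), "na")
})

test_that("cli: simulate is reproducible, reconstruct demands parameters", {
  dir <- tempfile("cli")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- run_config(optics = list(na = 1.33, em_wavelength_um = 0.515,
                                  pixel_size_um = 0.08, grid = c(128L, 128L)))
  cfg_path <- file.path(dir, "config.json")
  write_config(cfg, cfg_path)
  out1 <- file.path(dir, "a.tif"); out2 <- file.path(dir, "b.tif")
  args <- function(out) c("simulate", "--phantom", "bead_clusters",
                          "--seed", "7", "--config", cfg_path, "--out", out)
  expect_identical(suppressMessages(cli(args(out1))), 0L)
  expect_identical(suppressMessages(cli(args(out2))), 0L)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  # reconstruct without --params refuses with instructions
  expect_identical(suppressMessages(
    cli(c("reconstruct", "--raw", out1, "--config", cfg_path))), 1L)
  # estimate then reconstruct end to end
  params <- file.path(dir, "params.json")
  expect_identical(suppressMessages(
    cli(c("estimate", "--raw", out1, "--config", cfg_path,
          "--out", params))), 0L)
  recon <- file.path(dir, "recon.tif")
  expect_identical(suppressMessages(
    cli(c("reconstruct", "--raw", out1, "--params", params,
          "--config", cfg_path, "--out", recon))), 0L)
  expect_identical(dim(read_tiff(recon)$images[[1]]), c(256L, 256L))
  # plan-timing prints the printed anchor cell
  txt <- capture.output(suppressMessages(
    cli(c("plan-timing", "--channels", "3", "--exposure", "1",
          "--lines", "512"))))
  expect_true(any(grepl("\\b25\\b", txt)))
  expect_identical(suppressMessages(cli(c("no-such-command"))), 1L)
  expect_identical(suppressMessages(cli(character(0))), 1L)
})
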
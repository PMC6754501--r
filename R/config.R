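#' Run configuration
#'
#' Single structured-text (JSON) configuration for the whole tool:
#' optics per channel, illumination defaults, reconstruction settings,
#' acquisition timing, stream settings, output paths, the global RNG
#' seed, and a free-text sample-metadata block (cell type, dyes,
#' excitation wavelengths, ...). Unknown keys are rejected with their
#' location; the seed and a config hash are recorded in all outputs so
#' every artifact is reproducible.
#'
#' @param optics list: `na`, `em_wavelength_um` (per channel),
#'   `pixel_size_um`, `grid` (rows/cols).
#' @param illumination list: `pattern_freq_frac`, `orientation_deg`,
#'   `modulation`.
#' @param recon named list of [recon_settings()] arguments.
#' @param timing named list of [timing_config()] arguments.
#' @param stream list: `capacity`, `consume_every`.
#' @param output list: `dir`.
#' @param seed integer RNG seed.
#' @param sample_meta free-form named list.
#' @return object of class `run_config`.
#' @export
run_config <- function(optics = list(na = 1.33,
                                     em_wavelength_um = c(0.515, 0.600, 0.670),
                                     pixel_size_um = 0.08,
                                     grid = c(512L, 512L)),
                       illumination = list(pattern_freq_frac = 0.8,
                                           orientation_deg = 13,
                                           modulation = 1),
                       recon = list(),
                       timing = list(),
                       stream = list(capacity = 8L, consume_every = 1L),
                       output = list(dir = "."),
                       seed = 1L,
                       sample_meta = list()) {
  cfg <- structure(list(optics = optics, illumination = illumination,
                        recon = recon, timing = timing, stream = stream,
                        output = output, seed = as.integer(seed),
                        sample_meta = sample_meta),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  known <- list(
    .top = c("optics", "illumination", "recon", "timing", "stream",
             "output", "seed", "sample_meta"),
    optics = c("na", "em_wavelength_um", "pixel_size_um", "grid"),
    illumination = c("pattern_freq_frac", "orientation_deg", "modulation"),
    recon = names(formals(recon_settings)),
    timing = names(formals(timing_config)),
    stream = c("capacity", "consume_every"),
    output = c("dir"))
  for (sec in names(known)) {
    block <- if (sec == ".top") cfg else cfg[[sec]]
    if (is.null(block)) next
    extra <- setdiff(names(block), known[[sec]])
    if (length(extra))
      stop(sprintf("unknown configuration key%s at '%s': %s",
                   if (length(extra) > 1) "s" else "",
                   if (sec == ".top") "<top level>" else sec,
                   paste(extra, collapse = ", ")))
  }
  if (!is.numeric(cfg$optics$na) || cfg$optics$na <= 0 || cfg$optics$na >= 2)
    stop("optics$na out of range at 'optics'")
  if (cfg$optics$pixel_size_um <= 0) stop("optics$pixel_size_um must be positive")
  invisible(cfg)
}

#' @rdname run_config
#' @param path JSON file.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(raw), c("optics", "illumination", "recon", "timing",
                                 "stream", "output", "seed", "sample_meta"))
  if (length(extra))
    stop(sprintf("unknown configuration key(s) at <top level> in %s: %s",
                 path, paste(extra, collapse = ", ")))
  args <- raw
  if (!is.null(args$optics$grid)) args$optics$grid <- as.integer(args$optics$grid)
  do.call(run_config, args)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Short stable hash of a configuration for output provenance (FNV-1a
# over the serialized JSON; avoids a digest dependency).
#' @noRd
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @noRd
otf_from_config <- function(cfg, channel = 1L) {
  otf_model(cfg$optics$na, cfg$optics$em_wavelength_um[channel],
            cfg$optics$pixel_size_um, cfg$optics$grid)
}
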
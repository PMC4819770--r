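#' Run configuration
#'
#' A flat YAML-backed configuration covering every tunable of the
#' pipeline: per-channel optics, frame geometry, camera model, QC
#' thresholds, fit method and tolerance, registration parameters, pairing
#' gate, histogram bin width, simulation scene parameters, and the run
#' seed. Values from the YAML file (and then from `...`) override the
#' defaults; a `null` (or otherwise invalid) required field raises a
#' validation error naming the field.
#'
#' @param path Optional YAML file path.
#' @param ... Named overrides (nested lists merge recursively).
#' @return A validated `run_config` list.
#' @examples
#' cfg <- run_config()
#' cfg$channels$a$wavelength_nm
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- modifyList(cfg, read_yaml(path))
  dots <- list(...)
  if (length(dots)) cfg <- modifyList(cfg, dots)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

default_config <- function() {
  list(
    channels = list(
      a = list(wavelength_nm = 594, numerical_aperture = 1.45),
      b = list(wavelength_nm = 647, numerical_aperture = 1.45)),
    frame = list(width_px = 64, height_px = 64, pixel_size_nm = 200),
    camera = list(gain = 1, read_noise_e = 2),
    background_photons_per_px = 10,
    qc = list(snr_min = 3, gaussian_min = 0.7, contrast_min = 5, k_mad = 5),
    fit = list(method = "lsq", tol = 1e-4, max_iterations = 100),
    registration = list(k = 12, grid_pitch_px = 8, max_pair_dist_nm = 500),
    pairing = list(gate_nm = 200),
    histogram = list(bin_width_nm = 30),
    simulate = list(n_scenes = 10, pairs_per_scene = 4, separation_nm = 0,
                    photons = 150, n_beads = 30, warp_max_nm = 30,
                    bead_photons = 20000),
    seed = 1
  )
}

validate_config <- function(cfg) {
  required <- list(
    "channels.a.wavelength_nm" = function(v) is.numeric(v) && v >= 300 && v <= 900,
    "channels.a.numerical_aperture" = function(v) is.numeric(v) && v > 0 && v <= 1.7,
    "channels.b.wavelength_nm" = function(v) is.numeric(v) && v >= 300 && v <= 900,
    "channels.b.numerical_aperture" = function(v) is.numeric(v) && v > 0 && v <= 1.7,
    "frame.width_px" = function(v) is.numeric(v) && v >= 8,
    "frame.height_px" = function(v) is.numeric(v) && v >= 8,
    "frame.pixel_size_nm" = function(v) is.numeric(v) && v > 0,
    "camera.gain" = function(v) is.numeric(v) && v > 0,
    "camera.read_noise_e" = function(v) is.numeric(v) && v >= 0,
    "background_photons_per_px" = function(v) is.numeric(v) && v >= 0,
    "qc.snr_min" = function(v) is.numeric(v),
    "fit.tol" = function(v) is.numeric(v) && v > 0,
    "fit.max_iterations" = function(v) is.numeric(v) && v >= 1,
    "registration.k" = function(v) is.numeric(v) && v >= 6,
    "pairing.gate_nm" = function(v) is.numeric(v) && v > 0,
    "histogram.bin_width_nm" = function(v) is.numeric(v) && v > 0,
    "seed" = function(v) is.numeric(v)
  )
  for (key in names(required)) {
    v <- cfg[[strsplit(key, ".", fixed = TRUE)[[1]]]]
    if (is.null(v) || !required[[key]](v)) {
      nanosep_abort(sprintf("Invalid or missing config field `%s`.", key),
                    "nanosep_config_error")
    }
  }
  invisible(cfg)
}

config_frame <- function(cfg) {
  frame_geometry(cfg$frame$width_px, cfg$frame$height_px,
                 cfg$frame$pixel_size_nm)
}

config_optics <- function(cfg, channel) {
  ch <- cfg$channels[[channel]]
  optics_model(ch$wavelength_nm, ch$numerical_aperture)
}

config_noise <- function(cfg) {
  noise_model(cfg$background_photons_per_px, cfg$camera$read_noise_e,
              cfg$camera$gain)
}

flatten_config <- function(cfg, prefix = character(0)) {
  out <- character(0)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    key <- paste(c(prefix, nm), collapse = ".")
    if (is.list(v)) {
      out <- c(out, flatten_config(v, c(prefix, nm)))
    } else {
      out <- c(out, sprintf("%s: %s", key, paste(format(v), collapse = ",")))
    }
  }
  out
}

#' Write a result table with its configuration fingerprint
#'
#' Every output table carries the full flattened configuration as `#`
#' comment lines before the TSV body, so any result can be traced to the
#' exact thresholds that produced it. Read back with
#' `readr::read_tsv(path, comment = "#")`.
#'
#' @param tbl Tibble to write.
#' @param path Output path.
#' @param config A `run_config` (optional).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tbl, path, config = NULL) {
  header <- c("# nanosep result table",
              sprintf("# nanosep_version: %s",
                      as.character(utils::packageVersion("nanosep"))))
  if (!is.null(config)) {
    header <- c(header, paste0("# config. ", flatten_config(config)))
  }
  drop <- map_lgl(tbl, is.list)
  if (any(drop)) {
    tbl <- mutate(tbl, dplyr::across(dplyr::where(is.list),
                                     ~ map_chr(.x, paste, collapse = ";")))
  }
  writeLines(header, path)
  suppressMessages(write_tsv(tbl, path, append = TRUE, col_names = TRUE))
  invisible(path)
}
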
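#' Build a run configuration
#'
#' Bundles the preprocessing, optimizer and imaging settings consumed by
#' [run_optimize()] and the command-line front end, with validation and a
#' lossless YAML round-trip via [read_band_config()] /
#' [write_band_config()].
#'
#' @param window_nm Smoothing window (nm).
#' @param range_lo_nm,range_hi_nm Working wavelength range (nm).
#' @param grid_step_nm Working grid step (nm).
#' @param baseline_mode `"constant-min"` or `"dark-reference"`.
#' @param step_nm Band-edge lattice spacing (nm).
#' @param min_width_nm Minimum band width (nm).
#' @param match_tolerance Relative efficiency tolerance for
#'   [match_at_efficiency()].
#' @param reference Reference band pair as a length-4 numeric vector, or
#'   NULL.
#' @param bin Spatial binning factor for ratiometric images (currently 1
#'   or 2).
#' @param resolution_um Theoretical resolution for [fft_snr()].
#' @param seed Integer seed for any stochastic step.
#' @return A validated list of class `band_config`.
#' @export
band_config <- function(window_nm = 10, range_lo_nm = 425, range_hi_nm = 650,
                        grid_step_nm = 1, baseline_mode = "constant-min",
                        step_nm = 5, min_width_nm = step_nm,
                        match_tolerance = 0.001,
                        reference = c(410, 490, 510, 650),
                        bin = 2, resolution_um = 0.785 / (2 * 0.8),
                        seed = 1L) {
  cfg <- list(window_nm = window_nm, range_lo_nm = range_lo_nm,
              range_hi_nm = range_hi_nm, grid_step_nm = grid_step_nm,
              baseline_mode = baseline_mode, step_nm = step_nm,
              min_width_nm = min_width_nm, match_tolerance = match_tolerance,
              reference = reference, bin = bin,
              resolution_um = resolution_um, seed = as.integer(seed))
  validate_band_config(cfg)
}

validate_band_config <- function(cfg) {
  stopifnot(
    cfg$window_nm > 0,
    cfg$range_lo_nm < cfg$range_hi_nm,
    cfg$grid_step_nm > 0,
    cfg$baseline_mode %in% c("constant-min", "dark-reference"),
    cfg$step_nm >= cfg$grid_step_nm,
    cfg$min_width_nm >= 0,
    cfg$match_tolerance > 0,
    is.null(cfg$reference) || length(cfg$reference) == 4,
    cfg$bin %in% c(1, 2),
    cfg$resolution_um > 0
  )
  structure(cfg, class = "band_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_band_config()`, a `band_config`; for
#'   `write_band_config()`, `path` invisibly.
#' @export
read_band_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- unclass(band_config())
  base[names(raw)] <- raw
  if (!is.null(base$reference)) base$reference <- as.numeric(base$reference)
  validate_band_config(base)
}

#' @rdname read_band_config
#' @param cfg A `band_config`.
#' @export
write_band_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "band_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full band-optimization pipeline on two spectrum files
#'
#' Reads two raw emission spectra, preprocesses each (baseline,
#' smoothing, crop, resampling, PMF normalization), scores every
#' non-overlapping band pair, extracts the Pareto front, and — when a
#' reference setup is configured — finds the efficiency-matched improved
#' pair. Writes `pairs.csv` (all evaluated pairs, losslessly re-loadable),
#' `front.csv`, `summary.csv` and `scatter.png` under `out_dir`.
#'
#' @param spectrum_a,spectrum_b Paths to delimited spectrum files.
#' @param config A [band_config()].
#' @param out_dir Output directory (created if missing).
#' @param plot Also write the scatter figure (default TRUE).
#' @return Invisibly, a list with the `band_optimization` object, the
#'   front and summary tibbles and the written file paths.
#' @export
run_optimize <- function(spectrum_a, spectrum_b, config = band_config(),
                         out_dir = ".", plot = TRUE) {
  stopifnot(inherits(config, "band_config"))
  for (p in c(spectrum_a, spectrum_b)) {
    if (!file.exists(p)) stop("Spectrum file not found: ", p, call. = FALSE)
  }
  prep <- function(path) {
    read_spectrum(path) |>
      preprocess_spectrum(window_nm = config$window_nm,
                          range_lo_nm = config$range_lo_nm,
                          range_hi_nm = config$range_hi_nm,
                          step_nm = config$grid_step_nm,
                          baseline_mode = config$baseline_mode)
  }
  s1 <- prep(spectrum_a)
  s2 <- prep(spectrum_b)
  res <- optimize_bands(s1, s2, step_nm = config$step_nm,
                        min_width_nm = config$min_width_nm)
  front <- pareto_front(res)
  summary_tbl <- glance(res)
  if (!is.null(config$reference)) {
    ref <- as_band_pair(config$reference)
    matched <- match_at_efficiency(res, ref,
                                   rel_tolerance = config$match_tolerance)
    summary_tbl <- dplyr::bind_cols(
      summary_tbl,
      dplyr::rename_with(matched, ~ paste0("matched_", .x))
    )
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(pairs = file.path(out_dir, "pairs.csv"),
                front = file.path(out_dir, "front.csv"),
                summary = file.path(out_dir, "summary.csv"))
  readr::write_csv(res$pairs, paths$pairs)
  readr::write_csv(front, paths$front)
  readr::write_csv(summary_tbl, paths$summary)
  if (plot) {
    paths$plot <- file.path(out_dir, "scatter.png")
    gg <- autoplot(res, reference = config$reference)
    ggplot2::ggsave(paths$plot, gg, width = 6, height = 4.5, dpi = 150)
  }
  invisible(list(result = res, front = front, summary = summary_tbl,
                 paths = paths))
}

#' Run the imaging pipeline on a hyperspectral cube
#'
#' Integrates the cube over the two configured bands, builds the
#' cyan/red composite and the binned ratiometric image, and reports the
#' per-channel and ratiometric frequency-domain SNRs.
#'
#' @param cube A `hyperspectral_cube`.
#' @param band1,band2 Length-2 numeric vectors (start, end) in nm; band 1
#'   feeds the cyan channel, band 2 the red channel.
#' @param config A [band_config()] (bin factor and resolution are used).
#' @return A list: `cyan`, `red` (channel images), `composite`,
#'   `ratio` (binned ratiometric matrix), `snr` (tibble with one row per
#'   image: cyan, red, ratio), `redox_mean`.
#' @export
run_imaging <- function(cube, band1, band2, config = band_config()) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  cyan <- integrate_band(cube, band1[1], band1[2])
  red <- integrate_band(cube, band2[1], band2[2])
  composite <- two_channel_composite(cyan, red)
  ratio <- ratiometric_image(red, cyan)
  if (config$bin == 2) ratio <- bin2x2(ratio)
  snr <- dplyr::bind_rows(
    cyan = fft_snr(cyan$data, config$resolution_um, cube$pixel_size_um),
    red = fft_snr(red$data, config$resolution_um, cube$pixel_size_um),
    ratio = fft_snr(ratio, config$resolution_um,
                    cube$pixel_size_um * config$bin),
    .id = "image"
  )
  list(cyan = cyan, red = red, composite = composite, ratio = ratio,
       snr = snr, redox_mean = redox_per_image(ratio))
}
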
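#' Construct a hyperspectral image cube
#'
#' A cube holds one full emission spectrum per pixel: a 3-D array indexed
#' (row, col, wavelength) with an increasing wavelength axis and the
#' physical pixel pitch in micrometres.
#'
#' @param data 3-D numeric array, non-negative, dims (rows, cols,
#'   wavelengths).
#' @param wavelengths_nm Increasing numeric vector matching the third
#'   dimension.
#' @param pixel_size_um Pixel pitch in micrometres (> 0).
#' @return An object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(data, wavelengths_nm, pixel_size_um = 1) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3-D array (row, col, wavelength).", call. = FALSE)
  }
  if (length(wavelengths_nm) != dim(data)[3]) {
    stop("`wavelengths_nm` length (", length(wavelengths_nm),
         ") must match the third dimension (", dim(data)[3], ").",
         call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("`wavelengths_nm` must be strictly increasing.", call. = FALSE)
  }
  if (any(data < 0)) stop("Cube intensities must be >= 0.", call. = FALSE)
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0.", call. = FALSE)
  structure(list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
                 pixel_size_um = pixel_size_um),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Hyperspectral cube: %d x %d pixels, %d wavelengths (%g-%g nm), %g um/px\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$pixel_size_um))
  invisible(x)
}

#' Read a hyperspectral cube from a multi-page TIFF and wavelength sidecar
#'
#' One TIFF page per wavelength plane, plus a CSV sidecar listing the
#' wavelengths (column `wavelength_nm`, or the first column) in page order.
#'
#' @param tiff_path Multi-page TIFF stack.
#' @param wavelengths_path CSV sidecar with wavelengths in page order.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param scale Multiplies the TIFF's unit-range samples back to counts
#'   (default 1).
#' @return A `hyperspectral_cube`.
#' @export
read_cube <- function(tiff_path, wavelengths_path, pixel_size_um = 1,
                      scale = 1) {
  if (!file.exists(tiff_path)) {
    stop("Cube TIFF not found: ", tiff_path, call. = FALSE)
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  wl_tbl <- readr::read_csv(wavelengths_path, show_col_types = FALSE)
  wl <- if ("wavelength_nm" %in% names(wl_tbl)) {
    wl_tbl$wavelength_nm
  } else {
    wl_tbl[[1]]
  }
  if ("scale" %in% names(wl_tbl)) scale <- wl_tbl$scale[[1]]
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
  hyperspectral_cube(arr, wl, pixel_size_um)
}

#' Write a hyperspectral cube to a multi-page TIFF and wavelength sidecar
#'
#' Samples are stored scaled to the unit range; the scale factor is
#' recorded in the sidecar so [read_cube()] restores the original counts.
#'
#' @param cube A `hyperspectral_cube`.
#' @param tiff_path Output TIFF path.
#' @param wavelengths_path Output CSV sidecar path.
#' @return `tiff_path`, invisibly.
#' @export
write_cube <- function(cube, tiff_path, wavelengths_path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  scale <- max(cube$data, 1e-12)
  pages <- lapply(seq_along(cube$wavelengths_nm), function(i) {
    cube$data[, , i] / scale
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32)
  readr::write_csv(tibble::tibble(wavelength_nm = cube$wavelengths_nm,
                                  scale = scale),
                   wavelengths_path)
  invisible(tiff_path)
}

#' Integrate a cube over one spectral band
#'
#' Per-pixel sum of the wavelength planes with
#' `start_nm <= wavelength <= end_nm` (closed interval) — the image a
#' detector behind an ideal band-pass filter would record.
#'
#' @param cube A `hyperspectral_cube`.
#' @param start_nm,end_nm Band edges in nm.
#' @return A `channel_image`: list with `data` (matrix) and `band`.
#' @export
integrate_band <- function(cube, start_nm, end_nm) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  if (start_nm > end_nm) stop("`start_nm` must be <= `end_nm`.", call. = FALSE)
  sel <- which(cube$wavelengths_nm >= start_nm &
                 cube$wavelengths_nm <= end_nm)
  if (length(sel) == 0) {
    stop("Band [", start_nm, ", ", end_nm,
         "] nm covers no cube wavelength plane.", call. = FALSE)
  }
  img <- apply(cube$data[, , sel, drop = FALSE], c(1, 2), sum)
  structure(list(data = img, band = c(start_nm = start_nm, end_nm = end_nm)),
            class = "channel_image")
}

channel_matrix <- function(x, arg = "channel") {
  if (inherits(x, "channel_image")) return(x$data)
  if (is.matrix(x)) return(x)
  stop("`", arg, "` must be a channel_image or a matrix.", call. = FALSE)
}

#' Two-channel cyan/red false-colour composite
#'
#' Each channel is scaled relative to its own histogram so that
#' mean - 2*sd maps to 0 and mean + 5*sd maps to 1 (values outside are
#' clipped, never wrapped), then assembled with the red channel on R and
#' the cyan channel on G and B.
#'
#' @param cyan,red `channel_image`s or matrices of matching shape.
#' @return An (rows, cols, 3) RGB array in \[0, 1\] of class
#'   `composite_image`, with attribute `limits` recording the per-channel
#'   scaling window.
#' @export
two_channel_composite <- function(cyan, red) {
  cy <- channel_matrix(cyan, "cyan")
  rd <- channel_matrix(red, "red")
  if (!all(dim(cy) == dim(rd))) {
    stop("`cyan` and `red` must have the same shape.", call. = FALSE)
  }
  scale_channel <- function(img, label) {
    m <- mean(img)
    s <- stats::sd(img)
    if (!is.finite(s) || s == 0) {
      warning("Zero-variance ", label, " channel; rendering it flat 0.5.",
              call. = FALSE)
      return(list(img = array(0.5, dim(img)), limits = c(m, m)))
    }
    lo <- m - 2 * s
    hi <- m + 5 * s
    list(img = pmin(pmax((img - lo) / (hi - lo), 0), 1), limits = c(lo, hi))
  }
  sc <- scale_channel(cy, "cyan")
  sr <- scale_channel(rd, "red")
  out <- array(0, dim = c(dim(cy), 3))
  out[, , 1] <- sr$img
  out[, , 2] <- sc$img
  out[, , 3] <- sc$img
  structure(out, limits = list(cyan = sc$limits, red = sr$limits),
            class = c("composite_image", "array"))
}

#' Ratiometric (redox-type) image from two channels
#'
#' Per-pixel red / (red + cyan). With the blue band on the cyan channel
#' (NAD(P)H-weighted) and the red band on the red channel (FAD-weighted),
#' this is an optical redox ratio. Pixels with zero total signal are
#' undefined (`NA`) and excluded from downstream statistics.
#'
#' @param red,cyan `channel_image`s or matrices of matching shape.
#' @return A matrix of ratios in \[0, 1\], `NA` where red + cyan = 0.
#' @export
ratiometric_image <- function(red, cyan) {
  rd <- channel_matrix(red, "red")
  cy <- channel_matrix(cyan, "cyan")
  if (!all(dim(cy) == dim(rd))) {
    stop("`red` and `cyan` must have the same shape.", call. = FALSE)
  }
  tot <- rd + cy
  out <- rd / tot
  out[tot == 0] <- NA_real_
  out
}

#' 2x2 binning of an image
#'
#' Replaces each non-overlapping 2x2 block by its mean, halving both
#' dimensions and raising per-pixel SNR; a trailing odd row or column is
#' dropped.
#'
#' @param img Matrix, at least 2x2.
#' @return Matrix of halved dimensions.
#' @export
bin2x2 <- function(img) {
  img <- channel_matrix(img, "img")
  nr <- nrow(img) %/% 2L
  nc <- ncol(img) %/% 2L
  if (nr < 1 || nc < 1) stop("`img` must be at least 2x2.", call. = FALSE)
  img <- img[seq_len(2L * nr), seq_len(2L * nc), drop = FALSE]
  (img[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
     img[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
     img[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE] +
     img[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE]) / 4
}

fft_freq <- function(n, d) {
  k <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))
  k / (n * d)
}

#' Frequency-domain SNR of an image
#'
#' Power spectrum via the 2-D FFT; spatial frequencies above the cutoff
#' `f_c = cutoff_factor / resolution_um` are treated as noise, lower
#' (non-DC) frequencies as signal, and the SNR is the ratio of the
#' integrated power in the two regions. With the default
#' `cutoff_factor = 4` the cutoff sits at four times the resolution-limit
#' frequency `1/r`; set `cutoff_factor = 0.25` for the alternative
#' reading `f_c = 1/(4 r)`. The DC term is excluded from both integrals,
#' so the SNR is invariant to constant offsets.
#'
#' @param img Non-constant numeric matrix (`NA`s replaced by the image
#'   mean before transforming).
#' @param resolution_um Theoretical lateral resolution in micrometres; the
#'   default is the two-photon estimate `lambda_exc / (2 NA)` with a
#'   0.785 um excitation wavelength and NA 0.8.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param cutoff_factor Multiplier on the resolution-limit frequency.
#' @return A one-row tibble (class `snr_report`): `snr`,
#'   `cutoff_cycles_per_um`, `resolution_um`, `pixel_size_um`,
#'   `cutoff_factor`, `signal_power`, `noise_power`, `infinite` (TRUE when
#'   no power lies above the cutoff).
#' @export
fft_snr <- function(img, resolution_um = 0.785 / (2 * 0.8),
                    pixel_size_um = 1, cutoff_factor = 4) {
  img <- channel_matrix(img, "img")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0.", call. = FALSE)
  if (resolution_um <= 0) stop("`resolution_um` must be > 0.", call. = FALSE)
  if (anyNA(img)) img[is.na(img)] <- mean(img, na.rm = TRUE)
  if (all(img == 0)) stop("`img` is identically zero.", call. = FALSE)
  if (stats::sd(img) == 0) {
    stop("`img` is constant; its SNR is undefined.", call. = FALSE)
  }
  power <- Mod(stats::fft(img))^2
  fr <- fft_freq(nrow(img), pixel_size_um)
  fc_ <- fft_freq(ncol(img), pixel_size_um)
  f <- sqrt(outer(fr^2, fc_^2, `+`))
  cutoff <- cutoff_factor / resolution_um
  signal <- sum(power[f > 0 & f <= cutoff])
  noise <- sum(power[f > cutoff])
  # FFT round-off leaves ~1e-30 relative power in empty bands; treat
  # noise below 1e-12 of the signal power as an empty noise band
  infinite <- noise <= 1e-12 * signal
  out <- tibble::tibble(
    snr = if (infinite) Inf else signal / noise,
    cutoff_cycles_per_um = cutoff,
    resolution_um = resolution_um,
    pixel_size_um = pixel_size_um,
    cutoff_factor = cutoff_factor,
    signal_power = signal,
    noise_power = noise,
    infinite = infinite
  )
  class(out) <- c("snr_report", class(out))
  out
}

#' Plot a ratiometric image
#'
#' @param img Ratio matrix from [ratiometric_image()].
#' @return A ggplot raster plot; undefined pixels are blank.
#' @export
plot_ratiometric <- function(img) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$ratio <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$ratio)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "red / (red + cyan)")
}
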
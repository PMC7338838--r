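#' Construct an emission spectrum
#'
#' A spectrum is a tibble with two columns: `wavelength_nm` (strictly
#' increasing, in nanometres) and `intensity` (arbitrary units). All
#' preprocessing verbs in the package take and return this shape so that
#' calls chain with the pipe.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param intensity Numeric vector of intensities, same length.
#' @return A tibble with columns `wavelength_nm` and `intensity`.
#' @examples
#' spectrum_tbl(c(500, 510, 520), c(1, 2, 1))
#' @export
spectrum_tbl <- function(wavelength_nm, intensity) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity)) {
    stop("`wavelength_nm` and `intensity` must have the same length.",
         call. = FALSE)
  }
  if (length(wavelength_nm) < 2) {
    stop("A spectrum needs at least 2 points.", call. = FALSE)
  }
  if (anyNA(wavelength_nm) || anyNA(intensity)) {
    stop("Spectrum values must not contain NA.", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("Wavelengths must be strictly increasing.", call. = FALSE)
  }
  tibble::tibble(wavelength_nm = wavelength_nm, intensity = intensity)
}

check_spectrum <- function(s, arg = "s") {
  if (!is.data.frame(s) ||
      !all(c("wavelength_nm", "intensity") %in% names(s))) {
    stop("`", arg, "` must be a data frame with columns `wavelength_nm` ",
         "and `intensity`.", call. = FALSE)
  }
  spectrum_tbl(s$wavelength_nm, s$intensity)
}

check_pmf <- function(s, arg = "s", tol = 1e-9) {
  if (!is.data.frame(s) || !all(c("wavelength_nm", "pmf") %in% names(s))) {
    stop("`", arg, "` must be a PMF spectrum with columns `wavelength_nm` ",
         "and `pmf` (see `normalize_pmf()`).", call. = FALSE)
  }
  wl <- as.numeric(s$wavelength_nm)
  p <- as.numeric(s$pmf)
  if (any(p < -tol)) {
    stop("`", arg, "`: PMF weights must be non-negative.", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop("`", arg, "`: PMF must sum to 1 (got ", format(sum(p)), ").",
         call. = FALSE)
  }
  step <- grid_step(wl, arg)
  tibble::tibble(wavelength_nm = wl, pmf = p)
}

grid_step <- function(wl, arg = "s", tol = 1e-9) {
  d <- diff(wl)
  if (length(d) < 1 || any(d <= 0)) {
    stop("`", arg, "` must have a strictly increasing wavelength grid.",
         call. = FALSE)
  }
  if (max(d) - min(d) > tol) {
    stop("`", arg, "` must be on a uniform wavelength grid ",
         "(use `resample_uniform()`).", call. = FALSE)
  }
  mean(d)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && max(abs(a - b)) <= tol
}

#' Read an emission spectrum from delimited text
#'
#' Reads a two-column (wavelength, intensity) delimited text file. The
#' delimiter (comma, semicolon, tab or whitespace) and an optional single
#' header line are auto-detected. Rows are sorted by wavelength and
#' duplicate wavelengths are averaged, which tolerates spectrometer
#' re-reads of the same pixel.
#'
#' @param path Path to the text file.
#' @param wavelength_col,intensity_col Column indices holding wavelength and
#'   intensity (defaults 1 and 2).
#' @return A spectrum tibble (see [spectrum_tbl()]).
#' @export
read_spectrum <- function(path, wavelength_col = 1, intensity_col = 2) {
  if (!file.exists(path)) {
    stop("Spectrum file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop("Spectrum file ", path, " has fewer than 2 data rows.",
         call. = FALSE)
  }
  delim <- detect_delim(lines)
  split_row <- function(x) {
    parts <- strsplit(trimws(x), delim)[[1]]
    parts[nzchar(parts)]
  }
  first <- suppressWarnings(as.numeric(split_row(lines[[1]])))
  has_header <- anyNA(first)
  data_lines <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  ncol_needed <- max(wavelength_col, intensity_col)
  rows <- lapply(seq_along(data_lines), function(i) {
    vals <- suppressWarnings(as.numeric(split_row(data_lines[[i]])))
    if (anyNA(vals) || length(vals) < ncol_needed) {
      stop("Could not parse line ", i + offset, " of ", path,
           ": ", data_lines[[i]], call. = FALSE)
    }
    vals
  })
  wl <- vapply(rows, `[[`, numeric(1), wavelength_col)
  it <- vapply(rows, `[[`, numeric(1), intensity_col)
  if (length(wl) < 2) {
    stop("Spectrum file ", path, " has fewer than 2 points.", call. = FALSE)
  }
  tibble::tibble(wavelength_nm = wl, intensity = it) |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$wavelength_nm)
}

detect_delim <- function(lines) {
  probe <- lines[[min(2L, length(lines))]]
  for (d in c(",", ";", "\t")) {
    if (grepl(d, probe, fixed = TRUE)) return(d)
  }
  "[[:space:]]+"
}

#' Write a spectrum to CSV
#'
#' @param s A spectrum tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  s <- check_spectrum(s)
  readr::write_csv(s, path)
  invisible(path)
}

#' Subtract a baseline from a spectrum
#'
#' Background removal ahead of PMF normalization. `"constant-min"`
#' subtracts the minimum intensity; `"dark-reference"` subtracts a dark
#' reference spectrum measured on the same wavelength grid. Results are
#' clipped at zero in both modes.
#'
#' @param s A spectrum tibble.
#' @param mode `"constant-min"` or `"dark-reference"`.
#' @param reference Dark reference spectrum (required for
#'   `"dark-reference"`), on exactly the same grid as `s`.
#' @return A spectrum tibble with non-negative intensities.
#' @export
subtract_baseline <- function(s, mode = c("constant-min", "dark-reference"),
                              reference = NULL) {
  s <- check_spectrum(s)
  mode <- match.arg(mode)
  base <- switch(mode,
    "constant-min" = min(s$intensity),
    "dark-reference" = {
      if (is.null(reference)) {
        stop("`reference` is required for dark-reference subtraction.",
             call. = FALSE)
      }
      reference <- check_spectrum(reference, "reference")
      if (!same_grid(s$wavelength_nm, reference$wavelength_nm)) {
        stop("Dark reference is not on the same wavelength grid as `s`.",
             call. = FALSE)
      }
      reference$intensity
    }
  )
  dplyr::mutate(s, intensity = pmax(.data$intensity - base, 0))
}

#' Smooth a spectrum with a sliding-window (boxcar) average
#'
#' Centered moving average whose window is the smallest odd number of
#' samples spanning at least `window_nm` nanometres on the spectrum's
#' grid. At the edges the window truncates to the available samples, so a
#' constant spectrum is a fixed point of smoothing. The wavelength grid is
#' never changed.
#'
#' @param s A spectrum tibble on a uniform grid.
#' @param window_nm Window width in nm (default 10, matching a 10-nm
#'   spectrometer slit resolution).
#' @return The smoothed spectrum tibble.
#' @export
smooth_sliding_window <- function(s, window_nm = 10) {
  s <- check_spectrum(s)
  if (window_nm <= 0) stop("`window_nm` must be > 0.", call. = FALSE)
  # median step tolerates the slightly non-uniform grids of raw spectrometer
  # exports; the window is expressed in samples, not re-interpolated
  step <- stats::median(diff(s$wavelength_nm))
  if (window_nm < step) {
    warning("`window_nm` (", window_nm, " nm) is smaller than the grid step (",
            step, " nm); returning the spectrum unchanged.", call. = FALSE)
    return(s)
  }
  # smallest odd n with span (n - 1) * step >= window_nm
  n <- ceiling(window_nm / step) + 1L
  if (n %% 2L == 0L) n <- n + 1L
  half <- (n - 1L) %/% 2L
  y <- s$intensity
  m <- length(y)
  cs <- c(0, cumsum(y))
  idx <- seq_len(m)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, m)
  dplyr::mutate(s, intensity = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Crop a spectrum to a wavelength range
#'
#' Keeps samples with `lo_nm <= wavelength <= hi_nm` (both endpoints
#' inclusive). The default working range of the downstream optimizer is
#' 425 to 650 nm, where detector response is linear and excitation light
#' is excluded.
#'
#' @param s A spectrum tibble.
#' @param lo_nm,hi_nm Range limits in nm, `lo_nm < hi_nm`.
#' @return The cropped spectrum tibble.
#' @export
crop_range <- function(s, lo_nm = 425, hi_nm = 650) {
  s <- check_spectrum(s)
  if (lo_nm >= hi_nm) stop("`lo_nm` must be < `hi_nm`.", call. = FALSE)
  out <- dplyr::filter(s, .data$wavelength_nm >= lo_nm,
                       .data$wavelength_nm <= hi_nm)
  if (nrow(out) == 0) {
    stop("Crop range [", lo_nm, ", ", hi_nm,
         "] nm contains no spectrum samples.", call. = FALSE)
  }
  out
}

#' Resample a spectrum onto a uniform wavelength grid
#'
#' Linear interpolation onto the grid `seq(ceiling(min), floor(max),
#' by = step_nm)`. No extrapolation: nodes outside the spectrum's support
#' are not produced.
#'
#' @param s A spectrum tibble.
#' @param step_nm Grid step in nm (default 1).
#' @return The resampled spectrum tibble on a uniform grid.
#' @export
resample_uniform <- function(s, step_nm = 1) {
  s <- check_spectrum(s)
  if (step_nm <= 0) stop("`step_nm` must be > 0.", call. = FALSE)
  lo <- ceiling(min(s$wavelength_nm))
  hi <- floor(max(s$wavelength_nm))
  grid <- seq(lo, hi, by = step_nm)
  grid <- grid[grid >= min(s$wavelength_nm) & grid <= max(s$wavelength_nm)]
  if (length(grid) < 2) {
    stop("`step_nm` (", step_nm, " nm) is too large for the spectral span.",
         call. = FALSE)
  }
  y <- stats::approx(s$wavelength_nm, s$intensity, xout = grid,
                     method = "linear", rule = 1)$y
  tibble::tibble(wavelength_nm = grid, intensity = y)
}

#' Normalize a spectrum to a probability mass function
#'
#' Divides each intensity by the total over the (uniform) grid, so the
#' result sums to one and band powers become probabilities. All band
#' scoring runs on PMF spectra, which makes every downstream metric
#' independent of the absolute intensity of the input.
#'
#' @param s A spectrum tibble on a uniform grid with non-negative total
#'   intensity > 0.
#' @return A PMF tibble with columns `wavelength_nm` and `pmf`.
#' @export
normalize_pmf <- function(s) {
  s <- check_spectrum(s)
  grid_step(s$wavelength_nm)
  if (any(s$intensity < 0)) {
    stop("Negative intensities: subtract the baseline (with clipping) ",
         "before PMF normalization.", call. = FALSE)
  }
  tot <- sum(s$intensity)
  if (tot <= 0) {
    stop("Cannot PMF-normalize an all-zero spectrum.", call. = FALSE)
  }
  tibble::tibble(wavelength_nm = s$wavelength_nm, pmf = s$intensity / tot)
}

#' Average a group of PMF spectra
#'
#' Pointwise mean of replicate PMF spectra on a shared grid, renormalized
#' to unit sum. Replicate acquisitions of the same specimen class are
#' averaged this way before band optimization.
#'
#' @param group A list of PMF tibbles on identical grids.
#' @return A single PMF tibble.
#' @export
mean_spectrum <- function(group) {
  if (!is.list(group) || length(group) == 0 || is.data.frame(group)) {
    stop("`group` must be a non-empty list of PMF spectra.", call. = FALSE)
  }
  group <- lapply(seq_along(group), function(i) {
    check_pmf(group[[i]], paste0("group[[", i, "]]"))
  })
  wl <- group[[1]]$wavelength_nm
  for (g in group[-1]) {
    if (!same_grid(wl, g$wavelength_nm)) {
      stop("All spectra in `group` must share one wavelength grid.",
           call. = FALSE)
    }
  }
  p <- rowMeans(vapply(group, function(g) g$pmf, numeric(length(wl))))
  tibble::tibble(wavelength_nm = wl, pmf = p / sum(p))
}

#' Preprocess a raw spectrum into a PMF on the working grid
#'
#' Convenience chain: baseline subtraction, sliding-window smoothing, crop
#' to the working range, resampling to a uniform grid, PMF normalization.
#'
#' @param s A raw spectrum tibble.
#' @param window_nm Smoothing window (nm).
#' @param range_lo_nm,range_hi_nm Working wavelength range (nm).
#' @param step_nm Working grid step (nm).
#' @param baseline_mode Baseline mode, see [subtract_baseline()].
#' @param reference Optional dark reference spectrum.
#' @return A PMF tibble.
#' @export
preprocess_spectrum <- function(s, window_nm = 10, range_lo_nm = 425,
                                range_hi_nm = 650, step_nm = 1,
                                baseline_mode = "constant-min",
                                reference = NULL) {
  s |>
    subtract_baseline(mode = baseline_mode, reference = reference) |>
    smooth_sliding_window(window_nm = window_nm) |>
    resample_uniform(step_nm = step_nm) |>
    crop_range(lo_nm = range_lo_nm, hi_nm = range_hi_nm) |>
    normalize_pmf()
}
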
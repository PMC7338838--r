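#' Define a fluorophore emission model
#'
#' A fluorophore is modelled as a mixture of Gaussian emission peaks:
#' one row per peak with its center (nm), width (Gaussian standard
#' deviation, nm) and relative weight.
#'
#' @param center_nm,width_nm,weight Numeric vectors of equal length;
#'   widths and weights > 0.
#' @param name Label for the model.
#' @return A `fluorophore_model`: list with a `peaks` tibble and `name`.
#' @examples
#' fluorophore_model(c(470, 540), c(35, 45), c(0.7, 0.3), "class B")
#' @export
fluorophore_model <- function(center_nm, width_nm, weight, name = "model") {
  if (length(center_nm) != length(width_nm) ||
      length(center_nm) != length(weight)) {
    stop("`center_nm`, `width_nm`, `weight` must have equal length.",
         call. = FALSE)
  }
  if (any(width_nm <= 0) || any(weight <= 0)) {
    stop("Peak widths and weights must be > 0.", call. = FALSE)
  }
  structure(list(peaks = tibble::tibble(center_nm = as.numeric(center_nm),
                                        width_nm = as.numeric(width_nm),
                                        weight = as.numeric(weight)),
                 name = name),
            class = "fluorophore_model")
}

#' Default two-class emission models
#'
#' A pair of autofluorescence-like models: class B has a dominant blue
#' peak at 470 nm (sd 35 nm, weight 0.7) plus a green-yellow peak at
#' 540 nm (sd 45 nm, weight 0.3), loosely NAD(P)H- plus FAD-weighted;
#' class A is the same mixture blue-shifted by `shift_nm`, mimicking the
#' blue-shift of cancerous versus normal cell spectra. Purely a synthetic
#' fixture, not a claim about any cell line.
#'
#' @param shift_nm Blue-shift of class A relative to class B (default 15).
#' @return Named list with `fluorophore_model`s `a` and `b`.
#' @export
two_class_model <- function(shift_nm = 15) {
  b <- fluorophore_model(c(470, 540), c(35, 45), c(0.7, 0.3), "class B")
  a <- fluorophore_model(b$peaks$center_nm - shift_nm, b$peaks$width_nm,
                         b$peaks$weight, "class A")
  list(a = a, b = b)
}

#' Generate a noisy Gaussian-mixture emission spectrum
#'
#' Evaluates the model's Gaussian peaks on the grid, adds seeded Gaussian
#' noise of standard deviation `noise_sd` (in the same arbitrary units as
#' the peak weights) and clips at zero. Bit-reproducible for a fixed
#' seed.
#'
#' @param model A [fluorophore_model()].
#' @param grid Wavelength grid in nm, within 350–750 nm.
#' @param noise_sd Additive noise scale (>= 0).
#' @param seed Optional integer seed.
#' @return A spectrum tibble.
#' @export
gaussian_spectrum <- function(model, grid = seq(425, 650, by = 1),
                              noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "fluorophore_model"))
  if (any(grid < 350) || any(grid > 750)) {
    stop("`grid` must lie within 350-750 nm.", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(model$peaks))) {
    pk <- model$peaks[i, ]
    y <- y + pk$weight * exp(-(grid - pk$center_nm)^2 / (2 * pk$width_nm^2))
  }
  if (noise_sd > 0) {
    noise <- with_optional_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
    y <- y + noise
  }
  spectrum_tbl(grid, pmax(y, 0))
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Generate a blue-shifted / reference spectrum pair
#'
#' Two spectra from the same two-peak model, class A's peak centers
#' shifted `shift_nm` toward the blue — the structure the band optimizer
#' assumes: a larger shift yields a larger best achievable separation.
#'
#' @param shift_nm Blue-shift in nm.
#' @param grid Wavelength grid in nm.
#' @param noise_sd Additive noise scale for both spectra.
#' @param seed Optional integer seed (the two spectra get distinct
#'   sub-seeds).
#' @return Named list of spectrum tibbles `a` (shifted) and `b`.
#' @export
two_class_pair <- function(shift_nm = 15, grid = seq(425, 650, by = 1),
                           noise_sd = 0, seed = NULL) {
  m <- two_class_model(shift_nm)
  seeds <- if (is.null(seed)) list(NULL, NULL) else {
    list(as.integer(seed), as.integer(seed) + 1L)
  }
  list(a = gaussian_spectrum(m$a, grid, noise_sd, seeds[[1]]),
       b = gaussian_spectrum(m$b, grid, noise_sd, seeds[[2]]))
}

#' Generate a labelled synthetic hyperspectral cube
#'
#' Emulates a field of view containing two (or more) specimen classes:
#' each pixel's spectral vector is `counts_scale` times its label's PMF,
#' optionally modulated by a per-pixel `brightness` field (morphology-like
#' intensity structure that affects all wavelengths equally), plus
#' shot-like noise (Gaussian with variance proportional to the signal),
#' clipped at zero. Noise-free cubes reproduce each label's PMF exactly at
#' every pixel.
#'
#' @param regions Integer/character matrix of region labels.
#' @param spectra Named list mapping each label to a PMF tibble (shared
#'   grid).
#' @param counts_scale Mean total photon count per pixel (> 0).
#' @param brightness Optional non-negative matrix (same shape as
#'   `regions`) multiplying each pixel's expected counts; default flat 1.
#' @param noise Add shot-like noise (default TRUE; FALSE gives the
#'   noise-free limit regardless of `counts_scale`).
#' @param seed Optional integer seed.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @return A `hyperspectral_cube` with attribute `regions`.
#' @export
synth_cube <- function(regions, spectra, counts_scale = 1000, noise = TRUE,
                       brightness = NULL, seed = NULL, pixel_size_um = 1) {
  if (!is.matrix(regions)) stop("`regions` must be a matrix.", call. = FALSE)
  if (counts_scale <= 0) stop("`counts_scale` must be > 0.", call. = FALSE)
  if (!is.null(brightness)) {
    if (!is.matrix(brightness) || !all(dim(brightness) == dim(regions)) ||
        any(brightness < 0)) {
      stop("`brightness` must be a non-negative matrix shaped like ",
           "`regions`.", call. = FALSE)
    }
  }
  labels <- unique(as.vector(regions))
  missing_lab <- setdiff(as.character(labels), names(spectra))
  if (length(missing_lab) > 0) {
    stop("No spectrum supplied for region label(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  spectra <- lapply(spectra, check_pmf, arg = "spectra")
  wl <- spectra[[1]]$wavelength_nm
  for (s in spectra[-1]) {
    if (!same_grid(wl, s$wavelength_nm)) {
      stop("All label spectra must share one wavelength grid.", call. = FALSE)
    }
  }
  nr <- nrow(regions); nc <- ncol(regions); nw <- length(wl)
  arr <- array(0, dim = c(nr, nc, nw))
  for (lab in labels) {
    mask <- regions == lab
    mu <- counts_scale * spectra[[as.character(lab)]]$pmf
    arr[rep(mask, nw)] <- rep(mu, each = sum(mask))
  }
  if (!is.null(brightness)) {
    arr <- arr * rep(brightness, nw)
  }
  if (noise) {
    noise_arr <- with_optional_seed(
      seed, stats::rnorm(length(arr), 0, sqrt(pmax(arr, 0))))
    arr <- arr + noise_arr
  }
  cube <- hyperspectral_cube(pmax(arr, 0), wl, pixel_size_um)
  attr(cube, "regions") <- regions
  cube
}
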
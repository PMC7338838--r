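#' Spectral center of gravity
#'
#' Intensity-weighted mean emission wavelength of a PMF spectrum,
#' `sum(lambda * pmf)`. A blue-shift of one specimen group relative to
#' another shows up as a lower center of gravity.
#'
#' @param s A PMF tibble.
#' @return Wavelength in nm, within the grid's range.
#' @export
center_of_gravity <- function(s) {
  s <- check_pmf(s)
  sum(s$wavelength_nm * s$pmf)
}

#' Relative variability of two spectrum groups
#'
#' For each group of replicate PMF spectra, the sample standard deviation
#' of the within-group centers of gravity divided by the absolute
#' difference between the two groups' mean centers of gravity. Values
#' well below 1 indicate that within-group scatter is small compared to
#' the spectral shift separating the groups, the regime in which band
#' optimization on the mean spectra is meaningful. This is a working
#' definition of the spread-over-shift idea, not a reproduction of any
#' specific published formula.
#'
#' @param group_a,group_b Lists of >= 2 PMF tibbles each, on a shared grid.
#' @return A tibble with one row per group: `group`, `n`, `mean_cog_nm`,
#'   `sd_cog_nm`, `relative_variability`.
#' @export
relative_variability <- function(group_a, group_b) {
  cogs <- function(g, arg) {
    if (!is.list(g) || is.data.frame(g) || length(g) < 2) {
      stop("`", arg, "` must be a list of at least 2 PMF spectra.",
           call. = FALSE)
    }
    vapply(g, center_of_gravity, numeric(1))
  }
  ca <- cogs(group_a, "group_a")
  cb <- cogs(group_b, "group_b")
  shift <- abs(mean(ca) - mean(cb))
  if (shift == 0) {
    stop("The two groups have identical mean centers of gravity; ",
         "relative variability is undefined.", call. = FALSE)
  }
  tibble::tibble(
    group = c("a", "b"),
    n = c(length(ca), length(cb)),
    mean_cog_nm = c(mean(ca), mean(cb)),
    sd_cog_nm = c(stats::sd(ca), stats::sd(cb)),
    relative_variability = c(stats::sd(ca), stats::sd(cb)) / shift
  )
}

#' Mean redox ratio of one ratiometric image
#'
#' Mean of the defined (non-`NA`) pixels of a ratiometric image — the
#' per-image summary entering group comparisons.
#'
#' @param ratio_img Matrix from [ratiometric_image()].
#' @return The mean ratio, a number in \[0, 1\].
#' @export
redox_per_image <- function(ratio_img) {
  ratio_img <- channel_matrix(ratio_img, "ratio_img")
  vals <- ratio_img[!is.na(ratio_img)]
  if (length(vals) == 0) {
    stop("All pixels of `ratio_img` are undefined.", call. = FALSE)
  }
  mean(vals)
}

#' Summarise a group of per-image values
#'
#' @param values Numeric vector of per-image redox-ratio means.
#' @return A one-row tibble: `n`, `mean`, `sd` (sample standard deviation).
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NA.",
         call. = FALSE)
  }
  tibble::tibble(n = length(values), mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0)
}

#' T-ratio separating two specimen groups
#'
#' Absolute t-statistic on the two groups of per-image redox means:
#' `|mean_a - mean_b| / sqrt(sd_a^2/n_a + sd_b^2/n_b)` (Welch form,
#' default) or the pooled-variance Student form with
#' `var_equal = TRUE`. A larger T-ratio means the two specimen
#' populations are easier to tell apart; improved spectral bands raise it
#' by shrinking the per-group standard deviations even when the mean
#' difference barely moves.
#'
#' @param a,b Numeric vectors of per-image values, or one-row summaries
#'   from [group_summary()]. Each group needs n >= 2.
#' @param var_equal Use the pooled-variance Student form (default FALSE,
#'   Welch).
#' @return The T-ratio (>= 0).
#' @export
t_ratio <- function(a, b, var_equal = FALSE) {
  ga <- if (is.data.frame(a)) a else group_summary(a)
  gb <- if (is.data.frame(b)) b else group_summary(b)
  for (g in list(ga, gb)) {
    if (!all(c("n", "mean", "sd") %in% names(g)) || nrow(g) != 1) {
      stop("Group summaries must be one-row tibbles with n, mean, sd.",
           call. = FALSE)
    }
  }
  if (ga$n < 2 || gb$n < 2) {
    stop("Each group needs at least 2 images.", call. = FALSE)
  }
  if (ga$sd == 0 && gb$sd == 0 && ga$mean == gb$mean) {
    stop("Both groups are constant and equal; the T-ratio is undefined.",
         call. = FALSE)
  }
  se <- if (var_equal) {
    sp2 <- ((ga$n - 1) * ga$sd^2 + (gb$n - 1) * gb$sd^2) / (ga$n + gb$n - 2)
    sqrt(sp2 * (1 / ga$n + 1 / gb$n))
  } else {
    sqrt(ga$sd^2 / ga$n + gb$sd^2 / gb$n)
  }
  abs(ga$mean - gb$mean) / se
}
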
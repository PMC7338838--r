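#' Define a pair of non-overlapping spectral bands
#'
#' A band pair is the unit the optimizer scores: two closed wavelength
#' intervals, band 1 blue of band 2, with a strict gap
#' (`band1_end_nm < band2_start_nm`) so ideal band-pass filters never
#' overlap.
#'
#' @param band1_start_nm,band1_end_nm Edges of the blue band (nm).
#' @param band2_start_nm,band2_end_nm Edges of the red band (nm).
#' @return A named numeric vector of class `band_pair`.
#' @examples
#' band_pair(410, 490, 510, 650)
#' @export
band_pair <- function(band1_start_nm, band1_end_nm,
                      band2_start_nm, band2_end_nm) {
  p <- c(band1_start_nm = as.numeric(band1_start_nm),
         band1_end_nm = as.numeric(band1_end_nm),
         band2_start_nm = as.numeric(band2_start_nm),
         band2_end_nm = as.numeric(band2_end_nm))
  if (anyNA(p)) stop("Band edges must be numeric.", call. = FALSE)
  if (p[1] > p[2] || p[3] > p[4]) {
    stop("Each band must satisfy start <= end.", call. = FALSE)
  }
  if (p[2] >= p[3]) {
    stop("Bands must not overlap: band1 end (", p[2],
         " nm) must be strictly below band2 start (", p[3], " nm).",
         call. = FALSE)
  }
  structure(p, class = "band_pair")
}

as_band_pair <- function(pair) {
  if (inherits(pair, "band_pair")) return(pair)
  if (is.data.frame(pair) && nrow(pair) == 1 &&
      all(c("band1_start_nm", "band1_end_nm",
            "band2_start_nm", "band2_end_nm") %in% names(pair))) {
    return(band_pair(pair$band1_start_nm, pair$band1_end_nm,
                     pair$band2_start_nm, pair$band2_end_nm))
  }
  if (is.numeric(pair) && length(pair) == 4) {
    return(band_pair(pair[1], pair[2], pair[3], pair[4]))
  }
  stop("`pair` must be a band_pair, a length-4 numeric vector, or a ",
       "one-row data frame with band edge columns.", call. = FALSE)
}

#' Power of a PMF spectrum inside one band
#'
#' Sum of the PMF weights at grid nodes with
#' `start_nm <= wavelength <= end_nm` (closed interval). Because the
#' spectrum is a PMF, the result is a probability in \[0, 1\].
#'
#' @param s A PMF tibble (see [normalize_pmf()]).
#' @param start_nm,end_nm Band edges in nm.
#' @return The band power, a number in \[0, 1\].
#' @export
band_power <- function(s, start_nm, end_nm) {
  s <- check_pmf(s)
  if (start_nm > end_nm) stop("`start_nm` must be <= `end_nm`.", call. = FALSE)
  if (end_nm < min(s$wavelength_nm) || start_nm > max(s$wavelength_nm)) {
    stop("Band [", start_nm, ", ", end_nm,
         "] nm lies outside the spectrum grid.", call. = FALSE)
  }
  sum(s$pmf[s$wavelength_nm >= start_nm & s$wavelength_nm <= end_nm])
}

#' Within-spectrum ratio of two band powers
#'
#' The blue-over-red band-power ratio within one spectrum. Working on PMF
#' spectra makes the ratio independent of absolute intensity and thus of
#' system throughput drifts.
#'
#' @param s A PMF tibble.
#' @param pair A [band_pair()] (or 4-vector / one-row data frame of edges).
#' @param epsilon Powers at or below this are treated as degenerate.
#' @return The dimensionless ratio band1 / band2.
#' @export
band_ratio <- function(s, pair, epsilon = 1e-12) {
  pair <- as_band_pair(pair)
  p1 <- band_power(s, pair[1], pair[2])
  p2 <- band_power(s, pair[3], pair[4])
  if (p1 <= epsilon || p2 <= epsilon) {
    stop("Degenerate band: band power <= ", epsilon,
         "; choose bands covering non-zero parts of the spectrum.",
         call. = FALSE)
  }
  p1 / p2
}

#' Separation of two spectra for one band pair
#'
#' Ratio of the two spectra's within-spectrum band ratios. If the raw
#' ratio of ratios is below 1 its reciprocal is returned instead — the two
#' detection channels only need to be swapped — so separation is always
#' >= 1, with 1 meaning the band pair cannot distinguish the spectra.
#'
#' @param s1,s2 PMF tibbles on a shared grid.
#' @param pair A [band_pair()].
#' @param epsilon Degenerate-band threshold for the four band powers.
#' @return Separation (>= 1), with attribute `swapped` flagging the
#'   reciprocal branch.
#' @export
band_separation <- function(s1, s2, pair, epsilon = 1e-12) {
  r <- band_ratio(s1, pair, epsilon) / band_ratio(s2, pair, epsilon)
  swapped <- r < 1
  structure(if (swapped) 1 / r else r, swapped = swapped)
}

#' Relative signal collection efficiency of a band pair
#'
#' Geometric mean of the four band powers (two bands in each spectrum).
#' It rewards band pairs with balanced signal in both spectra and bounds
#' the achievable SNR of a two-channel setup: the value lies in (0, 0.5],
#' with 0.5 attained when each band collects half the total signal of each
#' spectrum.
#'
#' @inheritParams band_separation
#' @return Efficiency in (0, 0.5].
#' @export
collection_efficiency <- function(s1, s2, pair, epsilon = 1e-12) {
  pair <- as_band_pair(pair)
  p <- c(band_power(s1, pair[1], pair[2]), band_power(s1, pair[3], pair[4]),
         band_power(s2, pair[1], pair[2]), band_power(s2, pair[3], pair[4]))
  if (any(p <= epsilon)) {
    stop("Degenerate band: band power <= ", epsilon, ".", call. = FALSE)
  }
  prod(p)^0.25
}

#' Enumerate all non-overlapping band pairs on a wavelength lattice
#'
#' Band edges are placed on a sub-lattice of the working grid with spacing
#' `step_nm`; every combination of four edges with
#' `band1_start <= band1_end < band2_start <= band2_end` and both band
#' widths at least `min_width_nm` is produced, in lexicographic order of
#' the four edges.
#'
#' @param grid Uniform wavelength grid (numeric vector, nm).
#' @param step_nm Edge lattice spacing; must be a multiple of the grid step.
#' @param min_width_nm Minimum band width in nm (0 allows single-node bands).
#' @return A tibble with columns `band1_start_nm`, `band1_end_nm`,
#'   `band2_start_nm`, `band2_end_nm`. Lattice node indices into `grid`
#'   are attached as attribute `"lattice"` for reuse by [optimize_bands()].
#' @export
enumerate_band_pairs <- function(grid, step_nm = 5, min_width_nm = 0) {
  gstep <- grid_step(grid, "grid")
  ratio <- step_nm / gstep
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop("`step_nm` must be a positive multiple of the grid step (",
         gstep, " nm).", call. = FALSE)
  }
  if (min_width_nm < 0) stop("`min_width_nm` must be >= 0.", call. = FALSE)
  take <- seq(1L, length(grid), by = as.integer(round(ratio)))
  n <- length(take)
  if (n < 2) {
    stop("Edge lattice has fewer than 2 nodes; reduce `step_nm`.",
         call. = FALSE)
  }
  lat <- grid[take]
  # all single bands i <= j with width >= min_width_nm
  bands <- which(outer(lat, lat, function(a, b) b - a) >= min_width_nm - 1e-9 &
                   upper.tri(matrix(0, n, n), diag = TRUE),
                 arr.ind = TRUE)
  bi <- bands[, 1L]  # start index
  bj <- bands[, 2L]  # end index
  ord <- order(bi, bj)
  bi <- bi[ord]; bj <- bj[ord]
  nb <- length(bi)
  # cross all (band1, band2) with band1 end strictly before band2 start
  a <- rep(seq_len(nb), each = nb)
  b <- rep(seq_len(nb), times = nb)
  keep <- bj[a] < bi[b]
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) {
    stop("No band pair fits on the lattice; reduce `step_nm` or ",
         "`min_width_nm`.", call. = FALSE)
  }
  idx <- list(i = bi[a], j = bj[a], k = bi[b], l = bj[b],
              grid_pos = take, grid = grid)
  out <- tibble::tibble(
    band1_start_nm = lat[idx$i], band1_end_nm = lat[idx$j],
    band2_start_nm = lat[idx$k], band2_end_nm = lat[idx$l]
  )
  out <- out[order(out$band1_start_nm, out$band1_end_nm,
                   out$band2_start_nm, out$band2_end_nm), ]
  idx_ord <- order(lat[idx$i], lat[idx$j], lat[idx$k], lat[idx$l])
  idx$i <- idx$i[idx_ord]; idx$j <- idx$j[idx_ord]
  idx$k <- idx$k[idx_ord]; idx$l <- idx$l[idx_ord]
  attr(out, "lattice") <- idx
  out
}

# prefix sums of a PMF evaluated at lattice nodes: power of band [i..j]
# (lattice indices) = end[j] - before[i]
lattice_prefix <- function(pmf, grid_pos) {
  cs <- cumsum(pmf)
  list(end = cs[grid_pos], before = c(0, cs)[grid_pos])
}

#' Score every band pair for two spectra
#'
#' Evaluates [band_separation()] and [collection_efficiency()] for every
#' enumerated non-overlapping band pair using a prefix-sum fast path (a
#' band power is a difference of two cumulative sums), excluding pairs
#' where any of the four band powers is at or below `epsilon` — such pairs
#' sit in empty spectral regions and would make the ratios blow up.
#'
#' @param s1,s2 PMF tibbles on one shared uniform grid.
#' @param step_nm Band-edge lattice spacing in nm (default 5).
#' @param min_width_nm Minimum band width in nm; defaults to one lattice
#'   step so that every band spans at least two lattice nodes.
#' @param epsilon Degenerate-band exclusion threshold.
#' @param pairs Optional pre-computed enumeration from
#'   [enumerate_band_pairs()] on the same grid (reused across calls in
#'   sweeps).
#' @return A `band_optimization` object: list with `pairs` (tibble of band
#'   edges, `separation`, `efficiency`, `swapped`), `excluded_count`,
#'   `grid_step_nm`, `step_nm`, and the two input PMFs. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
optimize_bands <- function(s1, s2, step_nm = 5, min_width_nm = step_nm,
                           epsilon = 1e-12, pairs = NULL) {
  s1 <- check_pmf(s1, "s1")
  s2 <- check_pmf(s2, "s2")
  if (!same_grid(s1$wavelength_nm, s2$wavelength_nm)) {
    stop("`s1` and `s2` must share one wavelength grid.", call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- enumerate_band_pairs(s1$wavelength_nm, step_nm = step_nm,
                                  min_width_nm = min_width_nm)
  }
  idx <- attr(pairs, "lattice")
  if (is.null(idx) || !same_grid(idx$grid, s1$wavelength_nm)) {
    stop("`pairs` must come from enumerate_band_pairs() on the same grid.",
         call. = FALSE)
  }
  m <- eval_lattice(s1$pmf, s2$pmf, idx, epsilon)
  kept <- tibble::tibble(
    band1_start_nm = pairs$band1_start_nm[m$valid],
    band1_end_nm = pairs$band1_end_nm[m$valid],
    band2_start_nm = pairs$band2_start_nm[m$valid],
    band2_end_nm = pairs$band2_end_nm[m$valid],
    separation = m$separation,
    efficiency = m$efficiency,
    swapped = m$swapped
  )
  if (nrow(kept) == 0) {
    stop("No valid band pairs: every enumerated pair has a band power <= ",
         epsilon, ".", call. = FALSE)
  }
  structure(
    list(pairs = kept, excluded_count = m$excluded,
         grid_step_nm = grid_step(s1$wavelength_nm), step_nm = step_nm,
         min_width_nm = min_width_nm, epsilon = epsilon, s1 = s1, s2 = s2),
    class = "band_optimization"
  )
}

eval_lattice <- function(pmf1, pmf2, idx, epsilon) {
  c1 <- lattice_prefix(pmf1, idx$grid_pos)
  c2 <- lattice_prefix(pmf2, idx$grid_pos)
  p1s1 <- c1$end[idx$j] - c1$before[idx$i]
  p2s1 <- c1$end[idx$l] - c1$before[idx$k]
  p1s2 <- c2$end[idx$j] - c2$before[idx$i]
  p2s2 <- c2$end[idx$l] - c2$before[idx$k]
  valid <- p1s1 > epsilon & p2s1 > epsilon & p1s2 > epsilon & p2s2 > epsilon
  r <- (p1s1[valid] / p2s1[valid]) / (p1s2[valid] / p2s2[valid])
  swapped <- r < 1
  sep <- ifelse(swapped, 1 / r, r)
  eff <- (p1s1[valid] * p2s1[valid] * p1s2[valid] * p2s2[valid])^0.25
  list(separation = sep, efficiency = eff, swapped = swapped,
       valid = valid, excluded = sum(!valid))
}

#' @export
print.band_optimization <- function(x, ...) {
  cat("Band-pair optimization over", nrow(x$pairs), "valid pairs",
      sprintf("(%d excluded for near-zero band power)\n", x$excluded_count))
  cat("  edge lattice:", x$step_nm, "nm; working grid step:",
      x$grid_step_nm, "nm\n")
  best <- x$pairs[which.max(x$pairs$separation), ]
  cat(sprintf("  max separation %.4g at efficiency %.4g (bands %g-%g / %g-%g nm)\n",
              best$separation, best$efficiency, best$band1_start_nm,
              best$band1_end_nm, best$band2_start_nm, best$band2_end_nm))
  cat(sprintf("  max efficiency %.4g\n", max(x$pairs$efficiency)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the evaluated band pairs of an optimization
#'
#' @param x A `band_optimization` object.
#' @param ... Unused.
#' @return The long tibble of evaluated pairs: band edges, `separation`,
#'   `efficiency`, `swapped`.
#' @export
tidy.band_optimization <- function(x, ...) x$pairs

#' One-row summary of a band-pair optimization
#'
#' @param x A `band_optimization` object.
#' @param ... Unused.
#' @return A one-row tibble with pair counts and metric extrema.
#' @export
glance.band_optimization <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    excluded_count = x$excluded_count,
    step_nm = x$step_nm,
    max_separation = max(x$pairs$separation),
    min_separation = min(x$pairs$separation),
    max_efficiency = max(x$pairs$efficiency)
  )
}

#' Pareto front of separation versus collection efficiency
#'
#' The maximal-achievable-separation envelope: a band pair is on the front
#' iff no other evaluated pair has efficiency >= its efficiency and
#' strictly larger separation. The front is ordered by efficiency
#' descending, then separation descending, then lexicographically by band
#' edges, so the output is deterministic.
#'
#' @param result A `band_optimization` object.
#' @return A tibble of front pairs sorted by efficiency descending;
#'   separations are non-decreasing as efficiency decreases.
#' @export
pareto_front <- function(result) {
  stopifnot(inherits(result, "band_optimization"))
  p <- result$pairs
  p <- p[order(-p$efficiency, -p$separation, p$band1_start_nm,
               p$band1_end_nm, p$band2_start_nm, p$band2_end_nm), ]
  cm <- cummax(p$separation)
  # within an efficiency tie the running max of the whole tie group applies
  cm <- stats::ave(cm, p$efficiency, FUN = max)
  p[p$separation >= cm, ]
}

#' Metrics of one user-specified band pair
#'
#' Scores a custom filter setup — for instance the 410–490 nm / 510–650 nm
#' bands suggested in the literature for NAD(P)H / FAD detection — so it
#' can be compared with, and marked against, the optimized cloud.
#'
#' @param s1,s2 PMF tibbles on one shared grid.
#' @param pair A [band_pair()].
#' @param epsilon Degenerate-band threshold.
#' @return A one-row tibble: band edges, `separation`, `efficiency`,
#'   `swapped`.
#' @export
evaluate_custom_setup <- function(s1, s2, pair, epsilon = 1e-12) {
  pair <- as_band_pair(pair)
  sep <- band_separation(s1, s2, pair, epsilon)
  tibble::tibble(
    band1_start_nm = pair[[1]], band1_end_nm = pair[[2]],
    band2_start_nm = pair[[3]], band2_end_nm = pair[[4]],
    separation = as.numeric(sep),
    efficiency = collection_efficiency(s1, s2, pair, epsilon),
    swapped = attr(sep, "swapped")
  )
}

#' Best band pair at the efficiency of a reference setup
#'
#' Among all evaluated pairs whose collection efficiency lies within
#' `rel_tolerance` (relative) of the reference setup's efficiency, returns
#' the one with maximal separation. The reference itself is always a
#' candidate, so the reported separation gain is >= 1.
#'
#' @param result A `band_optimization` object.
#' @param reference The reference [band_pair()].
#' @param rel_tolerance Relative efficiency tolerance (default 0.001,
#'   i.e. 0.1%).
#' @return A one-row tibble: the matched pair's edges and metrics plus
#'   `reference_separation` and `gain` (matched / reference separation).
#' @export
match_at_efficiency <- function(result, reference, rel_tolerance = 0.001) {
  stopifnot(inherits(result, "band_optimization"))
  ref <- evaluate_custom_setup(result$s1, result$s2, reference,
                               epsilon = result$epsilon)
  cand <- result$pairs[abs(result$pairs$efficiency - ref$efficiency) <=
                         rel_tolerance * ref$efficiency, ]
  cand <- dplyr::bind_rows(cand, ref)
  if (nrow(cand) == 0) {
    nearest <- result$pairs$efficiency[
      which.min(abs(result$pairs$efficiency - ref$efficiency))]
    stop("No band pair within ", rel_tolerance * 100,
         "% of the reference efficiency ", format(ref$efficiency),
         "; nearest achievable efficiency is ", format(nearest),
         ". Widen `rel_tolerance`.", call. = FALSE)
  }
  cand <- cand[order(-cand$separation, -cand$efficiency, cand$band1_start_nm,
                     cand$band1_end_nm, cand$band2_start_nm,
                     cand$band2_end_nm), ]
  best <- cand[1, ]
  best$reference_separation <- ref$separation
  best$reference_efficiency <- ref$efficiency
  best$gain <- best$separation / ref$separation
  best
}

#' Scatter plot of separation versus collection efficiency
#'
#' Mirrors the optimizer's standard diagnostic: every evaluated band pair
#' as a point, the Pareto front as a line, and an optional reference
#' filter setup as a marked point.
#'
#' @param object A `band_optimization` object.
#' @param reference Optional [band_pair()] to highlight.
#' @param log_separation Plot separation on a log axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.band_optimization <- function(object, reference = NULL,
                                       log_separation = TRUE, ...) {
  front <- pareto_front(object)
  p <- ggplot2::ggplot(object$pairs,
                       ggplot2::aes(x = .data$efficiency,
                                    y = .data$separation)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4, colour = "grey40") +
    ggplot2::geom_line(data = front, colour = "forestgreen",
                       linewidth = 0.8) +
    ggplot2::labs(x = "relative signal collection efficiency",
                  y = "separation") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    ref <- evaluate_custom_setup(object$s1, object$s2, reference,
                                 epsilon = object$epsilon)
    p <- p + ggplot2::geom_point(data = ref, colour = "red", shape = 1,
                                 size = 3, stroke = 1.2)
  }
  if (log_separation) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
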
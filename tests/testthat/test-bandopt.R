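test_that("band powers, ratios, separation and efficiency match hand oracles", {
  fx <- fixture_5bin()
  s1 <- fx$s1
  s2 <- fx$s2
  pr <- band_pair(500, 510, 530, 540)

  # full-grid band collects all the probability mass
  expect_equal(band_power(s1, 500, 540), 1)
  # hand sums of two bins each
  expect_equal(band_power(s1, 500, 510), 0.7)
  expect_equal(band_power(s1, 530, 540), 0.1)

  expect_equal(band_ratio(s1, pr), 7)
  expect_equal(band_ratio(s2, pr), 1 / 7)

  # (7) / (1/7) = 49; geometric mean (0.7*0.1*0.1*0.7)^(1/4)
  expect_equal(as.numeric(band_separation(s1, s2, pr)), 49, tolerance = 1e-9)
  expect_equal(collection_efficiency(s1, s2, pr), (0.7 * 0.1 * 0.1 * 0.7)^0.25,
               tolerance = 1e-9)

  pr2 <- band_pair(500, 520, 530, 540)
  expect_equal(as.numeric(band_separation(s1, s2, pr2)),
               (0.9 / 0.1) / (0.3 / 0.7), tolerance = 1e-9)
  expect_equal(collection_efficiency(s1, s2, pr2),
               (0.9 * 0.1 * 0.3 * 0.7)^0.25, tolerance = 1e-9)

  # identical spectra cannot be separated
  expect_equal(as.numeric(band_separation(s1, s1, pr)), 1)
  # swapped branch flips only the flag
  expect_true(attr(band_separation(s2, s1, pr), "swapped"))
  expect_false(attr(band_separation(s1, s2, pr), "swapped"))

  # uniform PMF, symmetric equal-width bands: within-spectrum ratio 1
  u <- tibble::tibble(wavelength_nm = seq(500, 540, 10), pmf = rep(0.2, 5))
  expect_equal(band_ratio(u, pr), 1)
})

test_that("degenerate (near-zero power) bands raise errors", {
  fx <- fixture_5bin()
  # s1 has zero mass at 540; a single-node band there has zero power
  expect_error(band_ratio(fx$s1, band_pair(500, 510, 540, 540)),
               "Degenerate")
  expect_error(collection_efficiency(fx$s1, fx$s2,
                                     band_pair(500, 500, 540, 540)),
               "Degenerate")
  expect_error(band_power(fx$s1, 600, 650), "outside")
})

test_that("identical flat spectra split into equal halves reach efficiency 0.5", {
  wl <- seq(425, 650, by = 1)           # 226 nodes, even count
  flat <- tibble::tibble(wavelength_nm = wl, pmf = rep(1 / 226, 226))
  pr <- band_pair(425, 537, 538, 650)   # 113 + 113 nodes
  expect_equal(collection_efficiency(flat, flat, pr), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(band_separation(flat, flat, pr)), 1)
})

test_that("enumeration matches the brute-force quadruple count", {
  # 5-node lattice with zero minimum width: 35 pairs
  e5 <- enumerate_band_pairs(seq(500, 540, 10), step_nm = 10,
                             min_width_nm = 0)
  expect_equal(nrow(e5), 35)
  expect_equal(nrow(e5), brute_pair_count(5))

  # 2-node lattice: the single arrangement of two single-node bands
  e2 <- enumerate_band_pairs(c(500, 510), step_nm = 10, min_width_nm = 0)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$band1_start_nm, 500)
  expect_equal(e2$band2_start_nm, 510)

  # counts agree with brute force for n <= 12, with and without min width
  for (n in c(3, 6, 9, 12)) {
    lat <- seq(500, by = 5, length.out = n)
    expect_equal(nrow(enumerate_band_pairs(lat, 5, 0)), brute_pair_count(n, lat))
    if (n >= 4) {
      expect_equal(nrow(enumerate_band_pairs(lat, 5, 5)),
                   brute_pair_count(n, lat, min_width = 5))
    }
  }

  # every returned pair satisfies the strict non-overlap constraint
  e <- enumerate_band_pairs(seq(425, 650, 5), step_nm = 5)
  expect_true(all(e$band1_end_nm < e$band2_start_nm))
  expect_true(all(e$band1_start_nm <= e$band1_end_nm))
  expect_true(all(e$band2_start_nm <= e$band2_end_nm))

  # deterministic lexicographic ordering by the four edges
  expect_false(is.unsorted(e$band1_start_nm))
  key <- order(e$band1_start_nm, e$band1_end_nm,
               e$band2_start_nm, e$band2_end_nm)
  expect_equal(key, seq_len(nrow(e)))

  # lattice step must sit on the grid
  expect_error(enumerate_band_pairs(seq(425, 650, 2), step_nm = 5),
               "multiple")
  expect_error(enumerate_band_pairs(c(500, 505), step_nm = 5,
                                    min_width_nm = 5))
})

test_that("prefix-sum fast path equals direct per-pair summation", {
  grid <- seq(500, 595, by = 5)         # 20-node lattice
  pairs <- enumerate_band_pairs(grid, step_nm = 5, min_width_nm = 0)
  for (seed in 1:50) {
    s1 <- rand_pmf(grid, seed)
    s2 <- rand_pmf(grid, seed + 1000)
    res <- optimize_bands(s1, s2, pairs = pairs)
    expect_equal(res$excluded_count, 0)
    worst_sep <- 0
    worst_eff <- 0
    # spot-check every 7th pair against the brute-force oracle
    idx <- seq(1, nrow(res$pairs), by = 7)
    for (r in idx) {
      row <- res$pairs[r, ]
      bm <- brute_metrics(s1, s2, c(row$band1_start_nm, row$band1_end_nm,
                                    row$band2_start_nm, row$band2_end_nm))
      worst_sep <- max(worst_sep, abs(bm$separation - row$separation))
      worst_eff <- max(worst_eff, abs(bm$efficiency - row$efficiency))
    }
    expect_lt(worst_sep, 1e-9)
    expect_lt(worst_eff, 1e-9)
  }
})

test_that("optimize_bands on identical spectra gives separation 1 everywhere", {
  grid <- seq(425, 650, by = 5)
  s <- rand_pmf(grid, 3)
  res <- optimize_bands(s, s, step_nm = 5)
  expect_true(all(abs(res$pairs$separation - 1) < 1e-9))
})

test_that("metric bounds and symmetries hold on random inputs", {
  grid <- seq(425, 650, by = 5)
  pairs <- enumerate_band_pairs(grid, step_nm = 5, min_width_nm = 0)
  for (seed in 1:10) {
    s1 <- rand_pmf(grid, seed)
    s2 <- rand_pmf(grid, seed + 500)
    res <- optimize_bands(s1, s2, pairs = pairs)
    expect_true(all(res$pairs$efficiency <= 0.5 + 1e-12))
    expect_true(all(res$pairs$efficiency > 0))
    expect_true(all(res$pairs$separation >= 1 - 1e-12))

    # exchanging s1 and s2 flips only the swapped flag
    res_sw <- optimize_bands(s2, s1, pairs = pairs)
    expect_equal(res_sw$pairs$separation, res$pairs$separation,
                 tolerance = 1e-12)
    expect_equal(res_sw$pairs$efficiency, res$pairs$efficiency,
                 tolerance = 1e-12)
    tied <- abs(res$pairs$separation - 1) < 1e-12
    expect_equal(res_sw$pairs$swapped[!tied], !res$pairs$swapped[!tied])
  }
})

test_that("metrics are invariant to the absolute intensity of the raw input", {
  grid <- seq(425, 650, by = 1)
  raw <- withr::with_seed(5, spectrum_tbl(grid, runif(length(grid), 0.1, 1)))
  raw2 <- withr::with_seed(6, spectrum_tbl(grid, runif(length(grid), 0.1, 1)))
  pr <- band_pair(450, 500, 550, 600)
  base_sep <- as.numeric(band_separation(normalize_pmf(raw),
                                         normalize_pmf(raw2), pr))
  base_eff <- collection_efficiency(normalize_pmf(raw), normalize_pmf(raw2), pr)
  for (c_ in c(0.01, 3.7, 1e4)) {
    scaled <- spectrum_tbl(grid, c_ * raw$intensity)
    expect_equal(as.numeric(band_separation(normalize_pmf(scaled),
                                            normalize_pmf(raw2), pr)),
                 base_sep, tolerance = 1e-12)
    expect_equal(collection_efficiency(normalize_pmf(scaled),
                                       normalize_pmf(raw2), pr),
                 base_eff, tolerance = 1e-12)
  }
})

test_that("pareto_front matches the O(n^2) dominance oracle", {
  grid <- seq(425, 650, by = 5)
  for (seed in c(2, 9, 21)) {
    s1 <- rand_pmf(grid, seed)
    s2 <- rand_pmf(grid, seed + 100)
    res <- optimize_bands(s1, s2, step_nm = 15, min_width_nm = 0)
    expect_lte(nrow(res$pairs), 5000)
    front <- pareto_front(res)

    keep <- brute_front(res$pairs$efficiency, res$pairs$separation)
    oracle <- res$pairs[keep, ]
    expect_equal(nrow(front), nrow(oracle))
    expect_equal(
      dplyr::arrange(front, .data$band1_start_nm, .data$band1_end_nm,
                     .data$band2_start_nm, .data$band2_end_nm),
      dplyr::arrange(oracle, .data$band1_start_nm, .data$band1_end_nm,
                     .data$band2_start_nm, .data$band2_end_nm)
    )

    # envelope shape: sorted by efficiency descending, separation
    # non-decreasing as efficiency drops
    expect_true(all(diff(front$efficiency) <= 1e-12))
    expect_true(all(diff(front$separation) >= -1e-12))

    # every non-front pair is dominated by some front pair
    rest <- res$pairs[!keep, ]
    dominated <- vapply(seq_len(nrow(rest)), function(r) {
      any(front$efficiency >= rest$efficiency[r] &
            front$separation > rest$separation[r])
    }, logical(1))
    expect_true(all(dominated))
  }
})

test_that("pareto_front of a single evaluated pair is that pair", {
  fx <- fixture_5bin()
  res <- optimize_bands(fx$s1, fx$s2, step_nm = 10, min_width_nm = 0)
  res$pairs <- res$pairs[7, ]
  expect_equal(pareto_front(res), res$pairs)
})

test_that("match_at_efficiency maximizes separation within the tolerance band", {
  grid <- seq(425, 650, by = 1)
  sp <- two_class_pair(shift_nm = 15, grid = grid, noise_sd = 0)
  s1 <- normalize_pmf(sp$a)
  s2 <- normalize_pmf(sp$b)
  res <- optimize_bands(s1, s2, step_nm = 5)
  ref <- band_pair(440, 490, 510, 650)
  m <- match_at_efficiency(res, ref, rel_tolerance = 0.001)

  ref_metrics <- evaluate_custom_setup(s1, s2, ref)
  # the reference is always a candidate, so gain >= 1
  expect_gte(m$gain, 1)
  expect_gte(m$separation, ref_metrics$separation)
  expect_equal(m$reference_separation, ref_metrics$separation)

  # exhaustive scan oracle: no in-tolerance pair separates better
  in_tol <- res$pairs[abs(res$pairs$efficiency - ref_metrics$efficiency) <=
                        0.001 * ref_metrics$efficiency, ]
  expect_gte(nrow(in_tol), 1)
  expect_gte(m$separation, max(in_tol$separation))
  expect_true(abs(m$efficiency - ref_metrics$efficiency) <=
                0.001 * ref_metrics$efficiency + 1e-12)
})

test_that("evaluate_custom_setup agrees with the optimize() table on-lattice", {
  grid <- seq(425, 650, by = 5)
  s1 <- rand_pmf(grid, 13)
  s2 <- rand_pmf(grid, 14)
  res <- optimize_bands(s1, s2, step_nm = 5, min_width_nm = 0)
  row <- res$pairs[4321, ]
  ev <- evaluate_custom_setup(s1, s2, c(row$band1_start_nm, row$band1_end_nm,
                                        row$band2_start_nm, row$band2_end_nm))
  expect_equal(ev$separation, row$separation, tolerance = 1e-12)
  expect_equal(ev$efficiency, row$efficiency, tolerance = 1e-12)
  expect_equal(ev$swapped, row$swapped)

  # identical spectra: separation exactly 1
  expect_equal(evaluate_custom_setup(s1, s1, band_pair(450, 500, 550, 600))$separation,
               1)

  # the literature NAD(P)H/FAD reference setup is accepted
  expect_silent(band_pair(410, 490, 510, 650))
})

test_that("band_pair rejects overlap and disorder", {
  expect_error(band_pair(410, 490, 490, 650), "overlap")
  expect_error(band_pair(490, 410, 510, 650), "start <= end")
  expect_error(as_band_pair(c(1, 2, 3)), "band_pair")
})

test_that("tidy and glance expose the evaluated pairs and their extrema", {
  fx <- fixture_5bin()
  res <- optimize_bands(fx$s1, fx$s2, step_nm = 10, min_width_nm = 0)
  expect_identical(tidy(res), res$pairs)
  g <- glance(res)
  expect_equal(g$n_pairs, nrow(res$pairs))
  expect_equal(g$n_pairs + g$excluded_count, 35)
  expect_equal(g$max_separation, 49)
  expect_equal(g$max_efficiency, max(res$pairs$efficiency))
})

test_that("autoplot returns a ggplot scatter with a reference mark", {
  fx <- fixture_5bin()
  res <- optimize_bands(fx$s1, fx$s2, step_nm = 10, min_width_nm = 0)
  p <- autoplot(res, reference = band_pair(500, 510, 530, 540))
  expect_s3_class(p, "ggplot")
})
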
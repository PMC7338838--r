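# Independent brute-force oracles and small fixtures shared across tests.

# random PMF spectrum on a grid, reproducible
rand_pmf <- function(grid, seed) {
  withr::with_seed(seed, {
    normalize_pmf(spectrum_tbl(grid, runif(length(grid), 0.01, 1)))
  })
}

# the worked 5-bin fixture: linearly decreasing PMF and its reverse
fixture_5bin <- function() {
  wl <- seq(500, 540, by = 10)
  list(
    s1 = tibble::tibble(wavelength_nm = wl, pmf = c(0.4, 0.3, 0.2, 0.1, 0.0)),
    s2 = tibble::tibble(wavelength_nm = wl, pmf = c(0.0, 0.1, 0.2, 0.3, 0.4))
  )
}

# direct per-pair summation of the two metrics, no prefix sums
brute_metrics <- function(s1, s2, pair, epsilon = 1e-12) {
  pw <- function(s, lo, hi) {
    sum(s$pmf[s$wavelength_nm >= lo & s$wavelength_nm <= hi])
  }
  p <- c(pw(s1, pair[1], pair[2]), pw(s1, pair[3], pair[4]),
         pw(s2, pair[1], pair[2]), pw(s2, pair[3], pair[4]))
  if (any(p <= epsilon)) return(NULL)
  r <- (p[1] / p[2]) / (p[3] / p[4])
  list(separation = max(r, 1 / r), efficiency = prod(p)^0.25)
}

# brute-force count of edge quadruples i <= j < k <= l on an n-node lattice
brute_pair_count <- function(n, lat = seq_len(n), min_width = 0) {
  count <- 0L
  for (i in 1:n) for (j in i:n) for (k in 1:n) for (l in k:n) {
    if (j < k && lat[j] - lat[i] >= min_width && lat[l] - lat[k] >= min_width) {
      count <- count + 1L
    }
  }
  count
}

# O(n^2) dominance oracle: row r is on the front iff no other row has
# efficiency >= eff[r] and separation > sep[r]
brute_front <- function(eff, sep) {
  n <- length(eff)
  keep <- logical(n)
  for (r in seq_len(n)) {
    keep[r] <- !any(eff >= eff[r] & sep > sep[r])
  }
  keep
}
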
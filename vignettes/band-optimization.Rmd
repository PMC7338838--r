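---
title: "Optimal spectral band pairs for two-channel fluorescence detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal spectral band pairs for two-channel fluorescence detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandsep)
```

## The problem

Two-channel fluorescence detection — the standard way to read out metabolic
biomarkers such as NAD(P)H and FAD from cellular autofluorescence — sends
the emitted light through two band-pass filters onto two detectors. The
choice of the two pass bands controls two competing quantities:

* **separation**: how differently the two specimen classes (say, cancerous
  and normal cells, whose autofluorescence spectra are mutually
  blue-shifted) distribute their light across the two bands, which bounds
  the achievable classification contrast;
* **relative signal collection efficiency**: how much of the available
  light the two bands actually collect, which scales the achievable SNR.

`bandsep` scores *every* non-overlapping two-band combination on a
wavelength lattice for a given pair of emission spectra, so the trade-off
between the two quantities can be chosen deliberately rather than by
heuristics.

## The model

Each input spectrum is reduced to a probability mass function (PMF) on a
uniform wavelength grid: intensities divided by their total, so band
"powers" are probabilities and every downstream metric is independent of
absolute intensity. For a band pair $(B_1, B_2)$ with
$B_1 = [\lambda_{1,\mathrm{start}}, \lambda_{1,\mathrm{end}}]$ strictly
blue of $B_2$, and PMFs $S_1, S_2$:

* band power: $P_{b,i} = \sum_{\lambda \in B_b} S_i(\lambda)$ (closed
  intervals, both endpoint grid nodes included);
* within-spectrum ratio: $R_i = P_{1,i} / P_{2,i}$;
* separation: $R_1 / R_2$, or its reciprocal when that ratio is below 1
  (the channels merely need to be swapped, recorded in the `swapped`
  flag) — so separation $\ge 1$ always, with equality iff the pair
  cannot distinguish the spectra;
* efficiency: $(P_{1,1} P_{2,1} P_{1,2} P_{2,2})^{1/4}$, the geometric
  mean of the four band powers. It is maximal, $0.5$, exactly when each
  band collects half of each spectrum's light, and it penalizes any
  setup with one starved band.

All pairs are evaluated with a prefix-sum fast path (a band power is a
difference of two cumulative sums), and the upper envelope of the
separation-vs-efficiency cloud — the Pareto front — gives the maximal
achievable separation at every efficiency.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| working range | 425–650 nm | emission range analysed; chosen where detectors respond linearly and excitation light is excluded |
| working grid step | 1 nm | PMF sampling; band powers are sums over these nodes |
| smoothing window | 10 nm | boxcar width, matching a 10-nm spectrometer slit resolution |
| band-edge lattice `step_nm` | 5 nm | spacing of candidate band edges; ~2×10⁵ pairs over 425–650 nm evaluate in ~100 ms. A 1-nm lattice (~10⁸ pairs) is available by argument but rarely changes the front materially |
| `min_width_nm` | one lattice step | excludes single-node bands by default; set 0 to allow them (the high-separation regime favours narrow bands) |
| `epsilon` | 1e-12 | band powers at or below this are degenerate: the pair is excluded and counted, since empty spectral regions (e.g. flavin-like emission below ~470 nm) would otherwise produce unbounded ratios |
| match tolerance | 0.001 | relative efficiency window for `match_at_efficiency()`, i.e. "same efficiency within 0.1%" |

Design choices that were genuinely open:

* **Band-edge convention.** Bands are closed intervals and non-overlap is
  the strict inequality `band1_end < band2_start`. Enumeration is
  lexicographic in the four edges, and all tie-breaks (equal separation →
  higher efficiency → smallest edges) are deterministic, so identical
  inputs yield byte-identical output tables.
* **Baseline subtraction.** Two modes are provided — constant-minimum and
  dark-reference — both clipped at zero. Instrument-specific
  temperature-offset corrections are deliberately out of scope; users
  with such corrections should apply them before import.
* **Smoothing.** "Sliding window" is implemented as the simplest faithful
  reading: a centered boxcar over the smallest odd number of samples
  spanning the requested width, truncated at the edges. The sample count
  is derived from the median grid step so slightly non-uniform raw
  spectrometer grids are tolerated.
* **Pareto front definition.** A pair is dominated iff some other pair
  has efficiency ≥ its efficiency *and* strictly larger separation; the
  front is everything non-dominated. Pairs with identical metrics are all
  retained.

## Imaging and statistics

Hyperspectral cubes (row × col × wavelength) are reduced to two channel
images by integrating the in-band planes. For display, each channel is
scaled relative to its own histogram: mean − 2σ maps to 0 and mean + 5σ
to 1, clipped. The ratiometric (redox-type) image is red/(red + cyan)
per pixel, with zero-total pixels undefined (`NA`, excluded from all
statistics), optionally 2×2-binned.

Image SNR is estimated in the Fourier domain: power above a cutoff
spatial frequency is noise, power below (excluding DC) is signal, and
the SNR is the ratio of the two integrals. The phrase "four times the
theoretical resolution" is dimensionally ambiguous (resolution is a
length); we read it as $f_c = 4/r$ — four times the resolution-limit
frequency — and expose `cutoff_factor` so the alternative reading
$f_c = 1/(4r)$ is one argument away. The default resolution is the
two-photon lateral estimate $\lambda_{exc}/(2\,\mathrm{NA})$ with a
0.785-µm excitation wavelength and NA 0.8; both are overridable, and
the report records every convention used. Since this cutoff is derived
from a microscope's optics, synthetic-image tests pass `resolution_um`
values that place the cutoff inside the sampled frequency range. FFT
round-off leaves ~10⁻³⁰ relative power in analytically empty bands, so a
noise integral below 10⁻¹² of the signal integral is reported as the
infinite-SNR flag rather than a meaningless huge number.

Group comparison uses an absolute t-statistic ("T-ratio") on per-image
ratiometric means — Welch's unequal-variance form by default, the
pooled-variance Student form behind `var_equal = TRUE` — with sample
(n−1) standard deviations throughout. The *relative variability* of two
spectrum groups is defined here as the within-group standard deviation
of spectral centers of gravity divided by the between-group shift of
mean centers of gravity. This is a documented working definition of the
spread-over-shift idea; published variants of this quantity may differ
in detail, so values should not be compared across definitions.

## What the synthetic generator emulates — and what it does not

`two_class_model()` builds two Gaussian-mixture emission models: class B
with peaks at 470 nm (sd 35 nm, weight 0.7) and 540 nm (sd 45 nm,
weight 0.3) — loosely an NAD(P)H-plus-FAD-weighted autofluorescence
shape — and class A as the same mixture blue-shifted 15 nm, mimicking
the blue-shift of cancerous versus normal epithelial cell spectra.
These defaults are fixtures chosen once to have the right qualitative
structure (smooth, unimodal-to-bimodal, one class blue-shifted, heavy
spectral overlap); they are not calibrated to any cell line.

`synth_cube()` emulates a field of view with labelled regions: each
pixel's spectrum is its label's PMF times a mean photon count
(default 1000 counts per pixel, a realistic hyperspectral two-photon
budget), optionally modulated by a per-pixel brightness field standing
in for cell morphology, plus shot-like noise approximated as Gaussian
with variance equal to the signal — adequate above ~20 counts per
sample, cheap, and seedable. All generators are bit-reproducible for a
fixed seed.

What passing tests on this generator demonstrate: the algebraic bounds
and contracts of the optimizer, the analytic consistency of the
ratiometric pipeline, and the qualitative trade-off (narrower bands at
lower efficiency raise class contrast and group T-ratio while starving
individual channels of light). What they do not demonstrate: performance
on real autofluorescence, where multiple endogenous fluorophores,
instrument response, wavelength-dependent scattering and absorption, and
biological variability all shape the spectra. Quantities published for
measured cell cultures depend on those measured spectra and are not
reproducible from synthetic fixtures.

## Numerical choices

* PMF sums are exact cumulative sums; the fast path is tested against
  direct per-pair summation to 1e-9.
* Degenerate pairs are excluded, never patched with pseudo-counts; the
  exclusion count is part of the result object.
* `match_at_efficiency()` always includes the reference setup itself as
  a candidate, so its reported gain is ≥ 1 by construction.
* Test problem sizes: the bound sweep uses 1,000 random spectrum pairs
  on the 1-nm working grid with the 5-nm edge lattice (~1.9×10⁵ band
  pairs each); Pareto and matching oracles run on coarser lattices with
  ≤ 5,000 pairs where the quadratic dominance check is cheap; cube
  simulations use 32–64 px fields with 8 images per group.

## Known limitations

* Exactly two detection channels; no multi-channel extension.
* Ideal top-hat filter transmission; real filter edges and out-of-band
  leakage are not modelled.
* No excitation-side optimization, filter-catalog matching, mosaic
  stitching, or photobleaching correction.
* The shot-noise model is Gaussian, so very low photon counts (< ~20 per
  band) are outside its validity; ratio statistics become biased there.

## A worked example

```{r example, eval = FALSE}
sp <- two_class_pair(shift_nm = 15, noise_sd = 0)
s_a <- normalize_pmf(sp$a)
s_b <- normalize_pmf(sp$b)

res <- optimize_bands(s_a, s_b, step_nm = 5)
glance(res)
match_at_efficiency(res, band_pair(440, 490, 510, 650))
autoplot(res, reference = band_pair(440, 490, 510, 650))
```
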
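# bandsep

Optimal spectral band pairs for two-channel fluorescence detection.

## The problem

Label-free imaging of metabolic biomarkers — NAD(P)H and FAD in cellular
autofluorescence, for instance — typically splits the emitted light with
two band-pass filters onto two detectors and classifies specimens by the
ratio of the two channels. Because endogenous emission spectra overlap
heavily and shift with disease state and microenvironment, the filter
bands chosen by convention are rarely the bands that separate two given
specimen classes best. `bandsep` is for microscopists and biomedical
image analysts who have (or can record) the two emission spectra they
want to distinguish and need to pick the two filter bands deliberately.

## The method

Each emission spectrum is preprocessed (baseline subtraction, 10-nm
sliding-window smoothing, cropping to the 425–650 nm working range,
resampling) and normalized to a probability mass function (PMF)
$S_i(\lambda)$ so all results are independent of absolute intensity.
For every pair of non-overlapping closed bands
$B_1 = [\lambda_{1,s},\lambda_{1,e}]$, $B_2 = [\lambda_{2,s},\lambda_{2,e}]$
with $\lambda_{1,e} < \lambda_{2,s}$ on a 5-nm edge lattice, with band
powers $P_{b,i} = \sum_{\lambda \in B_b} S_i(\lambda)$:

- **separation** $= \max(\rho, 1/\rho)$ where
  $\rho = (P_{1,1}/P_{2,1}) \,/\, (P_{1,2}/P_{2,2})$ — the ratio of the
  two spectra's within-spectrum band ratios, always ≥ 1;
- **relative signal collection efficiency**
  $= (P_{1,1}\,P_{2,1}\,P_{1,2}\,P_{2,2})^{1/4}$ — the geometric mean of
  the four band powers, in (0, 0.5], a proxy for the achievable SNR.

All ~2×10⁵ combinations are scored with a prefix-sum fast path, the
Pareto front gives the maximal achievable separation at every
efficiency, and `match_at_efficiency()` finds the best band pair at a
reference setup's efficiency (within 0.1%). Companion modules integrate
hyperspectral cubes into channel images, build cyan/red composites
(mean−2σ…mean+5σ scaling) and ratiometric red/(red+cyan) images,
estimate image SNR in the Fourier domain, and compare specimen groups
with a t-statistic on per-image ratio means. Seeded generators supply
synthetic spectra and cubes so the entire pipeline runs without
measured data.

## Worked example

```r
library(bandsep)

# synthetic two-class pair: class A blue-shifted 15 nm against class B
sp  <- two_class_pair(shift_nm = 15, noise_sd = 0)
s_a <- normalize_pmf(sp$a)
s_b <- normalize_pmf(sp$b)

res <- optimize_bands(s_a, s_b, step_nm = 5)
res
#> Band-pair optimization over 163185 valid pairs (0 excluded for near-zero band power)
#>   edge lattice: 5 nm; working grid step: 1 nm
#>   max separation 3.647 at efficiency 0.004906 (bands 425-430 / 645-650 nm)
#>   max efficiency 0.4812

match_at_efficiency(res, band_pair(440, 490, 510, 650))
#>   band1_start_nm band1_end_nm band2_start_nm band2_end_nm separation efficiency
#> 1            425          455            465          615   1.599015  0.3825162
#>   swapped reference_separation reference_efficiency     gain
#> 1   FALSE             1.378118            0.3824014 1.160289

autoplot(res, reference = band_pair(440, 490, 510, 650))
```

Reading the numbers: the conventional-style 440–490 / 510–650 nm setup
separates the two synthetic classes by a factor 1.378 while collecting
an efficiency-0.382 share of the light. At the *same* collection
efficiency (within 0.1%), the optimizer finds 425–455 / 465–615 nm with
separation 1.599 — a 16% contrast gain for free. The extreme of the
front (separation 3.65) uses two 5-nm slivers at the spectral edges and
collects almost no light (efficiency 0.005): the scatter plot makes
that trade-off explicit so you can choose a working point.

The same flow runs from the shell via the thin front end in
`inst/cli/bandopt.R` (subcommands `optimize`, `image`, `snr`, `stats`,
`synth`).

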
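Package: bandsep
Title: Optimal Spectral Band Pairs for Two-Channel Fluorescence Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selects optimal pairs of optical band-pass filter bands that
    maximize the separation between two fluorescence emission spectra at a
    chosen relative signal collection efficiency. Emission spectra are
    preprocessed (baseline subtraction, sliding-window smoothing, cropping,
    resampling) and normalized to probability mass functions; all
    non-overlapping two-band combinations on a wavelength lattice are scored
    by a ratio-of-ratios separation statistic and by the geometric mean of
    the four band powers, and the Pareto front of separation versus
    efficiency is extracted. Companion tools turn hyperspectral image cubes
    into two-channel composites and ratiometric (redox-type) images, estimate
    image signal-to-noise ratios in the Fourier domain, and compare specimen
    groups with a t-statistic on per-image ratio means. Seeded generators for
    synthetic spectra and hyperspectral cubes make the whole pipeline
    testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
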
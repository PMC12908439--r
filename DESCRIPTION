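Package: pronypv
Title: Prony Analysis of Left-Ventricular Pressure and Volume Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes uniformly sampled cardiovascular pressure and volume
    signals into sums of exponentially damped sinusoids (Prony analysis) via
    linear prediction on a Hankel system, companion-matrix polynomial rooting,
    and Vandermonde least squares with an optimized time-scaling factor.
    Provides amplitude, damping and phase spectra, Fourier-based comparators,
    complex-pole stability classification and unit-circle metrics, stable-pole
    refits, and an analytic pressure-to-volume transfer function with Bode
    curves. Includes a seeded generator for synthetic pulsatile
    pressure-volume waveforms and exact damped-sinusoid test signals, plus
    delimited-text readers/writers and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
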
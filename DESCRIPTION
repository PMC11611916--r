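Package: thzcryst
Title: Terahertz Time-Domain Crystallinity Monitoring of Drug Polymorphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying crystalline polymorph content in drug
    tablets from terahertz time-domain spectroscopy (THz-TDS) transmission
    scans. Implements the full analysis chain for in-situ aging studies of
    amorphous nifedipine: waveform conditioning (DC-offset removal, Tukey
    windowing, zero-padded Fourier transformation), extraction of the
    frequency-dependent refractive index and absorption coefficient from
    sample/reference pulse pairs, decomposition of absorption spectra into
    three-Gaussian-plus-quadratic reference models for the alpha and beta
    polymorphs, constrained linear fitting of polymorph coefficients A and B,
    and replicate-aggregated kinetics time series. A synthetic-study
    generator emulates the instrument (single-cycle pulse, plano-parallel
    slab transmission, sequential amorphous-to-beta-to-alpha kinetics with
    temperature-dependent rates, averaged detector noise) so that every
    stage is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    pracma,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
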
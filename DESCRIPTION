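Package: fluctens
Title: Membrane Fluctuation Tension Mapping and Ligand Self-Association
    Analytics
Version: 0.1.0
Authors@R:
    person("fluctens", "maintainers", email = "fluctens@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for interference reflection microscopy
    (IRM) membrane-fluctuation analysis and oligonucleotide ligand
    biophysics. Converts interference intensity movies to relative
    membrane height, estimates power spectral densities (Welch-averaged
    periodogram or autoregressive Burg), fits the Helfrich-based
    fluctuation model for membrane tension, confinement, effective
    viscosity and active temperature, and produces filtered pixel-wise
    tension and SD_time maps. Adds correlative cluster-local tension
    profiling (registration, peak detection, center-normalized line
    scans, local tension surge), object-based endosome/actin
    colocalization with 8-connectivity and Manders coefficients, SAXS
    Guinier/Kratky shape analytics, FCS autocorrelation fitting with
    diffusion calibration, and small quantification utilities
    (nuclear:cytoplasmic ratio, qPCR relative expression). Every input
    can be generated synthetically with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
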
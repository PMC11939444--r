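Package: rfdosim
Title: Dosimetry, Thermal Control and Gene-Expression Readout for a 1.8 GHz
    RF Exposure System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising a far-field radiofrequency cell-culture
    exposure system and analysing its biological readout. Implements the
    probe-to-power dosimetry chain (dBm to watt, cable attenuation, antenna
    factor, plane-wave power flux), field-validity statistics on gridded field
    maps (inhomogeneity, polarization ratios, Poynting/plane-wave ratio),
    ICNIRP general-public reference levels, a lossless radiative heating
    budget, a PID/PWM hot-water temperature-regulation simulator with
    Internal Model Control tuning and first-order-plus-dead-time plant
    identification, a qPCR relative-expression pipeline (delta-delta-Ct,
    ANOVA with Tukey contrasts against sham) with amplitude-ladder
    dose-response shape classification (flat, monotonic, biphasic/U-shaped),
    and seeded synthetic-data generators so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
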
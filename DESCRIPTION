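Package: fendor
Title: Simulation and Analysis of Gd(III) ENDOR Spectra and Nuclear Decoherence
Version: 0.1.0
Authors@R:
    person("F.", "Endor", email = "fendor@example.org", role = c("aut", "cre"))
Description: Forward simulation and least-squares fitting of powder 19F/1H
    Mims-ENDOR spectra of Gd(III) spin labels (point-dipole hyperfine with
    optional 19F chemical-shift anisotropy), stretched-exponential analysis of
    electron spin-lattice relaxation, extraction of nuclear coherence times
    from nuclear-spin-echo decays, and quantitative comparison with the
    Solomon-Bloembergen-Morgan and slow-relaxation-limit theories of nuclear
    decoherence near a paramagnetic centre. Includes a seeded synthetic-data
    generator emulating the spectrometer data products, plain-text trace and
    spectrum file I/O, and an end-to-end analysis pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
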
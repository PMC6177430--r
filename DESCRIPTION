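Package: cochlenv
Title: Envelope Detection by Cochlear Mechanoelectrical Transduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the hearing organ extracts the envelope of
    complex sounds. Synthesizes three-tone complexes whose envelope shape is
    controlled by the centre-tone phase without changing the magnitude
    spectrum, computes Hilbert-envelope spectra, models mechanoelectrical
    transduction (MET) channel rectification with a memoryless first-order
    Boltzmann activation curve, tracks intermodulation distortion products,
    corrects recordings for first-order electrode low-pass filtering,
    generates synthetic basilar-membrane, organ-of-Corti and round-window
    recordings with realistic noise, and provides the permutation and
    phase-effect regression statistics used to analyse phase sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
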
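Package: qrelax
Title: Quantitative MRI Relaxometry for USPIO Uptake Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelwise quantitative MRI relaxometry for measuring uptake of
    ultrasmall superparamagnetic iron-oxide (USPIO) contrast agents.
    Implements B1-insensitive R1 mapping by joint fitting of multi-flip-angle
    spoiled gradient-echo and inversion-recovery-prepared spoiled
    gradient-echo data (DESPOT1-HIFI) with a choice of pulse-train signal
    models, multi-echo R2* mapping with Rician noise-floor exclusion,
    inversion-recovery spin-echo gold-standard fitting, blood-normalised
    relaxation-rate-change (cerebral blood volume) metrics with cohort
    statistics, and a digital multi-compartment phantom and synthetic USPIO
    cohort generator for end-to-end validation at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
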
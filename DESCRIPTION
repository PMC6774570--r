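Package: sexbias
Title: Sex-Biased Demography Inference from X-Chromosomal and Autosomal
    Site Frequency Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint Poisson random field modeling of X-chromosomal and
    autosomal site frequency spectra under multi-epoch demographic models.
    Provides closed-form relationships between the proportion of breeding
    females, effective population sizes and the X-to-autosome ratio Q;
    an exact expected-SFS engine for piecewise-constant and exponential
    demographies; nested likelihood-ratio tests for constant and changing
    sex-bias; closed-form and diversity-based estimators of the effective
    proportion of females; parametric and block bootstraps; coalescent and
    independent-sites simulators; and SFS/VCF input handling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
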
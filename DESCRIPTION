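Package: datspectnorm
Title: Reconstruction- and Calibration-Aware Normal Databases for Dopamine
    Transporter SPECT Quantification
Version: 0.1.0
Authors@R:
    person("DaT-SPECT", "Quantification Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for assessing [123I]FP-CIT (DaTSCAN) SPECT scan normality
    with a quantitative normal database. Provides a synthetic striatal
    phantom and cohort generator with image-space reconstruction effects
    (point-spread blurring, scatter/septal-penetration background,
    attenuation loss, Butterworth post-filtering, Poisson noise), tight-VOI
    and large-VOI specific binding ratio (SBR) quantification, phantom-based
    scanner characterisation (linear measured-vs-true SBR calibration),
    age-dependent normal-range fitting with lower-limit classification, and
    paired diagnostic-performance evaluation (sensitivity/specificity,
    DeLong ROC AUC and paired AUC comparison, McNemar test). A single-config
    driver runs the full reconstruction x quantifier x calibration study
    grid on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
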
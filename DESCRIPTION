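Package: lepsica
Title: Source Imaging and Group ICA of Laser-Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of emotional modulation of laser-evoked
    potentials (LEPs): synthetic multi-subject, multi-condition EEG with known
    dipole ground truth; preprocessing (common average reference, PCA artifact
    removal, epoching, zero-phase band-pass filtering, baseline correction,
    averaging, global field power); a three-shell spherical-head lead field;
    the LAURA (local autoregressive average) distributed linear inverse;
    group spatial independent component analysis with Infomax and ICASSO
    stability selection; and pointwise repeated-measures statistics with
    Greenhouse-Geisser correction and max-statistic permutation control of
    the family-wise error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
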
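Package: alpsdti
Title: Diffusion-Tensor ALPS Index Analysis of Glymphatic Activity During Sleep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the diffusion tensor image
    analysis along the perivascular space (DTI-ALPS) index, a non-invasive
    MRI marker of glymphatic activity. Provides synthetic two-shell
    diffusion-weighted phantoms with sleep-state modulation of perivascular
    diffusivity and Rician noise, weighted least-squares tensor fitting
    restricted to the low-b shell, template-space region-of-interest
    placement with primary-eigenvector alignment checks, the ALPS ratio and
    its numerator/denominator decomposition, EEG-consensus sleep annotation
    and subject inclusion rules, and time-resolved nonparametric statistics
    (Friedman test, Benjamini-Hochberg correction, exact Wilcoxon
    signed-rank tests with effect sizes, Fleiss' kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
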
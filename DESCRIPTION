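Package: aftwin
Title: Left-Atrial Digital Twins for Virtual Antiarrhythmic Drug Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds desk-scale left-atrial digital twins and runs virtual
    antiarrhythmic drug tests on them. Implements a Courtemanche-family
    human atrial myocyte model with atrial-fibrillation remodeling and an
    acetylcholine-activated potassium current, Hill-equation multichannel
    drug blockade, inverse-distance-weighted voltage interpolation with
    probabilistic fibrosis assignment, fiber-anisotropic monodomain
    reaction-diffusion simulation on 2D sheets with virtual pulmonary-vein
    isolation lesions, ramp-pacing atrial-fibrillation induction with
    rhythm-outcome classification, and the Smax (maximal restitution
    slope) and dominant-frequency biomarker maps used to stratify virtual
    drug response. A synthetic-cohort generator emulates electroanatomical
    voltage maps so the full pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    minpack.lm,
    yaml,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
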
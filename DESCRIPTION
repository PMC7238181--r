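Package: filadose
Title: Design of Passively Drug-Loaded Filaments and 3D-Printed Tablets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational workflow for designing passively drug-loaded fused
    deposition modelling (FDM) filaments and 3D-printed solid dosage forms.
    Provides Hansen solubility parameter (HSP) screening of drug-solvent-
    filament combinations, steady-state flux and permeability estimation from
    loading time courses, drug-release kinetic modelling (zero order, first
    order, Hixson-Crowell, Korsmeyer-Peppas) with mechanism classification,
    humidity-corrected Arrhenius shelf-life prediction from accelerated
    stability studies, surface-roughness and three-point-bend descriptors,
    and a multivariate predictive model of drug flux (PCA plus support vector
    regression). A synthetic-data generator with known ground truth emulates
    every raw instrument output the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    mixOmics,
    pracma,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
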
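Package: chainmig
Title: Agent-Based Simulation of Neuroblast Chain Migration Among Astrocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates collective migration of neuroblasts through a field of
    deformable astrocyte obstacles on a periodic two-dimensional domain.
    Neuroblasts are two-anchor "dumbbell" agents that advance by saltatory
    cycles of process extension and somal translocation; astrocytes are
    clusters of circular units that shrink in response to nearby neuroblasts
    (a contact-range abstraction of Slit-Robo signalling). The package
    provides seeded trial runs, condition sweeps (astrocyte density, reactive
    versus mismatched shrinkage, constant versus inconstant saltation
    amplitude and intercellular adhesion), and an evaluation layer that
    regresses forward migration speed on local collectivity to quantify when
    collective migration outperforms solitary migration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
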
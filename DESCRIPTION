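Package: mopforge
Title: Fragment-Based Design and Optimization of Metal-Organic Polyhedra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for fragment-based inverse design of metal-organic
    polyhedra (MOPs). Organic chemical building units (CBUs) are decomposed
    into typed molecular fragments (binding groups, linkers, nodes, side
    chains) by cleaving exocyclic single bonds, and reassembled into new
    CBUs via typed templates, either at the SMILES level for fast
    enumeration or at the geometry level for 3D structures. CBUs are
    combined with metal units into cage structures by a purely geometric
    assembly protocol, and cage properties (inner-sphere cavity volume,
    window diameter, synthetic accessibility, mean guest interaction energy
    from Widom insertion) are optimized with a fragment-encoded genetic
    algorithm. OpenBabel (via ChemmineOB) provides SMILES parsing,
    canonicalization and substructure matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
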
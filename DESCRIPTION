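Package: fragcr
Title: Energy-Based Molecular Fragmentation of Proteins with Fragment
    Combination Ranges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fragmentation engine for proteins and peptides that expresses
    four energy-based fragmentation schemes (molecular fractionation with
    hydrogen caps, the pair-pair approximation to the generalized many-body
    expansion, molecules-in-molecules, and the kernel energy method) within a
    common fragment-combination-range formalism. Provides covalent bond
    perception, backbone and hydrogen-bond annotation, neighbor and
    hierarchical coupling schemes, inclusion-exclusion coefficients, hydrogen
    link-atom capping, multilevel composite energies, iterative electrostatic
    embedding with point charges, deterministic synthetic polypeptide
    fixtures, mock energy backends, benchmark statistics, and an input-deck
    writer for external quantum-chemistry engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
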
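Package: mofscreen
Title: Hierarchical Virtual Screening of Metal-Organic Frameworks for Drug Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational pre-selection of metal-organic frameworks
    (MOFs) as drug-delivery carriers. Implements a hierarchical screening
    cascade: biocompatibility assessment of the building blocks (a curated
    metal-toxicity table plus an LD50-based three-class linker classifier with
    Shapley-value explanations), geometric porosity filtering via
    pore-limiting and largest-cavity diameters computed on periodic distance
    grids, grand canonical Monte Carlo estimation of drug-loading capacity for
    rigid guest models, and threshold-based ranking of candidate frameworks.
    Includes periodic-structure (CIF) input/output, MOF deconstruction into
    metal nodes and organic linkers, and synthetic-data generators (toy
    frameworks with closed-form pore metrics, lattice-gas systems with exact
    isotherms, and toxicity datasets with planted structure-activity rules)
    so every stage is testable without licensed structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
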
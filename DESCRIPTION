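Package: rxnmc
Title: Reaction-Based Monte Carlo Ligand Design over Combinatorial Synthon Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale engine for reaction-driven de novo ligand design by
    Monte Carlo Metropolis optimization. Candidate molecules are always products
    of predefined reactions applied to building-block (synthon) libraries, so
    every proposal is synthetically accessible by construction. Proposals are
    guided by fingerprint similarity through a geometrically weighted rank
    sampler with a dynamic step-size controller, aligned to the previous ligand
    pose by common-substructure atom mapping and rigid superposition, filtered
    on physicochemical properties and pocket location, and accepted by a
    Metropolis criterion on a size-normalized ligand-efficiency score. A
    pluggable scorer contract with a deterministic fingerprint-overlap
    surrogate lets the full optimization loop run and be tested without a
    docking engine. Includes a cascaded multi-round workflow, random-product
    baselines, diversity and novelty metrics, and a synthetic fixture-library
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
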
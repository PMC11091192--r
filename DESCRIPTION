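Package: chrom4d
Title: Multiscale Chromatin Polymer Simulation and 4D Contact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Molecular-dynamics simulation and analysis of chromatin polymer
    models in which folding is driven jointly by binder-mediated phase
    separation (Strings-and-Binders) and loop extrusion. Provides a Langevin
    bead-spring engine with typed binding sites, diffusing binders and
    mobile extruding springs halted at oriented anchors; model builders for
    A/B-compartment, TAD and single-locus scales; contact-map, saddle-plot,
    contact-probability and triplet-contact analysis; simplex fitting of
    ensemble mixtures; polymer shape descriptors and contact-time dynamics;
    simulated-annealing inference of binding-site profiles from contact
    maps; and cross-correlation of inferred binding sites with epigenetic
    tracks. Synthetic-data generators with planted structure exercise every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
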
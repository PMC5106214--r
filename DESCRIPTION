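Package: sir3coop
Title: Cooperative Binding of Sir3 to Nucleosome Pairs: Equilibrium,
    Kinetic and Genomic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of cooperative heterochromatin-reader
    binding to nucleosome templates. Fits equilibrium titrations (EMSA
    fraction-unbound or normalized biolayer-interferometry signal) with the
    Hill equation or a two-identical-independent-sites saturation model;
    decomposes BLI sensograms into mono- or bi-exponential association and
    dissociation phases with residual-based model selection and derivation
    of association rate constants; computes Boltzmann multi-state occupancy
    probabilities and pairwise selectivities from apparent dissociation
    constants and Hill coefficients; and aggregates subtelomeric ChIP-seq
    coverage into anchor-aligned, control-normalized ensemble profiles,
    including delta-CT qPCR fold enrichment. Seeded generators produce
    synthetic titrations, sensograms, coverage tracks and CT tables so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
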
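Package: coreHR
Title: Detection and Quantification of Homologous Recombination in
    Prokaryotic Core Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for detecting and quantifying
    intraspecific homologous recombination from multi-strain bacterial
    core-genome alignments. Implements five nonparametric sliding-window
    detection statistics (RDP, GENECONV, MaxChi, Chimaera, 3Seq-style
    maximum descent) with consensus event calling, MaxChi-based
    breakpoint refinement, event characterization (events per strain,
    fraction of genome recombined, size spectrum, GC content), moment
    estimators of r/m and rho/theta, NG86 pairwise dN/dS, ANIb from
    pairwise alignment coordinate tables, functional-category enrichment
    with FDR control, and the association statistics (Kruskal-Wallis,
    Jonckheere-Terpstra, Mantel and partial Mantel, path analysis) used
    to relate recombination levels to lifestyle and genomic variables.
    A coalescent-based genome-evolution simulator with recorded ground
    truth generates test data for all components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
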
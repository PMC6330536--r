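Package: octomap
Title: Single-Dose SNP Discovery, Linkage Mapping and Divergence Dating
    for Autopolyploid F1 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting highly autopolyploid genomes with
    transcriptome-derived single-dose markers. Implements the closed-form
    combinatorics of allele dosage and gamete segregation under random
    chromosome pairing, screening of single-dose SNP candidates from
    mpileup-style RNA-seq pileups by the pooled minor/major allele-ratio
    window, segregation-ratio quality control and co-segregation binning,
    two-point LOD linkage grouping with Kosambi map distances, detection of
    interchromosomal rearrangements against a diploid reference by synteny
    anchors, and Nei-Gojobori synonymous-substitution (Ks) divergence
    dating of orthologous coding sequences. A complete synthetic octoploid
    F1 cross simulator with ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
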
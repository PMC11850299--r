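Package: lociview
Title: Comparative Visualization of Annotated Genomic Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses annotated genomic loci from GenBank or extended GFF files
    (GFF3 with an embedded FASTA section), assigns coding sequences to protein
    homology groups, orders and clusters loci by proteome composition
    similarity with average-linkage (UPGMA) hierarchical clustering,
    classifies protein groups into conserved, intermediate and variable
    classes analogous to pangenome core/shell/cloud, and renders
    publication-quality vector PDF figures of aligned locus maps with
    homology connectors, automatic label placement and functional category
    strips. A single-genome browser mode stacks the gene map with GC content,
    GC skew and user-supplied coverage tracks (bedGraph) using
    image-width-aware moving-average smoothing. A synthetic fixture generator
    produces phage-like locus sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils,
    grDevices,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
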
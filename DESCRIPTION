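Package: hawmap
Title: Hawaiian SNP Mapping-by-Sequencing for C. elegans Mutant Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying causal mutations in Caenorhabditis elegans
    by pooled whole-genome sequencing of Hawaiian (CB4856) strain crosses.
    Implements the full bulked-segregant workflow: classification of pooled
    variant calls against Hawaiian and pre-mutagenesis background catalogs,
    detection of the mapping interval as the chromosomal span depleted of
    Hawaiian SNPs, filtering of homozygous nonsynonymous candidate lesions
    with a minimal codon-effect annotator, brood viability and
    complementation-test statistics, and verification of CRISPR/Cas9 HDR
    repair oligo designs (protospacer/PAM location, homology arms,
    PAM-silencing edits, diagnostic restriction sites). A meiotic-cross
    simulator generates truth-tagged pooled sequencing data so every stage
    is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, VariantDetection, Sequencing, LinkageDisequilibrium
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'classify.R'
    'crispr.R'
    'formats-io.R'
    'geneticMap.R'
    'interval.R'
    'pipeline.R'
    'synthetic-cross.R'
    'utils.R'
    'viability.R'
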
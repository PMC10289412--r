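Package: retroceRNA
Title: Retroelement Expression and miRNA-Sponge (ceRNA) Inference from RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intergenic LINE/LTR retroelement (RE) expression from
    aligned RNA-seq, scans differentially expressed RE transcripts for miRNA
    responsive elements (MREs) of the three canonical seed-match site types
    (8mer, 7mer-m8, 7mer-A1), converts RE expression into MRE expression to
    nominate miRNAs whose activity may be titrated by RE transcripts acting as
    competing endogenous RNAs (ceRNAs), and integrates externally predicted
    miRNA target-gene lists with differential gene expression to nominate
    genes released from miRNA control. Includes a fully deterministic
    synthetic-data generator (genome, repeat and gene annotations, alignments,
    miRNAs, target lists) with a ground-truth manifest so that every pipeline
    stage can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
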
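Package: chimeraCLIP
Title: miRNA-Target Chimera Discovery and Pairing-Rule Analysis from AGO CLIP Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns chimeric Argonaute (AGO) CLIP sequencing reads into unambiguous
    miRNA-target interactions and characterises miRNA pairing rules. Includes read
    demultiplexing, adapter trimming and duplicate collapse; reverse-mapping of mature
    miRNAs into reads to call miR-first and miR-last chimeras; unique genomic placement
    of target fragments and false-ligation estimation from mixing designs; clustering
    of chimeras into interactions with 75-nt target regions and transcript-region
    annotation; seed-match classification (8mer, 7mer-m8, 7mer-A1, 6mer, single
    mismatch, single bulge, G:U wobble); constrained intermolecular duplex minimum
    free-energy prediction; k-means discovery of binding classes with Fisher
    enrichment; de-novo 7mer motif discovery with a combined confidence statistic;
    miRNA seed-family paralogue specificity analysis; perturbation-response CDF
    statistics; and a fully specified synthetic-experiment generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
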
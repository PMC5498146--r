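Package: minimeta
Title: Sequence-Independent Genome Binning and Cell Counting for
    Microfluidic Mini-Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for microfluidic mini-metagenomic
    experiments in which an environmental sample is partitioned into 96
    sub-samples of a few cells each before amplification, sequencing and
    co-assembly.  Contigs are binned into genomes without using sequence
    composition or coverage depth: per-sub-sample coverage is thresholded
    into a binary occurrence map, every contig pair is scored with a
    hypergeometric point probability (single-term Fisher's exact test),
    and the resulting p-value matrix is embedded and density-clustered
    into genome bins.  Genome abundance is estimated by Poisson occupancy
    inversion (counting empty sub-samples), and within-population
    variation is quantified by confidence-filtered SNP calls classified
    as noncoding, synonymous or nonsynonymous, with NG86-style dN/dS.
    A synthetic-community simulator with full ground truth makes the
    entire pipeline testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    mclust,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
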
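## Shared fixtures and independent oracles, built in code at test time.

## bin table asserting ground truth (perfect binning)
truth_bin_table <- function(community) {
  df <- data.frame(contig_id = names(community$truth$contig_genome),
                   bin_id = unname(community$truth$contig_genome),
                   contig_length = unname(community$coverage$contig_lengths),
                   stringsAsFactors = FALSE)
  class(df) <- c("bin_table", "data.frame")
  df
}

## small one-genome community with a SNP model, for variation tests
snp_community <- function(seed, n_sites = 150, nonsyn_acceptance = 1) {
  cfg <- community_config(
    data.frame(genome_id = "g1", n_contigs = 8L, lambda = 2),
    n_subsamples = 48L,
    snp_model = list(n_sites = n_sites,
                     nonsyn_acceptance = nonsyn_acceptance),
    seed = seed)
  simulate_community(cfg)
}

## three genomes with very distinct presence patterns over 96 chambers
three_genome_occurrence <- function(seed = 12, contigs_per_genome = 12) {
  set.seed(seed)
  n <- 96
  patterns <- rbind(rbinom(n, 1, 0.6), rbinom(n, 1, 0.25), rbinom(n, 1, 0.1))
  pres <- patterns[rep(1:3, each = contigs_per_genome), ]
  ## light per-contig dropout so rows are not identical
  drop <- matrix(rbinom(length(pres), 1, 0.1), nrow(pres))
  pres <- pres * (1 - drop)
  rownames(pres) <- sprintf("g%d_c%02d", rep(1:3, each = contigs_per_genome),
                            rep(seq_len(contigs_per_genome), 3))
  colnames(pres) <- sprintf("s%02d", 1:n)
  structure(list(presence = pres, threshold = 2048, log2_coverage = NULL),
            class = "occurrence_matrix")
}

## wrap raw 2-D coordinates as an embedding object
fake_embedding <- function(Y) {
  colnames(Y) <- c("dim1", "dim2")
  structure(list(coordinates = Y, seed = 1L, method = "mds",
                 parameters = list()), class = "embedding")
}

## enumeration oracle for the hypergeometric point probability: over all
## C(n, x) placements of x X-present chambers among n, the exact fraction
## with overlap a against a fixed set of y Y-present chambers
enum_point_probability <- function(a, b, c, d) {
  n <- a + b + c + d
  x <- a + c              # chambers where X present
  y <- a + b              # chambers where Y present
  if (n == 0) return(1)
  if (x == 0) return(as.numeric(a == 0))
  sets <- combn(n, x)
  hits <- sum(apply(sets, 2, function(s) sum(s <= y) == a))
  hits / ncol(sets)
}

## brute-force adjusted Rand index by pair counting
pair_count_ari <- function(labels1, labels2) {
  n <- length(labels1)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same1 <- labels1[i] == labels1[j]
    same2 <- labels2[i] == labels2[j]
    if (same1 && same2) s11 <- s11 + 1
    else if (!same1 && !same2) s00 <- s00 + 1
    else if (same1) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  total <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / total
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(ifelse(s10 + s01 == 0, 1, 0))
  (s11 - expected) / (maxi - expected)
}

## write a minimal VCFv4.2 with per-sample AD fields; rows is a data.frame
## with chrom, pos, ref, alt, qual and a list-column ad of per-sample
## "ref,alt[,alt2]" strings
write_test_vcf <- function(rows, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (i in seq_len(nrow(rows))) {
    fields <- c(rows$chrom[i], rows$pos[i], ".", rows$ref[i], rows$alt[i],
                rows$qual[i], "PASS", ".", "GT:AD",
                paste0("./.:", rows$ad[[i]]))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

## independent line-scan count of biallelic-SNP records a VCF should yield
## (multiallelic rows contribute one record per single-base alternate)
scan_vcf_snp_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  total <- 0L
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (nchar(f[4]) != 1) next
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    total <- total + sum(nchar(alts) == 1)
  }
  total
}

## simple ORF fixture: one gene on a known sequence
single_orf_fixture <- function() {
  ## +-strand gene covering codons GGA AAA TGC at positions 11..19
  seq <- paste0("TTTTTTTTTT", "GGAAAATGC", "TTTTTTTTTT")
  orfs <- data.frame(contig_id = "ctg", start = 11L, end = 19L,
                     strand = "+", gene_id = "g1")
  list(seqs = c(ctg = seq), orfs = orfs)
}
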
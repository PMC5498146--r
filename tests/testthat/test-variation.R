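mk_snp_table <- function(rows, depths) {
  rd <- t(vapply(depths, function(d) vapply(d, `[`, 1L, 1L), integer(length(depths[[1]]))))
  ad <- t(vapply(depths, function(d) vapply(d, `[`, 1L, 2L), integer(length(depths[[1]]))))
  colnames(rd) <- colnames(ad) <- sprintf("s%02d", seq_len(ncol(rd)))
  snp_table(rows, rd, ad)
}

test_that("SNP filters apply quality, depth-support and alternate-only rules", {
  rows <- data.frame(contig_id = "c1", pos = c(100, 200, 300),
                     ref = "A", alt = "G", qual = c(200, 150, 200),
                     stringsAsFactors = FALSE)
  depths <- list(list(c(0L, 7L), c(10L, 0L)),    # passes all rules
                 list(c(0L, 7L), c(10L, 0L)),    # fails quality (150)
                 list(c(6L, 6L), c(10L, 0L)))    # het but no alt-only chamber
  fs <- filter_snps(mk_snp_table(rows, depths))
  expect_equal(fs$sites$pos, 100)
  expect_equal(unname(fs$calls[1, ]), c("alternate", "dominant"))

  ## with an alt-only chamber added, the (6,6) chamber is heterozygous and
  ## contributes one allele to each tally
  rows2 <- rows[3, ]
  depths2 <- list(list(c(6L, 6L), c(10L, 0L), c(0L, 9L)))
  fs2 <- filter_snps(mk_snp_table(rows2, depths2))
  expect_equal(nrow(fs2$sites), 1)
  expect_equal(unname(fs2$calls[1, ]), c("heterozygous", "dominant", "alternate"))
  expect_equal(fs2$sites$n_dominant, 2)   # dominant + het
  expect_equal(fs2$sites$n_alternate, 2)  # alternate + het
})

test_that("calls are only made with sufficient depth and quality is strict", {
  rows <- data.frame(contig_id = "c1", pos = c(10, 20), ref = "C", alt = "T",
                     qual = c(180, 181), stringsAsFactors = FALSE)
  depths <- list(list(c(2L, 2L), c(0L, 8L)),    # (2,2): 4 reads < 5 -> absent
                 list(c(2L, 2L), c(0L, 8L)))
  fs <- filter_snps(mk_snp_table(rows, depths))
  expect_equal(fs$sites$qual, 181)              # quality must exceed 180
  expect_equal(unname(fs$calls[1, ]), c("absent", "alternate"))
})

test_that("filter verdicts do not depend on sub-sample order", {
  comm <- snp_community(seed = 31, n_sites = 60)
  fs <- filter_snps(comm$snps)
  perm <- sample(ncol(comm$snps$ref_depth))
  shuffled <- snp_table(comm$snps$sites,
                        comm$snps$ref_depth[, perm],
                        comm$snps$alt_depth[, perm])
  fs2 <- filter_snps(shuffled)
  expect_equal(fs2$sites$pos, fs$sites$pos)
  expect_equal(fs2$sites$n_alternate, fs$sites$n_alternate)
})

test_that("classification distinguishes synonymous, nonsynonymous, noncoding", {
  fx <- single_orf_fixture()
  ## codon 1 GGA -> GGG third position: Gly -> Gly
  snps <- data.frame(contig_id = "ctg", pos = c(13, 14, 5),
                     ref = c("A", "A", "T"), alt = c("G", "G", "C"),
                     stringsAsFactors = FALSE)
  cls <- classify_snps(snps, fx$orfs, fx$seqs)
  expect_equal(cls[1], "synonymous")      # GGA -> GGG
  expect_equal(cls[2], "nonsynonymous")   # AAA -> GAA, Lys -> Glu
  expect_equal(cls[3], "noncoding")       # intergenic
})

test_that("minus-strand classification equals the reverse-complement gene", {
  set.seed(52)
  ## gene of 20 codons embedded mid-contig, once on + and once on - strand
  gene <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  flank1 <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  flank2 <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  fwd <- paste0(flank1, gene, flank2)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  rev_contig <- paste0(flank1, rc(gene), flank2)
  orf_fwd <- data.frame(contig_id = "f", start = 26L, end = 85L,
                        strand = "+", gene_id = "g")
  orf_rev <- data.frame(contig_id = "r", start = 26L, end = 85L,
                        strand = "-", gene_id = "g")
  for (i in 1:25) {
    off <- sample(0:59, 1)                 # offset within the gene (5'->3')
    ref <- substr(gene, off + 1, off + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cls_f <- classify_snps(
      data.frame(contig_id = "f", pos = 26 + off, ref = ref, alt = alt),
      orf_fwd, c(f = fwd))
    ## same gene position on the reverse-strand contig
    pos_r <- 85 - off
    cls_r <- classify_snps(
      data.frame(contig_id = "r", pos = pos_r,
                 ref = chartr("ACGT", "TGCA", ref),
                 alt = chartr("ACGT", "TGCA", alt)),
      orf_rev, c(r = rev_contig))
    expect_identical(cls_f, cls_r)
  }
})

test_that("NG86 site counts match per-codon enumeration of all 9 changes", {
  set.seed(64)
  n_codons <- 300
  gene <- paste(sample(c("A", "C", "G", "T"), n_codons * 3, replace = TRUE),
                collapse = "")
  orfs <- data.frame(contig_id = "c", start = 1L, end = n_codons * 3L,
                     strand = "+", gene_id = "g")
  sites <- count_ng86_sites(orfs, c(c = gene))
  ## brute force: walk every codon, try all 9 single-base changes
  code <- Biostrings::getGeneticCode("11")
  syn <- 0
  for (i in seq_len(n_codons)) {
    codon <- substr(gene, 3 * i - 2, 3 * i)
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] == code[[codon]]) syn <- syn + 1 / 3
    }
  }
  expect_equal(unname(sites["syn_sites"]), syn, tolerance = 1e-12)
  expect_equal(sum(sites), 3 * n_codons)
})

test_that("snp rate is SNPs per assembled bp", {
  expect_equal(snp_rate(30, 1e6), 3e-5)
  expect_equal(snp_rate(0, 1e6), 0)
  expect_error(snp_rate(5, 0), "positive")
  set.seed(2)
  n <- rpois(10, 40); len <- runif(10, 5e5, 5e6)
  expect_equal(snp_rate(n, len), n / len)
})

test_that("dN/dS handles zero tallies and both methods", {
  expect_equal(dn_ds(0, 10, 100, 50), 0)
  expect_true(is.na(dn_ds(5, 0, 100, 50)))
  expect_equal(dn_ds(6, 3, method = "count-ratio"), 2)
  ## equal per-site rates give a ratio of 1
  expect_equal(dn_ds(20, 10, 200, 100), 1)
})

test_that("uniform substitutions over coding sequence give dN/dS near 1", {
  vals <- vapply(1:20, function(sd) {
    comm <- snp_community(seed = sd, n_sites = 150)
    va <- summarize_variation(comm$snps, truth_bin_table(comm),
                              comm$orfs, comm$contig_seqs)
    va$dn_ds
  }, 1)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
})

test_that("injected all-synonymous SNP sets give dN/dS of exactly 0", {
  comm <- snp_community(seed = 5, n_sites = 60, nonsyn_acceptance = 0)
  va <- summarize_variation(comm$snps, truth_bin_table(comm),
                            comm$orfs, comm$contig_seqs)
  expect_equal(va$n_nonsynonymous, 0)
  expect_gt(va$n_synonymous, 0)
  expect_equal(va$dn_ds, 0)
})

test_that("variation summary classifications agree with simulator ground truth", {
  comm <- snp_community(seed = 8, n_sites = 80)
  fs <- filter_snps(comm$snps)
  fs <- classify_snps(fs, comm$orfs, comm$contig_seqs)
  truth <- comm$truth$snp_classes
  key <- paste(truth$contig_id, truth$pos)
  got <- fs$sites$classification
  want <- truth$class[match(paste(fs$sites$contig_id, fs$sites$pos), key)]
  expect_identical(got, want)
})
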
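## Population variation within genome bins: confidence filtering of SNP
## calls, noncoding/synonymous/nonsynonymous classification against ORFs, and
## dN/dS with NG86-style (equal-rate) site counting.

#' Confidence-filter SNP calls
#'
#' Three criteria keep a SNP:
#' \enumerate{
#'   \item site quality strictly greater than `quality_min` (default 180,
#'     aggregated over all sub-samples; the input's quality scale is taken as
#'     given, matching samtools/bcftools QUAL);
#'   \item per-sub-sample allele calls are made only where the sub-sample has
#'     at least `depth_min` reads at the site (default 5);
#'   \item the alternate allele appears as the *only* allele in at least one
#'     sub-sample.
#' }
#' A sub-sample with both alleles supported by at least `depth_min` reads is
#' called heterozygous — multiple cells of the same genome in one chamber —
#' and contributes one dominant and one alternate allele to the tallies.
#'
#' @param snps a [snp_table()]
#' @param quality_min site quality threshold (default 180)
#' @param depth_min per-sub-sample read support (default 5)
#' @return object of class `filtered_snps`: list with `sites` (kept SNP rows
#'   plus allele tallies `n_dominant`, `n_alternate`) and `calls` (character
#'   matrix sites x sub-samples with values `dominant`, `alternate`,
#'   `heterozygous`, `absent`).  May be empty.
#' @export
filter_snps <- function(snps, quality_min = 180, depth_min = 5L) {
  stopifnot(inherits(snps, "snp_table"))
  rd <- snps$ref_depth; ad <- snps$alt_depth
  total <- rd + ad
  calls <- matrix("absent", nrow(rd), ncol(rd), dimnames = dimnames(rd))
  callable <- total >= depth_min
  het <- callable & rd >= depth_min & ad >= depth_min
  dom <- callable & !het & rd > ad
  alt <- callable & !het & ad > rd
  calls[dom] <- "dominant"
  calls[alt] <- "alternate"
  calls[het] <- "heterozygous"
  alt_only <- rowSums(alt & rd == 0) > 0
  keep <- snps$sites$qual > quality_min & alt_only
  sites <- snps$sites[keep, , drop = FALSE]
  calls <- calls[keep, , drop = FALSE]
  sites$n_dominant <- rowSums(calls == "dominant") + rowSums(calls == "heterozygous")
  sites$n_alternate <- rowSums(calls == "alternate") + rowSums(calls == "heterozygous")
  rownames(sites) <- NULL
  structure(list(sites = sites, calls = calls,
                 quality_min = quality_min, depth_min = depth_min),
            class = "filtered_snps")
}

#' @method print filtered_snps
#' @export
print.filtered_snps <- function(x, ...) {
  cat(sprintf("filtered_snps: %d SNPs (quality > %g, depth >= %d)\n",
              nrow(x$sites), x$quality_min, x$depth_min))
  invisible(x)
}

## complement / reverse complement on plain character strings
revcomp <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
          collapse = ""), "", USE.NAMES = FALSE)
}
complement_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

#' Classify SNPs as noncoding, synonymous or nonsynonymous
#'
#' A SNP outside every ORF is noncoding.  Inside an ORF the alternate base is
#' substituted into its codon (reverse-complementing on the minus strand) and
#' the encoded amino acids are compared under the configured genetic code
#' (default bacterial/archaeal translation table 11; a change to or from a
#' stop counts as nonsynonymous).  A SNP falling in several overlapping ORFs
#' is classified against each and counted nonsynonymous if nonsynonymous in
#' any of them.
#'
#' @param snps a `filtered_snps` (or a data.frame with `contig_id`, `pos`,
#'   `ref`, `alt`)
#' @param orfs ORF table (see [read_orf_table()])
#' @param contig_seqs named character vector of contig sequences
#' @param genetic_code codon -> amino-acid map; default
#'   `Biostrings::getGeneticCode("11")`
#' @return character vector `"noncoding"|"synonymous"|"nonsynonymous"`, one
#'   per SNP; for a `filtered_snps` input the object is returned with a
#'   `classification` column added
#' @export
classify_snps <- function(snps, orfs, contig_seqs,
                          genetic_code = Biostrings::getGeneticCode("11")) {
  sites <- if (inherits(snps, "filtered_snps")) snps$sites else as.data.frame(snps)
  orfs <- validate_orf_table(orfs)
  cls <- character(nrow(sites))
  warned <- character(0)
  for (i in seq_len(nrow(sites))) {
    ctg <- sites$contig_id[i]; pos <- sites$pos[i]
    hits <- which(orfs$contig_id == ctg & orfs$start <= pos & orfs$end >= pos)
    if (length(hits) == 0) { cls[i] <- "noncoding"; next }
    seq <- contig_seqs[[ctg]]
    if (is.null(seq) || is.na(seq)) stop("no sequence for contig ", ctg)
    verdicts <- vapply(hits, function(h) {
      classify_in_orf(pos, sites$ref[i], sites$alt[i],
                      orfs$start[h], orfs$end[h], orfs$strand[h],
                      seq, genetic_code)
    }, "")
    bad <- hits[(orfs$end[hits] - orfs$start[hits] + 1) %% 3 != 0]
    newbad <- setdiff(paste(orfs$contig_id[bad], orfs$gene_id[bad]), warned)
    if (length(newbad) > 0) {
      warning("ORF length not a multiple of 3 (codon phase taken from start): ",
              paste(newbad, collapse = ", "))
      warned <- c(warned, newbad)
    }
    cls[i] <- if (any(verdicts == "nonsynonymous")) "nonsynonymous"
              else if (any(verdicts == "synonymous")) "synonymous"
              else "noncoding"
  }
  if (inherits(snps, "filtered_snps")) {
    snps$sites$classification <- cls
    return(snps)
  }
  cls
}

## classify one SNP against one ORF; returns "synonymous", "nonsynonymous",
## or "noncoding" for a partial trailing codon that cannot be translated
classify_in_orf <- function(pos, ref, alt, start, end, strand, seq, code) {
  if (strand == "+") {
    off <- pos - start                      # 0-based position in gene
    ci <- off %/% 3                         # codon index
    p1 <- start + ci * 3
    if (p1 + 2 > end) return("noncoding")   # partial trailing codon
    codon <- toupper(substr(seq, p1, p1 + 2))
    at <- off %% 3 + 1
    ref_g <- toupper(ref); alt_g <- toupper(alt)
  } else {
    off <- end - pos                        # 0-based position in gene (5'->3')
    ci <- off %/% 3
    p2 <- end - ci * 3                      # contig coord of codon's first base
    p1 <- p2 - 2
    if (p1 < start) return("noncoding")
    codon <- toupper(revcomp(substr(seq, p1, p2)))
    at <- off %% 3 + 1
    ref_g <- toupper(complement_base(ref)); alt_g <- toupper(complement_base(alt))
  }
  if (substr(codon, at, at) != ref_g)
    warning(sprintf("reference allele %s does not match contig base %s at %d",
                    ref_g, substr(codon, at, at), pos))
  mut <- codon
  substr(mut, at, at) <- alt_g
  aa1 <- code[[codon]]; aa2 <- code[[mut]]
  if (is.null(aa1) || is.null(aa2)) return("noncoding")  # ambiguous base
  if (identical(aa1, aa2)) "synonymous" else "nonsynonymous"
}

#' NG86 equal-rate synonymous and nonsynonymous site counts
#'
#' For every complete codon in the given ORFs, each of the three positions is
#' one site, split between synonymous and nonsynonymous in proportion to how
#' many of its three possible single-base changes preserve the amino acid
#' (changes to or from a stop count as nonsynonymous).  Summed over all
#' codons this gives the S and N denominators of the NG86 dN/dS estimator.
#'
#' @param orfs ORF table
#' @param contig_seqs named character vector of contig sequences
#' @param genetic_code default translation table 11
#' @return named numeric `c(syn_sites, nonsyn_sites)`
#' @export
count_ng86_sites <- function(orfs, contig_seqs,
                             genetic_code = Biostrings::getGeneticCode("11")) {
  orfs <- validate_orf_table(orfs)
  lut <- ng86_codon_sites(genetic_code)
  syn <- 0; nonsyn <- 0
  for (i in seq_len(nrow(orfs))) {
    seq <- contig_seqs[[orfs$contig_id[i]]]
    if (is.null(seq)) stop("no sequence for contig ", orfs$contig_id[i])
    g <- toupper(substr(seq, orfs$start[i], orfs$end[i]))
    if (orfs$strand[i] == "-") g <- revcomp(g)
    L <- nchar(g) - nchar(g) %% 3
    if (L < 3) next
    codons <- substring(g, seq(1, L - 2, 3), seq(3, L, 3))
    tab <- table(codons)
    known <- names(tab)[names(tab) %in% rownames(lut)]
    syn <- syn + sum(lut[known, "syn"] * as.numeric(tab[known]))
    nonsyn <- nonsyn + sum(lut[known, "nonsyn"] * as.numeric(tab[known]))
  }
  c(syn_sites = syn, nonsyn_sites = nonsyn)
}

## per-codon (syn, nonsyn) site lookup under a genetic code
ng86_codon_sites <- function(code) {
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  out <- matrix(0, length(codons), 2,
                dimnames = list(codons, c("syn", "nonsyn")))
  for (cd in codons) {
    s <- 0
    for (p in 1:3) for (b in setdiff(bases, substr(cd, p, p))) {
      mut <- cd
      substr(mut, p, p) <- b
      if (identical(code[[mut]], code[[cd]])) s <- s + 1 / 3
    }
    out[cd, "syn"] <- s
    out[cd, "nonsyn"] <- 3 - s
  }
  out
}

#' Per-genome SNP rate
#'
#' Total filtered SNPs normalized to the assembled genome length.
#'
#' @param n_snps total number of filtered SNPs in the bin
#' @param assembled_length total assembled bin length in bp (> 0)
#' @return fraction (SNPs per bp)
#' @export
snp_rate <- function(n_snps, assembled_length) {
  if (any(assembled_length <= 0)) stop("assembled_length must be positive")
  n_snps / assembled_length
}

#' dN/dS ratio
#'
#' Default method `"ng86"`: the ratio of per-site rates,
#' `(n_nonsyn / nonsyn_sites) / (n_syn / syn_sites)`, with site counts from
#' [count_ng86_sites()].  Method `"count-ratio"` is the raw
#' `n_nonsyn / n_syn`.  A value near 1 indicates no selection; values toward
#' 0 indicate purifying selection.  Undefined (`NA`) when the synonymous
#' tally is zero.
#'
#' @param n_nonsyn,n_syn nonsynonymous and synonymous SNP counts
#' @param nonsyn_sites,syn_sites NG86 site counts (required for `"ng86"`)
#' @param method `"ng86"` (default) or `"count-ratio"`
#' @return non-negative ratio, or `NA_real_` when undefined
#' @export
dn_ds <- function(n_nonsyn, n_syn, nonsyn_sites = NULL, syn_sites = NULL,
                  method = c("ng86", "count-ratio")) {
  method <- match.arg(method)
  if (n_syn == 0) return(NA_real_)
  if (method == "count-ratio") return(n_nonsyn / n_syn)
  if (is.null(nonsyn_sites) || is.null(syn_sites))
    stop("ng86 method needs nonsyn_sites and syn_sites")
  (n_nonsyn / nonsyn_sites) / (n_syn / syn_sites)
}

#' Per-bin variation summary
#'
#' Filters and classifies SNPs, then tallies them per genome bin with the SNP
#' rate and dN/dS.
#'
#' @param snps a [snp_table()] (filtered internally) or an already
#'   `filtered_snps` object
#' @param bins a `bin_table` mapping contigs to bins
#' @param orfs ORF table
#' @param contig_seqs named character vector of contig sequences
#' @param quality_min,depth_min passed to [filter_snps()]
#' @param dnds_method `"ng86"` (default) or `"count-ratio"`
#' @param genetic_code default translation table 11
#' @return data.frame per bin: `bin_id, n_noncoding, n_synonymous,
#'   n_nonsynonymous, assembled_length, snp_rate, dn_ds, dn_ds_method`
#' @export
summarize_variation <- function(snps, bins, orfs, contig_seqs,
                                quality_min = 180, depth_min = 5L,
                                dnds_method = c("ng86", "count-ratio"),
                                genetic_code = Biostrings::getGeneticCode("11")) {
  dnds_method <- match.arg(dnds_method)
  if (inherits(snps, "snp_table"))
    snps <- filter_snps(snps, quality_min, depth_min)
  stopifnot(inherits(snps, "filtered_snps"))
  if (is.null(snps$sites$classification))
    snps <- classify_snps(snps, orfs, contig_seqs, genetic_code)
  orfs <- validate_orf_table(orfs)
  ids <- setdiff(unique(bins$bin_id), "unbinned")
  rows <- lapply(ids, function(b) {
    members <- bins$contig_id[bins$bin_id == b]
    len <- sum(bins$contig_length[bins$bin_id == b])
    s <- snps$sites[snps$sites$contig_id %in% members, , drop = FALSE]
    tallies <- table(factor(s$classification,
                            levels = c("noncoding", "synonymous", "nonsynonymous")))
    ratio <- if (dnds_method == "ng86") {
      sites <- count_ng86_sites(orfs[orfs$contig_id %in% members, , drop = FALSE],
                                contig_seqs, genetic_code)
      dn_ds(tallies[["nonsynonymous"]], tallies[["synonymous"]],
            sites[["nonsyn_sites"]], sites[["syn_sites"]], method = "ng86")
    } else {
      dn_ds(tallies[["nonsynonymous"]], tallies[["synonymous"]],
            method = "count-ratio")
    }
    data.frame(bin_id = b,
               n_noncoding = tallies[["noncoding"]],
               n_synonymous = tallies[["synonymous"]],
               n_nonsynonymous = tallies[["nonsynonymous"]],
               assembled_length = len,
               snp_rate = snp_rate(nrow(s), len),
               dn_ds = ratio,
               dn_ds_method = dnds_method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
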
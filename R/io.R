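## Domain containers and file I/O.  All tables are UTF-8 TSV with header rows;
## genomic coordinates are 1-based inclusive throughout.

#' Construct a coverage matrix
#'
#' The raw analog signal of a mini-metagenomic experiment: for every contig and
#' every sub-sample, the number of base pairs of the contig covered by at least
#' one read from that sub-sample.
#'
#' @param values integer matrix, contigs in rows, sub-samples in columns, with
#'   dimnames giving contig and sub-sample identifiers.  All entries must be
#'   non-negative.
#' @param contig_lengths optional named vector of contig lengths (bp).  When
#'   supplied, every coverage entry is checked against its contig's length.
#' @return an object of class `coverage_matrix`: a list with elements `values`
#'   (integer matrix) and `contig_lengths` (named numeric or `NULL`).
#' @export
coverage_matrix <- function(values, contig_lengths = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("coverage matrix needs contig row names and sub-sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate contig ids in coverage matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sub-sample ids in coverage matrix")
  if (!is.numeric(values) || anyNA(values) || any(values < 0))
    stop("coverage values must be non-negative numbers")
  if (!is.null(contig_lengths)) {
    contig_lengths <- contig_lengths[rownames(values)]
    if (anyNA(contig_lengths))
      stop("contig_lengths missing for some contigs in the coverage matrix")
    if (any(contig_lengths <= 0))
      stop("contig lengths must be positive")
    bad <- which(values > contig_lengths[row(values)], arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf(
        "coverage exceeds contig length at contig '%s', sub-sample '%s'",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  structure(list(values = values, contig_lengths = contig_lengths),
            class = "coverage_matrix")
}

#' @method print coverage_matrix
#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %d contigs x %d sub-samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  covered bp range: [%g, %g]\n",
              min(x$values), max(x$values)))
  if (!is.null(x$contig_lengths))
    cat(sprintf("  total assembled length: %.3f Mbp\n",
                sum(x$contig_lengths) / 1e6))
  invisible(x)
}

#' Read a contig-by-sub-sample coverage table
#'
#' Reads a TSV whose first column holds contig identifiers and whose remaining
#' columns, one per sub-sample, hold the number of base pairs of the contig
#' covered by that sub-sample's reads (reference positions with depth >= 1, as
#' tabulated from a read alignment).  Sub-samples sequenced too shallowly are
#' unreliable; when per-sub-sample paired-end read counts are supplied, columns
#' below `min_reads_per_subsample` are dropped with a message.
#'
#' @param path TSV file; header row of sub-sample ids, first column contig ids.
#' @param min_reads_per_subsample sub-samples with fewer total paired-end reads
#'   than this are dropped (default 800,000).  Only applied when
#'   `subsample_read_counts` is given, since coverage alone cannot
#'   reconstruct read counts.
#' @param subsample_read_counts optional named vector (or 2-column TSV path)
#'   mapping each sub-sample id to its total paired-end read count.
#' @param contig_lengths optional named vector of contig lengths used to
#'   validate coverage entries.
#' @return a [coverage_matrix()].
#' @export
read_coverage_table <- function(path, min_reads_per_subsample = 8e5,
                                subsample_read_counts = NULL,
                                contig_lengths = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#", na.strings = "NA",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("coverage table needs a contig column and at least one sub-sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric coverage cell in ", path)
  rownames(m) <- ids
  if (is.character(subsample_read_counts) && length(subsample_read_counts) == 1) {
    rc <- read.delim(subsample_read_counts, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    subsample_read_counts <- setNames(as.numeric(rc[[2]]), as.character(rc[[1]]))
  }
  if (!is.null(subsample_read_counts)) {
    known <- colnames(m)[colnames(m) %in% names(subsample_read_counts)]
    low <- known[subsample_read_counts[known] < min_reads_per_subsample]
    if (length(low) > 0) {
      message(sprintf("dropping %d sub-sample(s) below %g paired-end reads: %s",
                      length(low), min_reads_per_subsample,
                      paste(low, collapse = ", ")))
      m <- m[, setdiff(colnames(m), low), drop = FALSE]
    }
  }
  coverage_matrix(m, contig_lengths)
}

#' Write a coverage table
#'
#' Inverse of [read_coverage_table()]; the written file round-trips.
#'
#' @param coverage a [coverage_matrix()]
#' @param path output TSV path
#' @export
write_coverage_table <- function(coverage, path) {
  stopifnot(inherits(coverage, "coverage_matrix"))
  df <- data.frame(contig_id = rownames(coverage$values),
                   coverage$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read contig lengths from FASTA or TSV
#'
#' @param path either a FASTA file of contig sequences (lengths are the
#'   sequence character counts) or a 2-column TSV `contig_id <TAB> length`.
#' @return named numeric vector of contig lengths (bp)
#' @export
read_contig_lengths <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 1 && startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (any(Biostrings::width(seqs) == 0)) stop("empty sequence in ", path)
    ids <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(ids)) stop("duplicate contig id in ", path)
    return(setNames(as.numeric(Biostrings::width(seqs)), ids))
  }
  df <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  ## tolerate a header row
  if (!is.numeric(df[[2]]) && suppressWarnings(is.na(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]
  len <- as.numeric(df[[2]])
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate contig id in ", path)
  if (anyNA(len) || any(len <= 0)) stop("contig lengths must be positive integers")
  setNames(len, ids)
}

#' Construct a SNP table
#'
#' One row per biallelic SNP plus per-sub-sample allele depths.
#'
#' @param sites data.frame with columns `contig_id`, `pos` (1-based bp),
#'   `ref`, `alt` (single bases, ref != alt), `qual` (non-negative site
#'   quality aggregated over all sub-samples).
#' @param ref_depth,alt_depth integer matrices (sites x sub-samples) of reads
#'   supporting the reference and alternate allele; equal dimnames.
#' @return object of class `snp_table`
#' @export
snp_table <- function(sites, ref_depth, alt_depth) {
  sites <- as.data.frame(sites)
  need <- c("contig_id", "pos", "ref", "alt", "qual")
  if (!all(need %in% names(sites)))
    stop("sites needs columns: ", paste(need, collapse = ", "))
  ref_depth <- as.matrix(ref_depth); alt_depth <- as.matrix(alt_depth)
  stopifnot(nrow(ref_depth) == nrow(sites),
            identical(dim(ref_depth), dim(alt_depth)))
  if (any(ref_depth < 0) || any(alt_depth < 0)) stop("allele depths must be >= 0")
  if (any(sites$ref == sites$alt)) stop("ref and alt allele must differ")
  if (any(sites$qual < 0) || anyNA(sites$qual)) stop("site quality must be non-negative")
  structure(list(sites = sites, ref_depth = ref_depth, alt_depth = alt_depth,
                 subsample_ids = colnames(ref_depth)),
            class = "snp_table")
}

#' @method print snp_table
#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d biallelic SNPs x %d sub-samples\n",
              nrow(x$sites), length(x$subsample_ids)))
  invisible(x)
}

#' Read SNP calls from a VCF (or flat TSV dialect)
#'
#' Consumes variant calls produced upstream (e.g. samtools mpileup + bcftools
#' against binned contigs).  Only biallelic SNPs are retained: indels are
#' skipped with a warning, and multiallelic rows are split into one record per
#' alternate allele or dropped, per `multiallelic`.  Per-sample allele depths
#' are taken from AD-style FORMAT fields.
#'
#' The TSV dialect (recognised by a non-VCF extension) has columns
#' `contig_id, pos, ref, alt, qual` followed by paired columns
#' `ref:<subsample>` and `alt:<subsample>` of allele depths.
#'
#' @param path VCF (`.vcf`) or TSV file
#' @param multiallelic `"split"` (default) or `"drop"`
#' @return a [snp_table()]
#' @export
read_snp_table <- function(path, multiallelic = c("split", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(read_snp_vcf(path, multiallelic))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  rd <- as.matrix(df[, grepl("^ref:", names(df)), drop = FALSE])
  ad <- as.matrix(df[, grepl("^alt:", names(df)), drop = FALSE])
  colnames(rd) <- sub("^ref:", "", colnames(rd))
  colnames(ad) <- sub("^alt:", "", colnames(ad))
  stopifnot(identical(colnames(rd), colnames(ad)))
  keep <- nchar(df$ref) == 1 & nchar(df$alt) == 1
  if (any(!keep)) warning(sum(!keep), " non-SNP row(s) skipped")
  snp_table(df[keep, c("contig_id", "pos", "ref", "alt", "qual")],
            rd[keep, , drop = FALSE], ad[keep, , drop = FALSE])
}

read_snp_vcf <- function(path, multiallelic) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  if (anyNA(qual)) stop("missing QUAL in VCF ", path)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF has no per-sample AD field: ", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  rows <- list()
  for (i in seq_along(ref)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    depths <- strsplit(ad[i, ], ",", fixed = TRUE)
    if (nchar(ref[i]) != 1 || all(nchar(alts) != 1)) {
      warning(sprintf("skipping indel at %s:%s", fix[i, "CHROM"], fix[i, "POS"]))
      next
    }
    snp_alts <- which(nchar(alts) == 1)
    if (length(snp_alts) > 1 && multiallelic == "drop") next
    if (length(snp_alts) > 1 && multiallelic != "split") snp_alts <- snp_alts[1]
    for (j in snp_alts) {
      rd <- vapply(depths, function(d) suppressWarnings(as.integer(d[1])), 1L)
      aj <- vapply(depths, function(d) suppressWarnings(as.integer(d[j + 1])), 1L)
      rd[is.na(rd)] <- 0L; aj[is.na(aj)] <- 0L
      rows[[length(rows) + 1]] <- list(
        contig_id = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref[i], alt = alts[j], qual = qual[i], rd = rd, aj = aj)
      if (multiallelic == "drop" && length(snp_alts) > 1) break
    }
  }
  if (length(rows) == 0)
    return(snp_table(data.frame(contig_id = character(), pos = integer(),
                                ref = character(), alt = character(),
                                qual = numeric()),
                     matrix(0L, 0, ncol(ad), dimnames = list(NULL, colnames(ad))),
                     matrix(0L, 0, ncol(ad), dimnames = list(NULL, colnames(ad)))))
  sites <- data.frame(contig_id = vapply(rows, `[[`, "", "contig_id"),
                      pos = vapply(rows, `[[`, 1L, "pos"),
                      ref = vapply(rows, `[[`, "", "ref"),
                      alt = vapply(rows, `[[`, "", "alt"),
                      qual = vapply(rows, `[[`, 1, "qual"))
  rd <- do.call(rbind, lapply(rows, `[[`, "rd"))
  am <- do.call(rbind, lapply(rows, `[[`, "aj"))
  colnames(rd) <- colnames(am) <- colnames(ad)
  snp_table(sites, rd, am)
}

#' Write a SNP table in the flat TSV dialect
#'
#' @param snps a [snp_table()]
#' @param path output path
#' @export
write_snp_table <- function(snps, path) {
  stopifnot(inherits(snps, "snp_table"))
  rd <- snps$ref_depth; ad <- snps$alt_depth
  colnames(rd) <- paste0("ref:", colnames(rd))
  colnames(ad) <- paste0("alt:", colnames(ad))
  df <- cbind(snps$sites[c("contig_id", "pos", "ref", "alt", "qual")], rd, ad)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ORF table
#'
#' GFF-like TSV with columns `contig_id, start, end, strand, gene_id`;
#' coordinates 1-based inclusive, strand `+` or `-`.
#'
#' @param path TSV path
#' @return data.frame of validated ORF records
#' @export
read_orf_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  validate_orf_table(df)
}

validate_orf_table <- function(df) {
  need <- c("contig_id", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(df)))
    stop("ORF table needs columns: ", paste(need, collapse = ", "))
  if (any(df$start < 1) || any(df$end < df$start))
    stop("ORF coordinates must satisfy 1 <= start <= end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (anyDuplicated(df[c("contig_id", "gene_id")]))
    stop("gene_id must be unique within a contig")
  df[need]
}

#' Write / read a bin assignment table
#'
#' TSV with stable column order `contig_id, bin_id, contig_length`; the
#' reserved bin id `"unbinned"` marks noise contigs.
#'
#' @param bins data.frame from [cluster_embedding()] (class `bin_table`)
#' @param path output/input TSV path
#' @export
write_bins <- function(bins, path) {
  stopifnot(is.data.frame(bins),
            all(c("contig_id", "bin_id", "contig_length") %in% names(bins)))
  write.table(bins[c("contig_id", "bin_id", "contig_length")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "bin_id", "contig_length") %in% names(df)))
  class(df) <- c("bin_table", "data.frame")
  df
}

#' Write / read an occurrence matrix
#'
#' 0/1 TSV, contigs in rows and sub-samples in columns.  The binarization
#' threshold is recorded in a `# threshold=` comment line and restored on read.
#'
#' @param occurrence an `occurrence_matrix` from [binarize_coverage()]
#' @param path output/input TSV path
#' @export
write_occurrence <- function(occurrence, path) {
  stopifnot(inherits(occurrence, "occurrence_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold=%.10g", occurrence$threshold), con)
  df <- data.frame(contig_id = rownames(occurrence$presence),
                   occurrence$presence, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrence
#' @export
read_occurrence <- function(path) {
  top <- readLines(path, n = 10)
  tl <- grep("^# threshold=", top, value = TRUE)
  threshold <- if (length(tl) > 0)
    as.numeric(sub("^# threshold=", "", tl[1])) else NA_real_
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  structure(list(presence = m, threshold = threshold, log2_coverage = NULL),
            class = "occurrence_matrix")
}

#' Read KEGG-module definitions
#'
#' TSV with columns `module_id, name, kos` where `kos` is a comma-separated
#' list of KO identifiers.  Empty modules are rejected.
#'
#' @param path TSV path
#' @return named list of `module_definition` objects (`module_id`, `name`,
#'   `ko_terms`)
#' @export
read_module_definitions <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("module_id", "name", "kos") %in% names(df)))
  mods <- lapply(seq_len(nrow(df)), function(i) {
    raw <- as.character(df$kos[i])
    if (is.na(raw)) raw <- ""
    kos <- unique(trimws(strsplit(raw, ",", fixed = TRUE)[[1]]))
    kos <- kos[nzchar(kos)]
    if (length(kos) == 0)
      stop("module ", df$module_id[i], " has an empty KO set")
    list(module_id = df$module_id[i], name = df$name[i], ko_terms = kos)
  })
  setNames(mods, df$module_id)
}

#' Read per-gene KO assignments
#'
#' TSV with columns `bin_id` (or `contig_id`), `gene_id`, `ko`; returns the
#' distinct KO set per grouping id.
#'
#' @param path TSV path
#' @param by grouping column, default `"bin_id"`
#' @return named list of character KO vectors
#' @export
read_ko_assignments <- function(path, by = "bin_id") {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  stopifnot(all(c(by, "ko") %in% names(df)))
  lapply(split(df$ko, df[[by]]), unique)
}
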
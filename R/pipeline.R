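## Pipeline orchestration: validated configuration + staged execution with
## logged, reproducible outputs.  The command-line wrapper in
## inst/scripts/minimeta.R is a thin shell over run_pipeline().

#' Build and validate a pipeline configuration
#'
#' Collects every stage parameter in one validated object; unknown names are
#' rejected so typos fail before any stage runs.
#'
#' @param coverage_path coverage-table TSV (ignored by `simulate`)
#' @param lengths_path optional contig FASTA or length TSV
#' @param snp_path optional VCF/TSV of SNP calls
#' @param orf_path optional ORF TSV
#' @param ko_path,module_path optional KO-assignment and module-definition TSVs
#' @param read_counts_path optional per-sub-sample read-count sidecar
#' @param out_dir output directory (created if missing)
#' @param threshold binarization threshold (covered bp, default 2^11)
#' @param min_reads_per_subsample sub-sample read-count gate (default 800,000)
#' @param correction multiple-comparison method for the reported p-value
#'   matrix (default `"bonferroni"`)
#' @param distance which matrix feeds the embedding: `"raw"` (default) or
#'   `"corrected"`
#' @param tail `"point"` (default) or `"two-sided"` Fisher variant
#' @param embedding `"tsne"` (default; deterministic via MDS initialisation)
#'   or `"mds"`
#' @param seed integer seed (default 1)
#' @param perplexity,eps,min_points,min_bin_contigs clustering parameters
#' @param min_bin_size bin size cutoff in bp (default 500,000)
#' @param allow_singletons promote large unbinned contigs (default TRUE)
#' @param abundance_rule `"read-support"` (default) or
#'   `"occurrence-threshold"`
#' @param min_qual,min_depth SNP filter parameters (defaults 180, 5)
#' @param dnds_method `"ng86"` (default) or `"count-ratio"`
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(coverage_path = NULL, lengths_path = NULL,
                            snp_path = NULL, orf_path = NULL,
                            ko_path = NULL, module_path = NULL,
                            read_counts_path = NULL,
                            out_dir = ".",
                            threshold = 2^11,
                            min_reads_per_subsample = 8e5,
                            correction = "bonferroni",
                            distance = c("raw", "corrected"),
                            tail = c("point", "two-sided"),
                            embedding = c("tsne", "mds"),
                            seed = 1L, perplexity = 30, eps = NULL,
                            min_points = 4L, min_bin_contigs = 5L,
                            min_bin_size = 5e5, allow_singletons = TRUE,
                            abundance_rule = c("read-support",
                                               "occurrence-threshold"),
                            min_qual = 180, min_depth = 5L,
                            dnds_method = c("ng86", "count-ratio")) {
  if (threshold <= 0) stop("parameter out of range: --threshold must be > 0")
  if (!is.null(eps) && eps <= 0) stop("parameter out of range: --eps must be > 0")
  if (min_bin_size < 0) stop("parameter out of range: --min-bin-size")
  cfg <- list(coverage_path = coverage_path, lengths_path = lengths_path,
              snp_path = snp_path, orf_path = orf_path, ko_path = ko_path,
              module_path = module_path, read_counts_path = read_counts_path,
              out_dir = out_dir, threshold = threshold,
              min_reads_per_subsample = min_reads_per_subsample,
              correction = match.arg(correction,
                                     c("bonferroni", "benjamini-hochberg", "none")),
              distance = match.arg(distance), tail = match.arg(tail),
              embedding = match.arg(embedding), seed = as.integer(seed),
              perplexity = perplexity, eps = eps,
              min_points = as.integer(min_points),
              min_bin_contigs = as.integer(min_bin_contigs),
              min_bin_size = min_bin_size,
              allow_singletons = isTRUE(allow_singletons),
              abundance_rule = match.arg(abundance_rule),
              min_qual = min_qual, min_depth = as.integer(min_depth),
              dnds_method = match.arg(dnds_method))
  class(cfg) <- "pipeline_config"
  cfg
}

config_header <- function(stage, cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[!grepl("_path$|^out_dir$", names(cfg))]  # paths vary per machine
  scalars <- Filter(function(x) !is.null(x) && length(x) == 1, cfg)
  sprintf("# minimeta %s stage=%s %s",
          as.character(packageVersion("minimeta")), stage,
          paste(names(scalars), unname(vapply(scalars, as.character, "")),
                sep = "=", collapse = " "))
}

prepend_header <- function(path, header) {
  lines <- readLines(path)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Stages: `simulate` (writes a reference-scenario community to `out_dir`),
#' `binarize`, `pvals`, `bin`, `abundance`, `variation`, `modules`, and
#' `all` (binarize, pvals, bin, abundance, then variation when SNP inputs are
#' present).  Each stage reads the TSV outputs of its predecessors from
#' `config$out_dir`, so stages can be re-run individually.  Every output file
#' starts with a header comment carrying the package version and the
#' effective parameter set.
#'
#' @param stage stage name (see above)
#' @param config a [pipeline_config()]
#' @return invisibly, a named list of the paths written
#' @export
run_pipeline <- function(stage = c("simulate", "binarize", "pvals", "bin",
                                   "abundance", "variation", "modules", "all"),
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  written <- list()
  message(sprintf("[minimeta] stage %s (seed %d)", stage, config$seed))

  if (stage == "simulate") {
    community <- simulate_community(reference_scenario(seed = config$seed))
    write_coverage_table(community$coverage, out("coverage.tsv"))
    write.table(data.frame(contig_id = names(community$coverage$contig_lengths),
                           length = community$coverage$contig_lengths),
                out("contig_lengths.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(community$orfs, out("orfs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_snp_table(community$snps, out("snps.tsv"))
    writeLines(paste0(">", names(community$contig_seqs), "\n",
                      community$contig_seqs), out("contigs.fasta"))
    write.table(data.frame(contig_id = names(community$truth$contig_genome),
                           genome_id = community$truth$contig_genome),
                out("truth_contig_genome.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (f in c("coverage.tsv", "contig_lengths.tsv", "orfs.tsv", "snps.tsv",
                "truth_contig_genome.tsv"))
      prepend_header(out(f), config_header("simulate", config))
    return(invisible(lapply(c("coverage.tsv", "contig_lengths.tsv",
                              "orfs.tsv", "snps.tsv", "contigs.fasta",
                              "truth_contig_genome.tsv"), out)))
  }

  cov_path <- config$coverage_path %||% out("coverage.tsv")
  len_path <- config$lengths_path %||% out("contig_lengths.tsv")
  if (stage %in% c("binarize", "pvals", "bin", "abundance", "variation", "all")) {
    if (!file.exists(cov_path)) stop("missing input file: ", cov_path)
    lengths <- if (file.exists(len_path)) read_contig_lengths(len_path) else NULL
    coverage <- read_coverage_table(
      cov_path, config$min_reads_per_subsample,
      subsample_read_counts = config$read_counts_path,
      contig_lengths = lengths)
  }

  if (stage %in% c("binarize", "all")) {
    occurrence <- binarize_coverage(coverage, config$threshold)
    write_occurrence(occurrence, out("occurrence.tsv"))
    prepend_header(out("occurrence.tsv"), config_header("binarize", config))
    written$occurrence <- out("occurrence.tsv")
    if (stage == "binarize") return(invisible(written))
  }

  if (stage %in% c("pvals", "all")) {
    if (stage == "pvals") occurrence <- read_occurrence(out("occurrence.tsv"))
    pm <- pairwise_pvalues(occurrence, tail = config$tail)
    write_pvalues(pm, out("pvalues_raw.tsv"))
    pc <- if (config$correction == "none") pm
          else correct_pvalues(pm, method = config$correction)
    write_pvalues(pc, out("pvalues_corrected.tsv"))
    for (f in c("pvalues_raw.tsv", "pvalues_corrected.tsv"))
      prepend_header(out(f), config_header("pvals", config))
    written$pvalues <- out("pvalues_corrected.tsv")
    if (stage == "pvals") return(invisible(written))
  }

  if (stage %in% c("bin", "all")) {
    pm <- read_pvalues(out(if (config$distance == "raw") "pvalues_raw.tsv"
                           else "pvalues_corrected.tsv"))
    emb <- embed_pvalue_distances(pm, seed = config$seed,
                                  perplexity = config$perplexity,
                                  method = config$embedding)
    write.table(data.frame(contig_id = rownames(emb$coordinates),
                           emb$coordinates),
                out("embedding.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    lengths <- if (file.exists(len_path)) read_contig_lengths(len_path) else NULL
    bins <- cluster_embedding(emb, eps = config$eps,
                              min_points = config$min_points,
                              min_bin_contigs = config$min_bin_contigs,
                              contig_lengths = lengths)
    if (!is.null(lengths))
      bins <- filter_bins_by_size(bins, min_total_length = config$min_bin_size,
                                  allow_singletons = config$allow_singletons)
    write_bins(bins, out("bins.tsv"))
    for (f in c("embedding.tsv", "bins.tsv"))
      prepend_header(out(f), config_header("bin", config))
    written$bins <- out("bins.tsv")
    if (stage == "bin") return(invisible(written))
  }

  if (stage %in% c("abundance", "all")) {
    bins <- read_bins(out("bins.tsv"))
    ab <- estimate_abundances(coverage, bins, rule = config$abundance_rule)
    write.table(ab, out("abundance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    prepend_header(out("abundance.tsv"), config_header("abundance", config))
    written$abundance <- out("abundance.tsv")
    if (stage == "abundance") return(invisible(written))
  }

  if (stage %in% c("variation", "all")) {
    snp_path <- config$snp_path %||% out("snps.tsv")
    orf_path <- config$orf_path %||% out("orfs.tsv")
    fasta <- out("contigs.fasta")
    have <- file.exists(snp_path) && file.exists(orf_path) && file.exists(fasta)
    if (!have && stage == "variation")
      stop("missing input file: ", if (!file.exists(snp_path)) snp_path
           else if (!file.exists(orf_path)) orf_path else fasta)
    if (have) {
      bins <- read_bins(out("bins.tsv"))
      snps <- read_snp_table(snp_path)
      orfs <- read_orf_table(orf_path)
      ss <- Biostrings::readDNAStringSet(fasta)
      seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
      va <- summarize_variation(snps, bins, orfs, seqs,
                                quality_min = config$min_qual,
                                depth_min = config$min_depth,
                                dnds_method = config$dnds_method)
      write.table(va, out("variation.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      prepend_header(out("variation.tsv"), config_header("variation", config))
      written$variation <- out("variation.tsv")
    }
    if (stage == "variation") return(invisible(written))
  }

  if (stage == "modules") {
    if (is.null(config$ko_path) || !file.exists(config$ko_path))
      stop("missing input file: ", config$ko_path %||% "--ko-path")
    if (is.null(config$module_path) || !file.exists(config$module_path))
      stop("missing input file: ", config$module_path %||% "--module-path")
    kos <- read_ko_assignments(config$ko_path)
    mods <- read_module_definitions(config$module_path)
    ratios <- compute_module_ratios(kos, mods)
    write.table(data.frame(bin_id = rownames(ratios), ratios,
                           check.names = FALSE),
                out("module_ratios.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    prepend_header(out("module_ratios.tsv"), config_header("modules", config))
    written$module_ratios <- out("module_ratios.tsv")
  }
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
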
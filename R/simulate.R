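## Synthetic mini-metagenomic communities with full ground truth.  Cells are
## Poisson-loaded into chambers; MDA bias is modelled as independent
## per-contig Bernoulli dropout plus lognormal covered-bp given presence; SNP
## alleles are carried per simulated cell and aggregated into per-chamber
## allele depths.

#' Build and validate a community configuration
#'
#' @param genomes data.frame with columns `genome_id`, `n_contigs`, `lambda`
#'   (mean cells of that genome per chamber)
#' @param n_subsamples number of microfluidic chambers (default 96)
#' @param contig_dropout probability in `[0, 1)` that a contig of a present
#'   genome fails to reach the coverage threshold in a chamber (MDA-bias
#'   proxy; default 0.2)
#' @param contig_length_meanlog,contig_length_sdlog,contig_length_range
#'   lognormal contig-length model (bp), clamped to the range; defaults give
#'   a median ~25 kbp in `[10, 100]` kbp, mirroring a >10 kbp contig filter
#' @param coverage_meanlog,coverage_sdlog lognormal covered-bp model given
#'   presence, clamped to `[occurrence_threshold, contig length]`
#' @param occurrence_threshold covered-bp presence threshold the simulation
#'   is calibrated around (default 2^11)
#' @param noise_rate probability of spurious sub-threshold coverage on a
#'   contig whose genome is absent from the chamber (default 0.01)
#' @param partial_coverage_prob probability that a dropped-out contig still
#'   shows sub-threshold coverage (default 0.5)
#' @param lineage_assigned_prob probability a contig carries its genome's
#'   phylum label rather than "unassigned" (default 0.7)
#' @param snp_model `NULL`, or a list with `n_sites` (polymorphic sites per
#'   genome), `alt_freq` (per-cell alternate-allele probability, default
#'   0.3), `nonsyn_acceptance` (probability a proposed nonsynonymous change
#'   is accepted, 1 = neutral, 0 = all coding SNPs synonymous),
#'   `per_cell_depth` (mean reads per cell per site, default 10) and
#'   `n_artifact_sites` (low-quality decoy sites per genome, default 0)
#' @param seed integer seed; all randomness in [simulate_community()] flows
#'   from it
#' @return validated list of class `community_config`
#' @export
community_config <- function(genomes, n_subsamples = 96L,
                             contig_dropout = 0.2,
                             contig_length_meanlog = log(25000),
                             contig_length_sdlog = 0.6,
                             contig_length_range = c(10000, 100000),
                             coverage_meanlog = log(30000),
                             coverage_sdlog = 1,
                             occurrence_threshold = 2^11,
                             noise_rate = 0.01,
                             partial_coverage_prob = 0.5,
                             lineage_assigned_prob = 0.7,
                             snp_model = NULL,
                             seed = 1L) {
  genomes <- as.data.frame(genomes)
  stopifnot(all(c("genome_id", "n_contigs", "lambda") %in% names(genomes)))
  if (any(genomes$lambda <= 0)) stop("lambda must be positive for every genome")
  if (any(genomes$n_contigs < 1)) stop("n_contigs must be positive")
  if (anyDuplicated(genomes$genome_id)) stop("duplicate genome_id")
  if (contig_dropout < 0 || contig_dropout >= 1)
    stop("contig_dropout must be in [0, 1)")
  if (n_subsamples < 1) stop("n_subsamples must be positive")
  if (contig_length_range[1] <= occurrence_threshold)
    stop("minimum contig length must exceed the occurrence threshold")
  if (!is.null(snp_model)) {
    defaults <- list(alt_freq = 0.3, nonsyn_acceptance = 1,
                     per_cell_depth = 10, n_artifact_sites = 0L)
    snp_model <- modifyList(defaults, snp_model)
    if (is.null(snp_model$n_sites) || snp_model$n_sites < 1)
      stop("snp_model$n_sites must be positive")
    if (snp_model$alt_freq <= 0 || snp_model$alt_freq >= 1)
      stop("snp_model$alt_freq must be in (0, 1)")
    if (snp_model$nonsyn_acceptance < 0 || snp_model$nonsyn_acceptance > 1)
      stop("snp_model$nonsyn_acceptance must be in [0, 1]")
  }
  structure(list(genomes = genomes, n_subsamples = as.integer(n_subsamples),
                 contig_dropout = contig_dropout,
                 contig_length_meanlog = contig_length_meanlog,
                 contig_length_sdlog = contig_length_sdlog,
                 contig_length_range = contig_length_range,
                 coverage_meanlog = coverage_meanlog,
                 coverage_sdlog = coverage_sdlog,
                 occurrence_threshold = occurrence_threshold,
                 noise_rate = noise_rate,
                 partial_coverage_prob = partial_coverage_prob,
                 lineage_assigned_prob = lineage_assigned_prob,
                 snp_model = snp_model, seed = as.integer(seed)),
            class = "community_config")
}

#' Reference community scenario
#'
#' The canonical simulated fixture: 8 genomes with mean per-chamber loads
#' log-spaced from 0.05 to 1.0 cells (total ~2.8 cells/chamber, spanning a
#' near-saturating lineage down to a rare one seen in a handful of chambers),
#' 20-60 contigs per genome, 96 chambers, 20% contig dropout, and a neutral
#' SNP model with 40 polymorphic sites per genome.
#'
#' @param seed integer seed (default 101)
#' @param snp_model override for the SNP model; `NULL` disables SNP
#'   simulation (faster when only binning is exercised)
#' @return a `community_config`
#' @export
reference_scenario <- function(seed = 101L,
                               snp_model = list(n_sites = 40)) {
  genomes <- data.frame(
    genome_id = sprintf("genome_%d", 1:8),
    n_contigs = c(24L, 58L, 31L, 45L, 20L, 52L, 37L, 60L),
    lambda = exp(seq(log(0.05), log(1.0), length.out = 8)))
  community_config(genomes, n_subsamples = 96L, contig_dropout = 0.2,
                   snp_model = snp_model, seed = seed)
}

.phyla <- c("Bacteroidetes", "Chlorobi", "Deferribacteres", "Spirochaetes",
            "Thermodesulfobacteria", "Ignavibacteriae", "Euryarchaeota",
            "Bathyarchaeota", "Fervidibacteria", "Microgenomates")

#' Simulate a mini-metagenomic experiment
#'
#' For each chamber and genome, the cell count is Poisson(`lambda`); the
#' genome is present where the count is >= 1.  Each contig of a present
#' genome independently escapes dropout and receives lognormal covered bp at
#' or above the occurrence threshold; dropped or absent contigs receive
#' sub-threshold noise or zero.  When a SNP model is configured, contig
#' sequences and tiled ORFs are generated, polymorphic sites are placed with
#' per-cell alleles, and allele depths are aggregated per chamber.
#'
#' Deterministic for a fixed `config$seed`: all stages draw from one RNG
#' stream in a fixed order (lengths, cells, coverage, sequences, SNPs,
#' lineages).  The caller's RNG state is left untouched.
#'
#' @param config a [community_config()]
#' @return list of class `mm_community` with elements `coverage`
#'   ([coverage_matrix()]), `snps` ([snp_table()] or `NULL`), `orfs`
#'   (ORF data.frame or `NULL`), `contig_seqs` (named character or `NULL`),
#'   `lineages` (named character), `truth` (list: `contig_genome`, `cells`
#'   genome x chamber matrix, `lambda`, `snp_classes` data.frame), and
#'   `config`
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  G <- nrow(config$genomes)
  n <- config$n_subsamples
  sub_ids <- sprintf("s%02d", seq_len(n))
  genome_of <- rep(config$genomes$genome_id, config$genomes$n_contigs)
  contig_ids <- unlist(lapply(seq_len(G), function(g)
    sprintf("%s_c%03d", config$genomes$genome_id[g],
            seq_len(config$genomes$n_contigs[g]))))
  nC <- length(contig_ids)

  ## stage 1: contig lengths
  len <- round(rlnorm(nC, config$contig_length_meanlog,
                      config$contig_length_sdlog))
  len <- pmin(pmax(len, config$contig_length_range[1]),
              config$contig_length_range[2])
  names(len) <- contig_ids

  ## stage 2: Poisson cell loading
  cells <- matrix(rpois(G * n, config$genomes$lambda), G, n,
                  dimnames = list(config$genomes$genome_id, sub_ids))
  present <- cells >= 1

  ## stage 3: coverage with dropout and noise
  thr <- config$occurrence_threshold
  gidx <- match(genome_of, config$genomes$genome_id)
  pres_c <- present[gidx, , drop = FALSE]          # contig x chamber
  detected <- pres_c & matrix(rbinom(nC * n, 1, 1 - config$contig_dropout),
                              nC, n) == 1
  cov <- matrix(0, nC, n, dimnames = list(contig_ids, sub_ids))
  nd <- sum(detected)
  if (nd > 0) {
    draw <- round(rlnorm(nd, config$coverage_meanlog, config$coverage_sdlog))
    Lm <- matrix(len, nC, n)[detected]
    cov[detected] <- pmin(pmax(draw, thr), Lm)
  }
  dropped <- pres_c & !detected
  ndr <- sum(dropped)
  if (ndr > 0) {
    partial <- runif(ndr) < config$partial_coverage_prob
    cov[dropped] <- ifelse(partial, floor(runif(ndr, 1, thr)), 0)
  }
  spurious <- !pres_c & matrix(runif(nC * n) < config$noise_rate, nC, n)
  if (any(spurious))
    cov[spurious] <- floor(runif(sum(spurious), 1, thr))
  coverage <- coverage_matrix(cov, len)

  ## stage 4: sequences, ORFs and SNPs (only under a SNP model)
  snps <- NULL; orfs <- NULL; seqs <- NULL
  truth_snps <- NULL
  if (!is.null(config$snp_model)) {
    seqs <- vapply(len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      "")
    orfs <- tile_orfs(contig_ids, len)
    sim <- simulate_snps(config, contig_ids, genome_of, len, seqs, orfs,
                         cells, detected, sub_ids)
    snps <- sim$snps
    truth_snps <- sim$truth
  }

  ## stage 5: lineage labels
  phyla <- rep_len(.phyla, G)
  lineages <- ifelse(runif(nC) < config$lineage_assigned_prob,
                     phyla[gidx], "unassigned")
  names(lineages) <- contig_ids

  structure(list(coverage = coverage, snps = snps, orfs = orfs,
                 contig_seqs = seqs, lineages = lineages,
                 truth = list(contig_genome = setNames(genome_of, contig_ids),
                              cells = cells,
                              lambda = setNames(config$genomes$lambda,
                                                config$genomes$genome_id),
                              snp_classes = truth_snps),
                 config = config),
            class = "mm_community")
}

#' @method print mm_community
#' @export
print.mm_community <- function(x, ...) {
  cat(sprintf("mm_community: %d genomes, %d contigs, %d sub-samples (seed %d)\n",
              nrow(x$config$genomes), nrow(x$coverage$values),
              x$config$n_subsamples, x$config$seed))
  if (!is.null(x$snps))
    cat(sprintf("  %d simulated SNP sites\n", nrow(x$snps$sites)))
  invisible(x)
}

## tile each contig with non-overlapping ORFs (300-1500 bp multiples of 3,
## random strand, short intergenic gaps) covering most of its length
tile_orfs <- function(contig_ids, len) {
  rows <- vector("list", length(contig_ids))
  for (i in seq_along(contig_ids)) {
    L <- len[i]
    pos <- sample(20:120, 1)
    starts <- integer(0); ends <- integer(0); strands <- character(0)
    while (pos + 299 <= L) {
      glen <- 3 * sample(100:500, 1)
      if (pos + glen - 1 > L) glen <- 3 * ((L - pos + 1) %/% 3)
      if (glen < 300) break
      starts <- c(starts, pos); ends <- c(ends, pos + glen - 1)
      strands <- c(strands, sample(c("+", "-"), 1))
      pos <- pos + glen + sample(20:200, 1)
    }
    if (length(starts) > 0)
      rows[[i]] <- data.frame(contig_id = contig_ids[i], start = starts,
                              end = ends, strand = strands,
                              gene_id = sprintf("%s_g%02d", contig_ids[i],
                                                seq_along(starts)))
  }
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

## place polymorphic sites, assign per-cell alleles, aggregate chamber depths
simulate_snps <- function(config, contig_ids, genome_of, len, seqs, orfs,
                          cells, detected, sub_ids) {
  sm <- config$snp_model
  code <- Biostrings::getGeneticCode("11")
  G <- nrow(config$genomes)
  site_rows <- list()
  for (g in seq_len(G)) {
    gid <- config$genomes$genome_id[g]
    ctgs <- contig_ids[genome_of == gid]
    w <- len[ctgs] / sum(len[ctgs])
    placed <- 0
    guard <- 0
    while (placed < sm$n_sites && guard < sm$n_sites * 200) {
      guard <- guard + 1
      ctg <- sample(ctgs, 1, prob = w)
      pos <- sample.int(len[ctg], 1)
      ref <- substr(seqs[[ctg]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      cls <- classify_in_orf_any(ctg, pos, ref, alt, orfs, seqs, code)
      if (cls == "nonsynonymous" && runif(1) > sm$nonsyn_acceptance) next
      placed <- placed + 1
      site_rows[[length(site_rows) + 1]] <-
        data.frame(contig_id = ctg, pos = pos, ref = ref, alt = alt,
                   genome_id = gid, class = cls, artifact = FALSE)
    }
    na <- sm$n_artifact_sites
    if (na > 0) {
      for (j in seq_len(na)) {
        ctg <- sample(ctgs, 1, prob = w)
        pos <- sample.int(len[ctg], 1)
        ref <- substr(seqs[[ctg]], pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        site_rows[[length(site_rows) + 1]] <-
          data.frame(contig_id = ctg, pos = pos, ref = ref, alt = alt,
                     genome_id = gid,
                     class = classify_in_orf_any(ctg, pos, ref, alt, orfs,
                                                 seqs, code),
                     artifact = TRUE)
      }
    }
  }
  sites <- do.call(rbind, site_rows)
  n <- length(sub_ids)
  S <- nrow(sites)
  rd <- matrix(0L, S, n, dimnames = list(NULL, sub_ids))
  ad <- matrix(0L, S, n, dimnames = list(NULL, sub_ids))
  for (s in seq_len(S)) {
    g <- sites$genome_id[s]
    ci <- match(sites$contig_id[s], contig_ids)
    for (j in seq_len(n)) {
      m <- cells[g, j]
      if (m == 0 || !detected[ci, j]) next
      n_alt_cells <- rbinom(1, m, sm$alt_freq)
      rd[s, j] <- sum(rpois(m - n_alt_cells, sm$per_cell_depth))
      ad[s, j] <- sum(rpois(n_alt_cells, sm$per_cell_depth))
    }
  }
  qual <- ifelse(sites$artifact, runif(S, 0, 180), runif(S, 200, 999))
  snps <- snp_table(data.frame(contig_id = sites$contig_id, pos = sites$pos,
                               ref = sites$ref, alt = sites$alt, qual = qual),
                    rd, ad)
  list(snps = snps, truth = sites)
}

classify_in_orf_any <- function(ctg, pos, ref, alt, orfs, seqs, code) {
  hits <- which(orfs$contig_id == ctg & orfs$start <= pos & orfs$end >= pos)
  if (length(hits) == 0) return("noncoding")
  verdicts <- vapply(hits, function(h)
    classify_in_orf(pos, ref, alt, orfs$start[h], orfs$end[h],
                    orfs$strand[h], seqs[[ctg]], code), "")
  if (any(verdicts == "nonsynonymous")) "nonsynonymous"
  else if (any(verdicts == "synonymous")) "synonymous"
  else "noncoding"
}
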
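## Genome abundance by Poisson occupancy inversion: cells are loaded into
## chambers independently at random, so the count of chambers *empty* of a
## genome determines the most probable total number of its cells.

#' Presence profile of a genome bin across sub-samples
#'
#' A genome counts as present (>= 1 cell) in a sub-sample when strictly more
#' than 50% of its member contigs are supported there.  Two support rules are
#' offered: `"read-support"` (default; a contig is supported when covered by
#' at least one read, i.e. covered bp > 0 — sensitive, appropriate for
#' detecting single cells) and `"occurrence-threshold"` (a contig is supported
#' when it passes the binarization threshold — the stricter rule used for
#' binning).
#'
#' @param x a [coverage_matrix()] (for `"read-support"`) or an
#'   `occurrence_matrix` (for `"occurrence-threshold"`; a coverage matrix is
#'   also accepted and thresholded at 2^11)
#' @param contig_ids the bin's member contigs
#' @param rule `"read-support"` (default) or `"occurrence-threshold"`
#' @return named binary vector over sub-samples (1 = at least one cell)
#' @export
genome_presence_profile <- function(x, contig_ids,
                                    rule = c("read-support",
                                             "occurrence-threshold")) {
  rule <- match.arg(rule)
  if (length(contig_ids) == 0) stop("empty bin")
  support <- if (rule == "read-support") {
    stopifnot(inherits(x, "coverage_matrix"))
    x$values[contig_ids, , drop = FALSE] > 0
  } else if (inherits(x, "occurrence_matrix")) {
    x$presence[contig_ids, , drop = FALSE] > 0
  } else {
    stopifnot(inherits(x, "coverage_matrix"))
    x$values[contig_ids, , drop = FALSE] >= 2^11
  }
  frac <- colMeans(support)
  as.integer(frac > 0.5)
}

#' Estimate total cell count from empty-chamber occupancy
#'
#' Cells of a genome are scattered independently and uniformly over `n`
#' chambers.  If `X` cells were loaded in total, the expected fraction of
#' chambers containing none is `k/n = exp(-X/n)`; inverting gives the maximum
#' likelihood estimate
#' \deqn{X = -n \ln(k/n)}
#' where `k` is the observed number of empty chambers.  `k = n` (genome never
#' seen) gives `X = 0`.  `k = 0` (genome in every chamber) saturates the
#' estimator: the count is reported as the `k = 1` lower bound with
#' `saturated = TRUE`.
#'
#' @param k integer, number of sub-samples with zero cells of this genome
#' @param n integer, total number of sub-samples
#' @return list with `n`, `k`, `X` (estimated total cells), `saturated`
#' @examples
#' estimate_cell_count(k = 48, n = 96)  # 96 * log(2) ~ 66.5 cells
#' @export
estimate_cell_count <- function(k, n) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n))
    stop("k and n must be single integers")
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  saturated <- k == 0
  X <- if (saturated) -n * log(1 / n) else -n * log(k / n)
  list(n = as.integer(n), k = as.integer(k), X = X, saturated = saturated)
}

#' Abundance estimates for a set of genome bins
#'
#' Applies [genome_presence_profile()] and [estimate_cell_count()] to every
#' bin and attaches relative abundances.
#'
#' @param coverage a [coverage_matrix()]
#' @param bins a `bin_table`; the reserved `"unbinned"` id is ignored
#' @param rule passed to [genome_presence_profile()]
#' @return data.frame per bin: `bin_id, n, k, X, relative_abundance,
#'   saturated`
#' @export
estimate_abundances <- function(coverage, bins,
                                rule = c("read-support",
                                         "occurrence-threshold")) {
  rule <- match.arg(rule)
  ids <- setdiff(unique(bins$bin_id), "unbinned")
  rows <- lapply(ids, function(b) {
    members <- bins$contig_id[bins$bin_id == b]
    prof <- genome_presence_profile(coverage, members, rule = rule)
    est <- estimate_cell_count(k = sum(prof == 0), n = length(prof))
    data.frame(bin_id = b, n = est$n, k = est$k, X = est$X,
               saturated = est$saturated)
  })
  out <- do.call(rbind, rows)
  relative_abundance(out)
}

#' Normalize cell counts to relative abundances
#'
#' Each bin's estimated cell count divided by the total over reported bins;
#' the fractions sum to 1.
#'
#' @param estimates data.frame with columns `bin_id`, `X`, `saturated` (or a
#'   bare numeric vector of cell counts)
#' @return the input with a `relative_abundance` column added (or, for a bare
#'   vector, the normalized vector)
#' @export
relative_abundance <- function(estimates) {
  if (is.numeric(estimates)) {
    if (sum(estimates) <= 0) stop("total cell count must be positive")
    return(estimates / sum(estimates))
  }
  if (all(estimates$saturated)) stop("all estimates are saturated")
  total <- sum(estimates$X)
  if (total <= 0) stop("total cell count must be positive")
  estimates$relative_abundance <- estimates$X / total
  estimates[c("bin_id", "n", "k", "X", "relative_abundance", "saturated")]
}
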
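## Co-occurrence statistics: binarization of coverage and the pairwise
## hypergeometric point-probability matrix used as a contig-contig distance.

#' Binarize coverage into an occurrence map
#'
#' MDA amplification makes coverage depth an unreliable abundance signal, but
#' whether a contig was covered *at all* in a sub-sample is informative.
#' Thresholding covered base pairs digitizes the noisy analog coverage into a
#' binary presence pattern.  The default threshold of 2^11 = 2048 covered bp
#' sits in the middle of a robustness band (2^9-2^13) over which binning
#' results are stable.
#'
#' @param coverage a [coverage_matrix()]
#' @param threshold positive number of covered bp at or above which a contig
#'   counts as present (default `2^11`); boundary values count as present.
#' @return object of class `occurrence_matrix`: list with `presence`
#'   (0/1 integer matrix), `threshold`, and `log2_coverage` (log2 of covered
#'   bp with zeros kept at 0, retained for heat-map display only).
#' @export
binarize_coverage <- function(coverage, threshold = 2^11) {
  stopifnot(inherits(coverage, "coverage_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number")
  v <- coverage$values
  presence <- matrix(as.integer(v >= threshold), nrow(v), ncol(v),
                     dimnames = dimnames(v))
  log2cov <- ifelse(v > 0, log2(v), 0)
  structure(list(presence = presence, threshold = threshold,
                 log2_coverage = log2cov),
            class = "occurrence_matrix")
}

#' @method print occurrence_matrix
#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence_matrix: %d contigs x %d sub-samples (threshold %g bp)\n",
              nrow(x$presence), ncol(x$presence), x$threshold))
  cat(sprintf("  %.1f%% of entries present\n", 100 * mean(x$presence)))
  invisible(x)
}

#' Tabulate the 2x2 contingency counts of two presence patterns
#'
#' For contigs X and Y over the same sub-samples:
#' a = both present, b = X absent and Y present, c = X present and Y absent,
#' d = both absent; a + b + c + d equals the number of sub-samples.
#'
#' @param x,y equal-length binary (0/1) vectors
#' @return named integer vector `c(a, b, c, d)`
#' @export
tabulate_contingency <- function(x, y) {
  if (length(x) != length(y)) stop("presence vectors differ in length")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("presence vectors must be binary")
  c(a = sum(x == 1 & y == 1), b = sum(x == 0 & y == 1),
    c = sum(x == 1 & y == 0), d = sum(x == 0 & y == 0))
}

#' Hypergeometric point probability of a co-occurrence table
#'
#' The probability of observing *exactly* the contingency table
#' `(a, b, c, d)` when the two margins are fixed and presence is assigned at
#' random:
#' \deqn{p = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{a!\,b!\,c!\,d!\,(a+b+c+d)!}}
#' This is the single term of Fisher's exact test at the observed table, not a
#' tail sum; a two-sided tail (the sum of all tables at least as extreme, the
#' conventional Fisher p-value) is available with `tail = "two-sided"`.  Small
#' values mean the overlap pattern is unlikely under independent placement,
#' i.e. the two contigs plausibly ride in the same cells.
#'
#' Computed in log-factorial space (`lchoose`), exact to machine precision and
#' overflow-free for n up to at least 1e4.
#'
#' @param a,b,c,d non-negative integer contingency counts; `a` may also be a
#'   length-4 vector as returned by [tabulate_contingency()].
#' @param tail `"point"` (default) or `"two-sided"`
#' @return probability in (0, 1]
#' @examples
#' fisher_point_probability(8, 1, 2, 6)   # ~0.013
#' @export
fisher_point_probability <- function(a, b = NULL, c = NULL, d = NULL,
                                     tail = c("point", "two-sided")) {
  tail <- match.arg(tail)
  if (length(a) == 4 && is.null(b)) { b <- a[[2]]; c <- a[[3]]; d <- a[[4]]; a <- a[[1]] }
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  if (tail == "two-sided") {
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2, 2))$p.value
    return(min(p, 1))
  }
  n <- a + b + c + d
  if (n == 0) return(1)
  ## P(A = a | margins) = C(a+b, a) C(c+d, c) / C(n, a+c)
  exp(lchoose(a + b, a) + lchoose(c + d, c) - lchoose(n, a + c))
}

#' Pairwise co-occurrence p-value matrix
#'
#' For every unordered pair of contigs, the hypergeometric point probability of
#' their observed presence overlap.  Each entry is the probability of
#' incorrectly rejecting the null hypothesis that the presence patterns of the
#' two contigs occur randomly; the matrix doubles as a pairwise distance
#' metric for embedding and clustering.  Self-pairs carry the smallest
#' off-diagonal value of the matrix so that self-distance is minimal.
#'
#' @param occurrence an `occurrence_matrix` from [binarize_coverage()]
#' @param tail passed to [fisher_point_probability()]
#' @return object of class `pvalue_matrix`: list with `p` (symmetric matrix),
#'   `corrected` (FALSE), `correction_method` ("none"), `m` (NULL)
#' @export
pairwise_pvalues <- function(occurrence, tail = c("point", "two-sided")) {
  tail <- match.arg(tail)
  stopifnot(inherits(occurrence, "occurrence_matrix"))
  P <- occurrence$presence
  if (nrow(P) < 2) stop("need at least 2 contigs")
  if (ncol(P) < 1) stop("need at least 1 sub-sample")
  n <- ncol(P)
  if (tail == "point") {
    ## vectorized: a_ij = overlap; margins from row sums
    s <- rowSums(P)
    A <- P %*% t(P)
    Si <- matrix(s, nrow(P), nrow(P))            # X margin (rows)
    Sj <- t(Si)                                  # Y margin (cols)
    lp <- lchoose(Sj, A) + lchoose(n - Sj, Si - A) - lchoose(n, Si)
    pm <- exp(lp)
  } else {
    nc <- nrow(P)
    pm <- matrix(1, nc, nc)
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
      ct <- tabulate_contingency(P[i, ], P[j, ])
      pm[i, j] <- pm[j, i] <- fisher_point_probability(ct, tail = "two-sided")
    }
  }
  dimnames(pm) <- list(rownames(P), rownames(P))
  off <- pm[upper.tri(pm)]
  diag(pm) <- min(off)
  pm <- (pm + t(pm)) / 2   # exact symmetry against fp rounding
  structure(list(p = pm, corrected = FALSE, correction_method = "none",
                 m = NULL),
            class = "pvalue_matrix")
}

#' @method print pvalue_matrix
#' @export
print.pvalue_matrix <- function(x, ...) {
  cat(sprintf("pvalue_matrix: %d contigs; correction: %s\n",
              nrow(x$p), x$correction_method))
  invisible(x)
}

#' Multiple-comparison correction of a p-value matrix
#'
#' With C contigs there are choose(C, 2) pairwise tests; correction guards the
#' reported matrix against that multiplicity.  Bonferroni (default) multiplies
#' by the number of distinct pairs and caps at 1; Benjamini-Hochberg applies
#' the step-up FDR procedure over the distinct pairs.
#'
#' @param pmatrix an uncorrected `pvalue_matrix`
#' @param method `"bonferroni"` (default), `"benjamini-hochberg"`, or `"none"`
#' @param m number of tests; defaults to the number of distinct contig pairs
#' @return corrected `pvalue_matrix` (values capped at 1, flag set)
#' @export
correct_pvalues <- function(pmatrix,
                            method = c("bonferroni", "benjamini-hochberg", "none"),
                            m = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(pmatrix, "pvalue_matrix"))
  if (isTRUE(pmatrix$corrected)) stop("p-value matrix is already corrected")
  pm <- pmatrix$p
  ut <- upper.tri(pm)
  if (is.null(m)) m <- sum(ut)
  p <- pm[ut]
  q <- switch(method,
    "bonferroni" = pmin(1, p * m),
    "benjamini-hochberg" = p.adjust(p, method = "BH", n = m),
    "none" = p)
  out <- pm
  out[ut] <- q
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- min(q)
  structure(list(p = out, corrected = method != "none",
                 correction_method = method, m = m),
            class = "pvalue_matrix")
}

#' Write / read a p-value matrix
#'
#' Square TSV with contig ids on both axes; correction metadata is stored in
#' comment lines.
#'
#' @param pmatrix a `pvalue_matrix`
#' @param path output/input TSV path
#' @export
write_pvalues <- function(pmatrix, path) {
  stopifnot(inherits(pmatrix, "pvalue_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# correction=%s corrected=%s",
                     pmatrix$correction_method, pmatrix$corrected), con)
  df <- data.frame(contig_id = rownames(pmatrix$p), pmatrix$p,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pvalues
#' @export
read_pvalues <- function(path) {
  top <- readLines(path, n = 10)
  ml <- grep("^# correction=", top, value = TRUE)
  meta <- if (length(ml) > 0)
    strsplit(sub("^# correction=", "", ml[1]), " corrected=")[[1]]
  else c("none", "FALSE")
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  structure(list(p = m, corrected = as.logical(meta[2]),
                 correction_method = meta[1], m = NULL),
            class = "pvalue_matrix")
}
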
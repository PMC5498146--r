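## Genome binning: embed the p-value distance matrix in 2-D, then density
## cluster.  Exact t-SNE (implemented here, O(n^2) gradient) initialised from
## the classical MDS solution is the default: deterministic, and unlike plain
## 2-D MDS it keeps many near-equidistant genome clusters apart.

#' Embed the pairwise p-value matrix in two dimensions
#'
#' The co-occurrence p-value matrix acts directly as a pairwise distance
#' metric between contigs: contigs from the same genome have near-zero mutual
#' p-values and sit close together.  The default embedding is exact t-SNE on
#' the precomputed distances, initialised from the classical MDS solution —
#' with a deterministic initialisation the whole embedding is deterministic,
#' so identical runs give identical coordinates regardless of seed.  A
#' randomly initialised t-SNE (reproducible for a fixed seed) and plain 2-D
#' classical MDS are available as alternatives; note that with many genomes
#' at roughly equal mutual distances a 2-D classical MDS cannot keep the
#' clusters apart, which is why t-SNE is the default.
#'
#' @param pmatrix a `pvalue_matrix` (raw or corrected)
#' @param seed integer seed; used only by `init = "random"`, but always
#'   recorded in the result
#' @param perplexity t-SNE perplexity (default 30; reduced automatically when
#'   there are too few contigs)
#' @param method `"tsne"` (default) or `"mds"`
#' @param init t-SNE initialisation: `"mds"` (default, deterministic) or
#'   `"random"`
#' @param max_iter t-SNE gradient-descent iterations (default 1000)
#' @return object of class `embedding`: list with `coordinates` (n x 2 matrix,
#'   contig ids as row names), `seed`, `method`, `parameters`
#' @export
embed_pvalue_distances <- function(pmatrix, seed = 1L, perplexity = 30,
                                   method = c("tsne", "mds"),
                                   init = c("mds", "random"),
                                   max_iter = 1000L) {
  method <- match.arg(method)
  init <- match.arg(init)
  stopifnot(inherits(pmatrix, "pvalue_matrix"))
  D <- pmatrix$p
  if (nrow(D) < 3)
    stop("fewer than 3 contigs; cluster the distance matrix directly instead")
  ## canonical internal ordering: results do not depend on contig input order
  ord <- order(rownames(D))
  D <- D[ord, ord]
  diag(D) <- 0
  if (method == "mds") {
    Y <- cmdscale(as.dist(D), k = 2)
    if (ncol(Y) < 2) Y <- cbind(Y, 0)  # degenerate geometry collapses an axis
  } else {
    Y <- tsne_exact(D, perplexity = perplexity, seed = seed,
                    max_iter = max_iter, init = init)
  }
  rownames(Y) <- rownames(pmatrix$p)[ord]
  Y <- Y[match(rownames(pmatrix$p), rownames(Y)), , drop = FALSE]
  colnames(Y) <- c("dim1", "dim2")
  structure(list(coordinates = Y, seed = as.integer(seed), method = method,
                 parameters = list(perplexity = perplexity, init = init,
                                   max_iter = max_iter)),
            class = "embedding")
}

## Exact t-SNE on a precomputed distance matrix (Student-t kernel, perplexity
## calibration by bisection, momentum + early exaggeration).  O(n^2) per
## iteration; intended for the few hundred to few thousand contigs typical of
## a mini-metagenomic assembly.
tsne_exact <- function(D, perplexity = 30, seed = 1L, max_iter = 1000L,
                       eta = 100, init = "mds") {
  n <- nrow(D)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 2) perplexity <- 2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  D2 <- D^2
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else          { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.xmin)
  if (identical(init, "mds")) {
    Y <- cmdscale(as.dist(D), k = 2)
    if (ncol(Y) < 2) Y <- cbind(Y, 0)
    s <- sd(Y[, 1])
    Y <- if (s > 0) Y / s * 1e-4 else Y  # small init, standard t-SNE practice
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  }
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exag <- 12
  for (it in seq_len(max_iter)) {
    Pi <- if (it <= 100) P * exag else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (Pi - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    mom <- if (it <= 250) 0.5 else 0.8
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @method print embedding
#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d contigs, method %s (seed %d)\n",
              nrow(x$coordinates), x$method, x$seed))
  invisible(x)
}

## Plain DBSCAN on 2-D points; 0 = noise.  O(n^2), adequate for contig counts.
dbscan_points <- function(Y, eps, min_points) {
  n <- nrow(Y)
  D <- as.matrix(dist(Y))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_points
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

## Knee of the sorted k-NN distance curve, located as the largest jump in its
## upper half: points above the jump sit at a different (noise) scale from the
## cluster fringe below it.  Robust both with and without genuine noise
## points, where chord-based kneedle variants under-shoot on curves whose
## lower half is a long near-zero plateau (typical of t-SNE output).
knn_knee_eps <- function(Y, k = 4) {
  D <- as.matrix(dist(Y))
  diag(D) <- Inf
  kd <- sort(apply(D, 1, function(r) sort(r)[k]))
  n <- length(kd)
  if (n < 4 || kd[n] == kd[1]) return(max(kd[n], .Machine$double.eps))
  hi <- seq(floor(n / 2), n - 1)
  eps <- kd[hi[which.max(kd[hi + 1] - kd[hi])]]
  max(eps, .Machine$double.eps)
}

#' Cluster an embedding into genome bins
#'
#' DBSCAN over the 2-D embedding: dense groups of contigs become genome bins;
#' points in no cluster, or in clusters with fewer than `min_bin_contigs`
#' members, are labelled `"unbinned"`.  When `eps` is `NULL` it is chosen as
#' the knee of the sorted 4-nearest-neighbour distance curve.
#'
#' @param embedding an `embedding` from [embed_pvalue_distances()]
#' @param eps DBSCAN neighbourhood radius; `NULL` (default) for the knee
#'   heuristic
#' @param min_points DBSCAN core-point minimum (default 4)
#' @param min_bin_contigs smallest cluster reported as a bin (default 5)
#' @param contig_lengths optional named lengths attached to the bin table
#' @return a `bin_table` data.frame with columns `contig_id`, `bin_id`
#'   (`"bin_01"`, ... or `"unbinned"`), `contig_length` (NA when lengths are
#'   not supplied)
#' @export
cluster_embedding <- function(embedding, eps = NULL, min_points = 4L,
                              min_bin_contigs = 5L, contig_lengths = NULL) {
  stopifnot(inherits(embedding, "embedding"))
  Y <- embedding$coordinates
  input_order <- rownames(Y)
  Y <- Y[order(rownames(Y)), , drop = FALSE]  # order-invariant border handling
  if (!is.null(eps) && eps <= 0) stop("eps must be positive")
  if (is.null(eps)) eps <- knn_knee_eps(Y, k = min_points)
  labels <- dbscan_points(Y, eps = eps, min_points = min_points)
  tab <- table(labels[labels > 0])
  small <- as.integer(names(tab)[tab < min_bin_contigs])
  labels[labels %in% small] <- 0L
  kept <- sort(unique(labels[labels > 0]))
  bin_id <- rep("unbinned", nrow(Y))
  for (i in seq_along(kept))
    bin_id[labels == kept[i]] <- sprintf("bin_%02d", i)
  ids <- rownames(Y)
  len <- if (is.null(contig_lengths)) NA_real_ else unname(contig_lengths[ids])
  out <- data.frame(contig_id = ids, bin_id = bin_id, contig_length = len,
                    stringsAsFactors = FALSE)
  out <- out[match(input_order, out$contig_id), ]
  rownames(out) <- NULL
  attr(out, "eps") <- eps
  attr(out, "min_points") <- min_points
  class(out) <- c("bin_table", "data.frame")
  out
}

#' Filter genome bins by total assembled size
#'
#' Keeps bins whose member contig lengths sum to more than `min_total_length`
#' (default 0.5 Mbp).  With `allow_singletons = TRUE`, an unbinned contig that
#' alone exceeds the cutoff — e.g. a complete, closed genome assembled as a
#' single multi-Mbp contig — is promoted to its own bin.
#'
#' @param bins a `bin_table`
#' @param contig_lengths named vector of contig lengths; may be omitted when
#'   the bin table already carries lengths
#' @param min_total_length bp cutoff (default 500,000)
#' @param allow_singletons promote large unbinned contigs (default FALSE)
#' @return filtered `bin_table`; members of dropped bins become `"unbinned"`
#' @export
filter_bins_by_size <- function(bins, contig_lengths = NULL,
                                min_total_length = 5e5,
                                allow_singletons = FALSE) {
  stopifnot(inherits(bins, "bin_table") || is.data.frame(bins))
  if (!is.null(contig_lengths))
    bins$contig_length <- unname(contig_lengths[bins$contig_id])
  if (anyNA(bins$contig_length))
    stop("missing contig length for: ",
         paste(head(bins$contig_id[is.na(bins$contig_length)], 3), collapse = ", "))
  sizes <- tapply(bins$contig_length, bins$bin_id, sum)
  drop <- names(sizes)[sizes <= min_total_length & names(sizes) != "unbinned"]
  bins$bin_id[bins$bin_id %in% drop] <- "unbinned"
  if (allow_singletons) {
    big <- bins$bin_id == "unbinned" & bins$contig_length > min_total_length
    if (any(big)) {
      existing <- sum(grepl("^bin_", unique(bins$bin_id)))
      idx <- which(big)
      bins$bin_id[idx] <- sprintf("bin_%02d", existing + seq_along(idx))
    }
  }
  class(bins) <- c("bin_table", "data.frame")
  bins
}

#' Summarize bins
#'
#' @param bins a `bin_table`
#' @return data.frame with one row per bin: `bin_id`, `n_contigs`,
#'   `total_length`
#' @export
bin_summary <- function(bins) {
  agg <- aggregate(contig_length ~ bin_id, data = bins, FUN = sum)
  cnt <- aggregate(contig_id ~ bin_id, data = bins, FUN = length)
  out <- merge(cnt, agg, by = "bin_id")
  names(out) <- c("bin_id", "n_contigs", "total_length")
  out[order(out$bin_id), ]
}

#' Consensus lineage of a genome bin
#'
#' Majority phylum-level (or any rank) label among the bin's *assigned*
#' contigs, with the fraction of assigned contigs supporting it.  Bins in
#' which fewer than half the contigs carry any assignment are flagged
#' `predominantly_unassigned` — their lineage is suggestive at best.
#'
#' @param bins a `bin_table`
#' @param contig_lineages named character vector contig_id -> label; missing
#'   or `"unassigned"` entries count as unassigned
#' @return data.frame per bin: `bin_id`, `lineage`, `support` (fraction of
#'   assigned contigs voting for the majority label), `assigned_fraction`,
#'   `predominantly_unassigned`
#' @export
consensus_lineage <- function(bins, contig_lineages) {
  ids <- unique(bins$bin_id)
  rows <- lapply(ids, function(b) {
    members <- bins$contig_id[bins$bin_id == b]
    lab <- contig_lineages[members]
    lab[is.na(lab)] <- "unassigned"
    assigned <- lab[lab != "unassigned"]
    if (length(assigned) == 0) {
      return(data.frame(bin_id = b, lineage = "unassigned", support = 0,
                        assigned_fraction = 0,
                        predominantly_unassigned = TRUE))
    }
    tab <- sort(table(assigned), decreasing = TRUE)
    data.frame(bin_id = b, lineage = names(tab)[1],
               support = unname(tab[1]) / length(assigned),
               assigned_fraction = length(assigned) / length(members),
               predominantly_unassigned = length(assigned) < length(members) / 2)
  })
  do.call(rbind, rows)
}

#' Score a binning against ground truth
#'
#' Validation harness for simulated communities: compares inferred bins with
#' the true contig -> genome map.
#'
#' @param bins a `bin_table`; unbinned contigs are kept as their own label so
#'   that failing to bin is penalised
#' @param truth named character vector contig_id -> genome_id covering every
#'   binned contig
#' @param contig_lengths optional named lengths for length-weighted
#'   completeness; defaults to the bin table's lengths
#' @return list with `ari` (adjusted Rand index over all contigs),
#'   `purity` (per-bin fraction of contigs from the bin's majority genome),
#'   `completeness` (per-genome fraction of the genome's total contig length
#'   captured by its best-matching bin)
#' @export
evaluate_binning <- function(bins, truth, contig_lengths = NULL) {
  miss <- setdiff(bins$contig_id[bins$bin_id != "unbinned"], names(truth))
  if (length(miss) > 0)
    stop("truth missing binned contig(s): ", paste(head(miss, 3), collapse = ", "))
  ids <- bins$contig_id[bins$contig_id %in% names(truth)]
  pred <- bins$bin_id[match(ids, bins$contig_id)]
  ## each unbinned contig is its own singleton cluster
  un <- pred == "unbinned"
  pred[un] <- paste0("unbinned_", seq_len(sum(un)))
  tru <- truth[ids]
  ari <- mclust::adjustedRandIndex(pred, tru)
  real_bins <- unique(bins$bin_id[bins$bin_id != "unbinned"])
  purity <- vapply(real_bins, function(b) {
    g <- truth[bins$contig_id[bins$bin_id == b]]
    max(table(g)) / length(g)
  }, 1)
  if (is.null(contig_lengths))
    contig_lengths <- setNames(bins$contig_length, bins$contig_id)
  genomes <- unique(tru)
  completeness <- vapply(genomes, function(g) {
    members <- names(truth)[truth == g]
    members <- members[members %in% bins$contig_id]
    lens <- contig_lengths[members]
    bl <- bins$bin_id[match(members, bins$contig_id)]
    inbin <- split(lens, bl)
    inbin <- inbin[names(inbin) != "unbinned"]
    if (length(inbin) == 0) return(0)
    max(vapply(inbin, sum, 1)) / sum(lens)
  }, 1)
  list(ari = ari, purity = purity, completeness = completeness)
}
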
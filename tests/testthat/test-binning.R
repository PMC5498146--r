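test_that("embedding has one 2-D point per contig and is run-to-run stable", {
  occ <- three_genome_occurrence()
  pm <- pairwise_pvalues(occ)
  emb <- embed_pvalue_distances(pm)
  expect_equal(dim(emb$coordinates), c(nrow(pm$p), 2))
  expect_identical(rownames(emb$coordinates), rownames(pm$p))
  emb2 <- embed_pvalue_distances(pm)
  expect_identical(emb$coordinates, emb2$coordinates)
  ## random-init variant is reproducible for a fixed seed
  r1 <- embed_pvalue_distances(pm, seed = 7, init = "random")
  r2 <- embed_pvalue_distances(pm, seed = 7, init = "random")
  expect_identical(r1$coordinates, r2$coordinates)
  expect_error(embed_pvalue_distances(
    structure(list(p = matrix(0.5, 2, 2)), class = "pvalue_matrix")),
    "fewer than 3")
})

test_that("same-genome contigs sit closer in the embedding than cross-genome", {
  occ <- three_genome_occurrence()
  pm <- pairwise_pvalues(occ)
  for (method in c("tsne", "mds")) {
    emb <- embed_pvalue_distances(pm, method = method)
    D <- as.matrix(dist(emb$coordinates))
    genome <- sub("_c.*", "", rownames(D))
    same <- outer(genome, genome, "==") & upper.tri(D)
    diff <- outer(genome, genome, "!=") & upper.tri(D)
    expect_lt(mean(D[same]), mean(D[diff]))
  }
})

test_that("DBSCAN clustering matches the expected geometry", {
  set.seed(1)
  blob <- function(cx, cy, n = 50, r = 0.1)
    cbind(rnorm(n, cx, r), rnorm(n, cy, r))
  Y <- rbind(blob(0, 0), blob(20, 20))
  rownames(Y) <- sprintf("c%03d", seq_len(nrow(Y)))
  bins <- cluster_embedding(fake_embedding(Y))
  expect_equal(length(setdiff(unique(bins$bin_id), "unbinned")), 2)

  ## all points identical: a single bin holding everything
  Y2 <- matrix(3, 30, 2, dimnames = list(sprintf("c%02d", 1:30), NULL))
  bins2 <- cluster_embedding(fake_embedding(Y2))
  expect_equal(unique(bins2$bin_id), "bin_01")

  ## an isolated point far from a blob is noise
  Y3 <- rbind(blob(0, 0), lonely = c(1e4, 1e4))
  rownames(Y3) <- c(sprintf("c%03d", 1:50), "lonely")
  bins3 <- cluster_embedding(fake_embedding(Y3))
  expect_equal(bins3$bin_id[bins3$contig_id == "lonely"], "unbinned")
  expect_error(cluster_embedding(fake_embedding(Y3), eps = -1), "eps")
})

test_that("clusters below the member floor are relabelled unbinned", {
  set.seed(2)
  Y <- rbind(cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1)),
             cbind(rnorm(4, 50, 0.01), rnorm(4, 50, 0.01)))
  rownames(Y) <- sprintf("c%02d", 1:24)
  bins <- cluster_embedding(fake_embedding(Y), eps = 1, min_points = 3,
                            min_bin_contigs = 5)
  small <- bins$bin_id[25 - 4:1]
  expect_true(all(bins$bin_id[21:24] == "unbinned"))
  expect_equal(sum(bins$bin_id != "unbinned"), 20)
})

test_that("size filter keeps bins above 0.5 Mbp and can promote singletons", {
  bins <- data.frame(
    contig_id = c("a1", "a2", "b1", "b2", "big", "tiny"),
    bin_id = c("bin_01", "bin_01", "bin_02", "bin_02", "unbinned", "unbinned"),
    contig_length = c(3e5, 2.5e5, 2e5, 2e5, 3.3e6, 2e4),
    stringsAsFactors = FALSE)
  class(bins) <- c("bin_table", "data.frame")
  out <- filter_bins_by_size(bins)
  expect_equal(out$bin_id[1:2], c("bin_01", "bin_01"))   # 550 kbp retained
  expect_true(all(out$bin_id[3:4] == "unbinned"))        # 400 kbp dropped
  out2 <- filter_bins_by_size(bins, allow_singletons = TRUE)
  big_bin <- out2$bin_id[out2$contig_id == "big"]
  expect_true(grepl("^bin_", big_bin))                   # 3.3 Mbp singleton
  expect_equal(out2$bin_id[out2$contig_id == "tiny"], "unbinned")
  bins$contig_length[1] <- NA
  expect_error(filter_bins_by_size(bins), "missing contig length")
})

test_that("consensus lineage reports majority label and assigned fraction", {
  bins <- data.frame(contig_id = sprintf("c%02d", 1:10),
                     bin_id = "bin_01",
                     contig_length = 1e4, stringsAsFactors = FALSE)
  class(bins) <- c("bin_table", "data.frame")
  lin <- setNames(c(rep("Bacteroidetes", 7), rep("unassigned", 3)),
                  bins$contig_id)
  res <- consensus_lineage(bins, lin)
  expect_equal(res$lineage, "Bacteroidetes")
  expect_equal(res$support, 1)
  expect_false(res$predominantly_unassigned)

  res2 <- consensus_lineage(bins, setNames(rep("unassigned", 10), bins$contig_id))
  expect_equal(res2$lineage, "unassigned")
  expect_equal(res2$support, 0)
  expect_true(res2$predominantly_unassigned)

  lin3 <- setNames(c(rep("Chlorobi", 4), rep("Spirochaetes", 3),
                     rep("unassigned", 3)), bins$contig_id)
  res3 <- consensus_lineage(bins, lin3)
  expect_equal(res3$lineage, "Chlorobi")
  expect_equal(res3$support, 4 / 7)
})

test_that("binning evaluation matches a brute-force pair-counting ARI", {
  mk_bins <- function(labels) {
    df <- data.frame(contig_id = names(labels), bin_id = unname(labels),
                     contig_length = 1e4, stringsAsFactors = FALSE)
    class(df) <- c("bin_table", "data.frame")
    df
  }
  truth <- setNames(rep(c("gA", "gB"), each = 6), sprintf("c%02d", 1:12))
  expect_equal(evaluate_binning(mk_bins(truth), truth)$ari, 1)
  lumped <- setNames(rep("bin_01", 12), names(truth))
  expect_equal(evaluate_binning(mk_bins(lumped), truth)$ari, 0)

  set.seed(77)
  for (i in 1:5) {
    pred <- setNames(sample(c("bin_01", "bin_02", "bin_03"), 12, replace = TRUE),
                     names(truth))
    expect_equal(evaluate_binning(mk_bins(pred), truth)$ari,
                 pair_count_ari(unname(pred), unname(truth)),
                 tolerance = 1e-12)
  }
  expect_error(evaluate_binning(mk_bins(lumped), truth[1:5]), "truth missing")
})

test_that("bin membership is invariant under contig input order", {
  occ <- three_genome_occurrence(seed = 21)
  pm <- pairwise_pvalues(occ)
  lens <- setNames(rep(2e4, nrow(pm$p)), rownames(pm$p))
  bins1 <- cluster_embedding(embed_pvalue_distances(pm), contig_lengths = lens)
  perm <- sample(nrow(occ$presence))
  occ2 <- structure(list(presence = occ$presence[perm, ], threshold = 2048,
                         log2_coverage = NULL), class = "occurrence_matrix")
  bins2 <- cluster_embedding(embed_pvalue_distances(pairwise_pvalues(occ2)),
                             contig_lengths = lens)
  m1 <- setNames(bins1$bin_id, bins1$contig_id)
  m2 <- setNames(bins2$bin_id, bins2$contig_id)[names(m1)]
  ## identical partitions up to bin relabelling
  expect_equal(pair_count_ari(unname(m1), unname(m2)), 1)
})
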
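test_that("binarization thresholds coverage at the presence cutoff", {
  m <- matrix(c(4096, 1024, 2048, 0), 2, 2,
              dimnames = list(c("c1", "c2"), c("s1", "s2")))
  occ <- binarize_coverage(coverage_matrix(m), threshold = 2048)
  expect_equal(occ$presence["c1", "s1"], 1L)   # above threshold
  expect_equal(occ$presence["c2", "s1"], 0L)   # below threshold
  expect_equal(occ$presence["c1", "s2"], 1L)   # boundary counts as present
  expect_error(binarize_coverage(coverage_matrix(m), threshold = 0),
               "positive")

  ## elementwise oracle on a random matrix
  set.seed(5)
  big <- matrix(rpois(100 * 96, 2200), 100, 96,
                dimnames = list(sprintf("c%03d", 1:100), sprintf("s%02d", 1:96)))
  occ2 <- binarize_coverage(coverage_matrix(big), threshold = 2048)
  manual <- sum(vapply(seq_along(big), function(i) big[i] >= 2048, TRUE))
  expect_equal(sum(occ2$presence), manual)
})

test_that("raising the binarization threshold never creates a presence", {
  set.seed(31)
  cov <- coverage_matrix(matrix(rpois(60 * 24, 2000), 60, 24,
                                dimnames = list(sprintf("c%02d", 1:60),
                                                sprintf("s%02d", 1:24))))
  thresholds <- 2^(9:13)
  prev <- binarize_coverage(cov, thresholds[1])$presence
  for (th in thresholds[-1]) {
    cur <- binarize_coverage(cov, th)$presence
    expect_true(all(cur <= prev))   # monotone thinning
    prev <- cur
  }
})

test_that("contingency counts follow the a/b/c/d definition", {
  ## the worked co-occurrence pattern: 8 shared, 1 only-Y, 2 only-X, 6 neither
  x1 <- c(rep(1, 8), 0, 1, 1, rep(0, 6))
  y1 <- c(rep(1, 8), 1, 0, 0, rep(0, 6))
  expect_equal(tabulate_contingency(x1, y1), c(a = 8, b = 1, c = 2, d = 6))

  x <- rbinom(20, 1, 0.5)
  expect_equal(unname(tabulate_contingency(x, x)[c("b", "c")]), c(0, 0))
  expect_equal(unname(tabulate_contingency(x, 1 - x)[c("a", "d")]), c(0, 0))
  expect_error(tabulate_contingency(c(0, 1), c(0, 1, 1)), "length")
  expect_error(tabulate_contingency(c(0, 2), c(0, 1)), "binary")
})

test_that("point probability reproduces the worked example and edge cases", {
  expect_equal(round(fisher_point_probability(8, 1, 2, 6), 3), 0.013)
  ## the value is the exact rational 252/19448
  expect_equal(fisher_point_probability(8, 1, 2, 6), 252 / 19448)
  expect_equal(fisher_point_probability(0, 0, 0, 9), 1)
  expect_equal(fisher_point_probability(0, 0, 0, 0), 1)
  expect_error(fisher_point_probability(-1, 0, 0, 3), "non-negative")
  expect_error(fisher_point_probability(1.5, 0, 0, 3), "non-negative")
})

test_that("point probability equals subset-enumeration oracle for n <= 12", {
  ## exhaustive over a deterministic sample of small tables plus all n <= 7
  tables <- list()
  for (n in 0:7)
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b))
      tables[[length(tables) + 1]] <- c(a, b, cc, n - a - b - cc)
  set.seed(2)
  for (i in 1:60) {
    n <- sample(8:12, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    tables[[length(tables) + 1]] <-
      c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], n - cuts[3])
  }
  for (tb in tables) {
    expect_equal(fisher_point_probability(tb[1], tb[2], tb[3], tb[4]),
                 enum_point_probability(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12,
                 info = paste(tb, collapse = ","))
  }
})

test_that("point probabilities over all overlaps with fixed margins sum to 1", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(2:60, 1)
    x <- sample(0:n, 1)   # X-present margin
    y <- sample(0:n, 1)   # Y-present margin
    as <- max(0, x + y - n):min(x, y)
    total <- sum(vapply(as, function(a)
      fisher_point_probability(a, y - a, x - a, n - x - y + a), 1))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("point probability respects the table's transposition symmetries", {
  set.seed(13)
  for (i in 1:40) {
    tb <- rmultinom(1, sample(4:40, 1), prob = runif(4, 0.05, 1))[, 1]
    a <- tb[1]; b <- tb[2]; cc <- tb[3]; d <- tb[4]
    expect_equal(fisher_point_probability(a, b, cc, d),
                 fisher_point_probability(a, cc, b, d))   # swap b <-> c
    expect_equal(fisher_point_probability(a, b, cc, d),
                 fisher_point_probability(b, a, d, cc))   # swap columns
  }
})

test_that("pairwise matrix is symmetric and matches per-pair evaluation", {
  set.seed(41)
  m <- matrix(rbinom(15 * 30, 1, 0.4) * 4096, 15, 30,
              dimnames = list(sprintf("c%02d", 1:15), sprintf("s%02d", 1:30)))
  occ <- binarize_coverage(coverage_matrix(m))
  pm <- pairwise_pvalues(occ)
  expect_identical(pm$p, t(pm$p))
  expect_true(all(pm$p > 0 & pm$p <= 1))
  for (pair in list(c(1, 2), c(3, 9), c(14, 15))) {
    ct <- tabulate_contingency(occ$presence[pair[1], ], occ$presence[pair[2], ])
    expect_equal(pm$p[pair[1], pair[2]], fisher_point_probability(ct))
  }
  ## the worked example as a 2-contig matrix
  x1 <- c(rep(1, 8), 0, 1, 1, rep(0, 6))
  y1 <- c(rep(1, 8), 1, 0, 0, rep(0, 6))
  occ2 <- structure(list(presence = rbind(X1 = x1, Y1 = y1), threshold = 2048,
                         log2_coverage = NULL), class = "occurrence_matrix")
  pm2 <- pairwise_pvalues(occ2)
  expect_equal(round(pm2$p["X1", "Y1"], 3), 0.013)
})

test_that("a duplicated contig attains the minimum over tables sharing its margins", {
  set.seed(6)
  x <- rbinom(24, 1, 0.5)
  occ <- structure(list(presence = rbind(X = x, X2 = x), threshold = 2048,
                        log2_coverage = NULL), class = "occurrence_matrix")
  p_self <- pairwise_pvalues(occ)$p["X", "X2"]
  n <- length(x); k <- sum(x)
  all_tables <- vapply(max(0, 2 * k - n):k, function(a)
    fisher_point_probability(a, k - a, k - a, n - 2 * k + a), 1)
  expect_equal(p_self, min(all_tables))
})

test_that("pairwise matrix is invariant under contig reordering", {
  set.seed(17)
  m <- matrix(rbinom(12 * 20, 1, 0.5) * 4096, 12, 20,
              dimnames = list(sprintf("c%02d", 1:12), sprintf("s%02d", 1:20)))
  occ <- binarize_coverage(coverage_matrix(m))
  perm <- sample(1:12)
  occp <- binarize_coverage(coverage_matrix(m[perm, ]))
  p1 <- pairwise_pvalues(occ)$p
  p2 <- pairwise_pvalues(occp)$p
  expect_equal(p2, p1[rownames(p2), colnames(p2)])
})

test_that("multiple-comparison correction follows bonferroni and BH rules", {
  mk <- function(p12, p13, p23) {
    p <- matrix(c(1, p12, p13, p12, 1, p23, p13, p23, 1), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
    diag(p) <- min(p12, p13, p23)
    structure(list(p = p, corrected = FALSE, correction_method = "none",
                   m = NULL), class = "pvalue_matrix")
  }
  pc <- correct_pvalues(mk(1e-4, 0.02, 0.5), method = "bonferroni", m = 100)
  expect_equal(pc$p["a", "b"], 0.01)
  expect_equal(pc$p["a", "c"], 1)      # capped
  expect_true(pc$corrected)
  expect_error(correct_pvalues(pc), "already corrected")

  ## BH equals a brute-force sort-and-scan step-up oracle
  set.seed(9)
  n <- 20
  labels <- sprintf("c%02d", seq_len(n))
  p <- matrix(1, n, n, dimnames = list(labels, labels))
  vals <- runif(choose(n, 2))^2
  p[upper.tri(p)] <- vals
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  pm <- structure(list(p = p, corrected = FALSE, correction_method = "none",
                       m = NULL), class = "pvalue_matrix")
  bh <- correct_pvalues(pm, method = "benjamini-hochberg")
  ord <- order(vals)
  m <- length(vals)
  stepup <- numeric(m)
  run_min <- 1
  for (r in m:1) {
    run_min <- min(run_min, vals[ord[r]] * m / r)
    stepup[ord[r]] <- run_min
  }
  expect_equal(bh$p[upper.tri(bh$p)], stepup)
})
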
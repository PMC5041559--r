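test_that("binary profile applies the score-2 rule", {
  m <- matrix(c(0, 1, 2), 1, 3, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(binary_profile(m)[1, ]), c(0L, 0L, 1L))
  all2 <- matrix(2, 2, 2, dimnames = list(1:2, 1:2))
  expect_true(all(binary_profile(all2) == 1))
  expect_error(binary_profile(matrix(integer(), 1, 0)), "empty marker set")
})

test_that("binary Euclidean distance is sqrt(Hamming) and a metric", {
  m <- rbind(a = c(1, 0, 0), b = c(0, 1, 0))
  expect_equal(euclidean_binary(m)["a", "b"], sqrt(2))
  m8 <- rbind(x = rep(c(1, 0), 4), y = rep(c(0, 1), 4))
  expect_equal(euclidean_binary(m8)["x", "y"], sqrt(8))
  expect_equal(euclidean_binary(rbind(a = c(1, 1), b = c(1, 1)))["a", "b"], 0)
  expect_error(euclidean_binary(rbind(c(0, 2))), "binary")
  # triangle inequality, exhaustively for all 4-bit profiles
  profs <- as.matrix(expand.grid(rep(list(0:1), 4)))
  rownames(profs) <- seq_len(nrow(profs))
  d <- euclidean_binary(profs)
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("UPGMA merges match hand calculations and tie-break rules", {
  d <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  h <- average_linkage(d)
  expect_equal(h$height, c(1, 5))
  expect_equal(h$merge[1, ], c(-1L, -2L))
  # all-equal distances: merges by smallest index, equal heights
  de <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  he <- average_linkage(de)
  expect_equal(he$height, rep(2, 3))
  expect_equal(he$merge[1, ], c(-1L, -2L))
  expect_equal(he$order, 1:4)
  expect_error(average_linkage(matrix(0, 1, 1)), "at least 2")
})

test_that("UPGMA equals the brute-force oracle for n <= 7", {
  set.seed(19)
  for (rep in 1:30) {
    n <- sample(2:7, 1)
    prof <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
                   dimnames = list(paste0("i", 1:n), NULL))
    d <- euclidean_binary(prof)
    h <- average_linkage(d)
    expect_equal(sort(h$height), oracle_upgma_heights(d), tolerance = 1e-9)
  }
})

test_that("UPGMA matches stats::hclust on tie-free distances", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 4), n)
    rownames(x) <- paste0("i", 1:n)
    d <- as.matrix(dist(x))
    mine <- average_linkage(d)
    ref <- hclust(as.dist(d), method = "average")
    expect_equal(tree_cophenetic(mine), tree_cophenetic(ref),
                 tolerance = 1e-9)
  }
})

test_that("UPGMA is invariant to item permutation", {
  set.seed(29)
  x <- matrix(rbinom(8 * 5, 1, 0.5), 8)
  rownames(x) <- paste0("i", 1:8)
  d <- euclidean_binary(x)
  h1 <- average_linkage(d)
  perm <- sample(8)
  h2 <- average_linkage(d[perm, perm])
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
  co1 <- tree_cophenetic(h1)
  co2 <- tree_cophenetic(h2)[rownames(co1), colnames(co1)]
  expect_equal(co1, co2, tolerance = 1e-12)
})

test_that("merge heights are monotone non-decreasing", {
  set.seed(31)
  for (rep in 1:10) {
    prof <- matrix(rbinom(60, 1, 0.4), 10)
    rownames(prof) <- paste0("i", 1:10)
    h <- average_linkage(euclidean_binary(prof))
    expect_true(all(diff(h$height) >= -1e-12))
  }
})

test_that("heatmap ordering permutes to leaf order and keeps blocks", {
  co <- simulate_cohort(cohort_config(
    n_regions = 10, group_sizes = c(PDSCC = 8, non_lepidic_AD = 10),
    seed = 14))
  markers <- rbind(ihc_marker("a1", "AD", sensitivity = .97, specificity = .97),
                   ihc_marker("a2", "AD", sensitivity = .97, specificity = .97),
                   ihc_marker("s1", "SCC", sensitivity = .97, specificity = .97),
                   ihc_marker("s2", "SCC", sensitivity = .97, specificity = .97))
  tab <- simulate_ihc(markers, co$samples, seed = 14)
  cl <- cluster_ihc(tab)
  ord <- heatmap_order(tab, cl$sample_tree, cl$marker_tree)
  expect_setequal(rownames(ord), rownames(tab$scores))
  expect_equal(rownames(ord),
               cl$sample_tree$labels[cl$sample_tree$order])
  # two-block structure: each supertype contiguous in the leaf order
  sup <- tab$samples$supertype[match(rownames(ord), tab$samples$sample_id)]
  expect_equal(length(rle(sup)$values), 2)
  expect_error(heatmap_order(tab$scores[, 1:2], cl$sample_tree,
                             cl$marker_tree), "labels")
})

test_that("two-class cohorts split at the root of the sample tree", {
  co <- simulate_cohort(cohort_config(n_regions = 10, seed = 41))
  markers <- do.call(rbind, c(
    lapply(1:4, function(i) ihc_marker(paste0("ad", i), "AD",
                                       sensitivity = .95, specificity = .95)),
    lapply(1:4, function(i) ihc_marker(paste0("sc", i), "SCC",
                                       sensitivity = .95, specificity = .95))))
  tab <- simulate_ihc(markers, co$samples, seed = 41)
  tree <- cluster_ihc(tab)$sample_tree
  groups <- cutree(tree, 2)
  sup <- tab$samples$supertype
  expect_true(all(table(groups, sup) %in%
                    c(0, as.vector(table(sup)))))
})

test_that("Newick export preserves tree depth as merge height", {
  prof <- matrix(rbinom(40, 1, 0.5), 8)
  rownames(prof) <- paste0("i", 1:8)
  h <- average_linkage(euclidean_binary(prof))
  nwk <- tree_newick(h)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(prof))
  depth <- max(ape::node.depth.edgelength(phy))
  expect_equal(depth, max(h$height), tolerance = 1e-6)
})
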
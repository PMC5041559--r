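make_counts <- function(counts, lib = NULL) {
  rownames(counts) <- sprintf("r%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  cage_counts(counts, lib_sizes = lib)
}

test_that("library QC uses a strict threshold and reports removals", {
  m <- make_counts(matrix(1, 2, 3), lib = c(3e6, 2e6, 1e6))
  expect_message(kept <- qc_libraries(m), "s02, s03")
  expect_identical(colnames(kept$counts), "s01")
  same <- make_counts(matrix(1, 2, 3), lib = rep(5e6, 3))
  expect_identical(qc_libraries(same)$counts, same$counts)
  expect_error(qc_libraries(m, min_mapped = 1e7), "no library exceeds")
})

test_that("CPM is count * 1e6 / library size with no pseudocount", {
  m <- make_counts(matrix(c(5, 0, 13, 2), 2, 2), lib = c(1e6, 2.5e6))
  v <- cpm(m)
  expect_equal(v[1, 1], 5.0)
  expect_equal(v[2, 1], 0.0)
  expect_equal(v[1, 2], 13 * 1e6 / 2.5e6)  # = 5.2
  expect_equal(v[1, 2], 5.2)
})

test_that("CPM round-trips back to counts given library sizes", {
  set.seed(42)
  m <- make_counts(matrix(rpois(200, 50), 20, 10),
                   lib = round(runif(10, 2e6, 8e6)))
  back <- sweep(cpm(m), 2, m$lib_sizes, "*") / 1e6
  expect_equal(back, m$counts + 0, tolerance = 1e-9)
})

test_that("inactivity filter removes regions silent in both groups", {
  samples <- sample_table(sprintf("s%02d", 1:20),
                          rep(c("MDSCC", "mixed_lepidic_AD"), each = 10))
  cpm_mat <- matrix(10, 4, 20,
                    dimnames = list(paste0("r", 1:4), samples$sample_id))
  cpm_mat[1, ] <- 0                      # silent everywhere -> removed
  cpm_mat[2, ] <- 2                      # active everywhere -> kept
  cpm_mat[3, 1:8] <- 0.5                 # 8/10 > 0.77 in SCC only -> kept
  cpm_mat[3, 11:17] <- 0.5               # 7/10 <= 0.77 in AD
  kept <- filter_inactive(cpm_mat, samples)
  expect_setequal(kept, c("r2", "r3", "r4"))
  expect_error(filter_inactive(cpm_mat, samples, frac = 1.2), "frac")
})

test_that("inactivity filter matches the brute-force oracle", {
  samples <- sample_table(sprintf("s%02d", 1:20),
                          rep(c("PDSCC", "non_lepidic_AD"), each = 10))
  ga <- samples$sample_id[1:10]; gb <- samples$sample_id[11:20]
  set.seed(7)
  for (i in 1:25) {
    cpm_mat <- matrix(round(rexp(400, 0.5), 2), 20, 20,
                      dimnames = list(sprintf("r%02d", 1:20),
                                      samples$sample_id))
    expect_identical(
      filter_inactive(cpm_mat, samples, groups = c("SCC", "AD")),
      oracle_filter_inactive(cpm_mat, ga, gb))
  }
})

test_that("pooled filter variant applies the rule over the union", {
  samples <- sample_table(sprintf("s%02d", 1:20),
                          rep(c("PDSCC", "non_lepidic_AD"), each = 10))
  cpm_mat <- matrix(0, 1, 20, dimnames = list("r1", samples$sample_id))
  cpm_mat[1, 1:10] <- 5   # active in all SCC: 10/20 low <= 0.77 pooled
  expect_identical(filter_inactive(cpm_mat, samples, pooled = TRUE), "r1")
  # per-group rule also keeps it (SCC group fully active)
  expect_identical(filter_inactive(cpm_mat, samples), "r1")
  cpm_mat[1, 1:8] <- 0    # now 18/20 = 0.9 > 0.77 pooled -> removed
  expect_identical(filter_inactive(cpm_mat, samples, pooled = TRUE),
                   character(0))
})

test_that("MDS distances are metric-shaped and separate planted supertypes", {
  co <- simulate_cohort(cohort_config(
    n_regions = 150, n_de = 40, de_log2fc = 4,
    group_sizes = c(PDSCC = 8, non_lepidic_AD = 10), seed = 3))
  cpm_mat <- cpm(co$counts)
  res <- mds_cage(cpm_mat, top_n = 100)
  d <- res$dist
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # identical columns at distance zero
  dup <- cbind(cpm_mat, dup = cpm_mat[, 1])
  colnames(dup)[ncol(dup)] <- "dup"
  d2 <- mds_cage(dup, top_n = 100)$dist
  expect_equal(unname(d2[1, ncol(dup)]), 0)
  # planted structure: embedded inter-supertype distance exceeds intra
  co_d <- as.matrix(dist(res$coords))
  scc <- co$samples$supertype == "SCC"
  inter <- mean(co_d[scc, !scc])
  intra <- mean(c(co_d[scc, scc][upper.tri(co_d[scc, scc])],
                  co_d[!scc, !scc][upper.tri(co_d[!scc, !scc])]))
  expect_gt(inter, intra)
  expect_error(mds_cage(cpm_mat[, 1:2]), "3 samples")
})

test_that("classical MDS reproduces rank-2 distance structures", {
  set.seed(10)
  y <- matrix(rnorm(16), 8, 2)           # true 2-d configuration
  # two 'regions' whose shifted log-CPM equals the coordinates (plus offset)
  lg <- t(y) + 10
  cpm_mat <- 2^lg - 0.5
  rownames(cpm_mat) <- c("rA", "rB")
  colnames(cpm_mat) <- paste0("s", 1:8)
  res <- mds_cage(cpm_mat, top_n = 2, dims = 2)
  want <- as.matrix(dist(y)) / sqrt(2)   # rms over the 2 regions
  expect_equal(as.matrix(dist(res$coords)), want, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("region and matrix IO round-trips through TSV and BED", {
  co <- simulate_cohort(cohort_config(n_regions = 25,
                                      group_sizes = c(PDSCC = 3,
                                                      non_lepidic_AD = 4),
                                      seed = 8))
  dir <- withr::local_tempdir()
  write_bed_regions(co$counts$regions, file.path(dir, "r.bed"))
  write_tsv_matrix(co$counts, file.path(dir, "c.tsv"))
  write_sample_table(co$samples, file.path(dir, "s.tsv"))
  regions <- read_bed_regions(file.path(dir, "r.bed"))
  m <- read_count_matrix(file.path(dir, "c.tsv"), regions,
                         co$counts$lib_sizes)
  expect_equal(m$counts, co$counts$counts)
  expect_equal(m$regions$start, co$counts$regions$start)
  expect_equal(read_sample_table(file.path(dir, "s.tsv")), co$samples)
})
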
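test_that("common dispersion estimator recovers Poisson and NB truth", {
  set.seed(31)
  grp <- rep(c("a", "b"), each = 10)
  mu <- rexp(2000, 1 / 50)
  pois <- t(sapply(mu, function(m) rpois(20, m)))
  dimnames(pois) <- list(sprintf("r%04d", 1:2000), sprintf("s%02d", 1:20))
  expect_lt(estimate_common_dispersion(pois, grp, rep(1e6, 20)), 0.05)

  nb <- t(sapply(mu, function(m) rnbinom(20, size = 1 / 0.4, mu = m)))
  dimnames(nb) <- dimnames(pois)
  phi_hat <- estimate_common_dispersion(nb, grp, rep(1e6, 20))
  expect_lt(abs(phi_hat / 0.4 - 1), 0.25)

  const <- matrix(5, 10, 4, dimnames = list(paste0("r", 1:10),
                                            paste0("s", 1:4)))
  expect_equal(estimate_common_dispersion(const, c("a", "a", "b", "b"),
                                          rep(1e6, 4)), 0)
  expect_error(estimate_common_dispersion(const, c("a", "b", "b", "b"),
                                          rep(1e6, 4)), "at least 2")
})

test_that("NB exact test: modal split has p = 1, groups are exchangeable", {
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), phi = 0.1), 1)
  set.seed(12)
  for (i in 1:20) {
    a <- rpois(3, 20); b <- rpois(4, 20)
    expect_equal(nb_exact_test(a, b, phi = 0.2),
                 nb_exact_test(b, a, phi = 0.2))
  }
  expect_error(nb_exact_test(c(-1, 2), c(1, 1), 0.1), "non-negative")
  expect_error(nb_exact_test(c(1, 2), c(1, 1), -0.5), "phi")
})

test_that("NB exact test reduces to the two-sided binomial at phi = 0", {
  for (t in c(1, 5, 12, 30)) {
    for (sa in 0:t) {
      expect_equal(nb_exact_test(sa, t - sa, phi = 0),
                   oracle_binom_twosided(sa, t, 0.5), tolerance = 1e-12)
    }
  }
})

test_that("NB exact test equals split enumeration on small instances", {
  for (t in c(4, 9, 14, 20)) {
    for (sa in 0:t) {
      got <- promopanel:::nb_exact_pvalue(sa, t - sa, 2, 2, 0.1)
      expect_equal(got, oracle_nb_exact(sa, t - sa, 2, 2, 0.1),
                   tolerance = 1e-9)
    }
  }
  # unequal group sizes too
  expect_equal(promopanel:::nb_exact_pvalue(3, 12, 3, 12, 0.25),
               oracle_nb_exact(3, 12, 3, 12, 0.25), tolerance = 1e-9)
})

test_that("BH adjustment matches the hand step-up and its edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(4)
  for (i in 1:10) {
    p <- runif(50)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("candidate filter applies strict cuts and is threshold-monotone", {
  res <- data.frame(region_id = c("r1", "r2", "r3", "r4"),
                    mean_cpm = c(10, 10, 10, 3),
                    log2fc = c(3, 3, -3, 3),
                    pvalue = c(1e-4, 1e-3, 1e-4, 1e-5),
                    fdr = c(0.01, 0.005, 0.001, 0.001))
  out <- candidate_filter(res, screen_thresholds())
  expect_identical(out$up_group2$region_id, "r2")  # r1 at fdr == 0.01: out
  expect_identical(out$up_group1$region_id, "r3")  # r4 fails cpm > 4
  strict <- candidate_filter(res, screen_thresholds(0.01, 4, 4))
  loose <- candidate_filter(res, screen_thresholds(0.02, 2, 1))
  expect_true(all(c(strict$up_group1$region_id, strict$up_group2$region_id)
                  %in% c(loose$up_group1$region_id,
                         loose$up_group2$region_id)))
  # exact fold-change boundary: |fc| = 4 is excluded
  res2 <- data.frame(region_id = "x", mean_cpm = 10, log2fc = 2,
                     pvalue = 1e-5, fdr = 1e-4)
  out2 <- candidate_filter(res2)
  expect_equal(nrow(out2$up_group2), 0)
})

test_that("complete separation handles direction, threshold and ties", {
  s <- complete_separation(c(1, 2, 3), c(10, 20))
  expect_equal(s$direction, "B")
  expect_equal(s$margin, log2(10 / 3))
  expect_equal(s$threshold, sqrt(30))
  expect_null(complete_separation(c(1, 5), c(4, 9)))
  expect_null(complete_separation(2, 2))
  z <- complete_separation(c(0, 0), c(3, 8))
  expect_equal(z$threshold, 1.5)   # arithmetic midpoint when boundary is 0
  expect_equal(z$margin, Inf)
  expect_error(complete_separation(numeric(0), 1), "non-empty")
})

test_that("complete separation agrees with a threshold-scan oracle", {
  set.seed(15)
  for (i in 1:200) {
    a <- round(rexp(sample(2:6, 1), 0.3), 1)
    b <- round(rexp(sample(2:6, 1), 0.3), 1)
    expect_equal(!is.null(complete_separation(a, b)), oracle_separates(a, b))
  }
})

test_that("null cohort yields near-zero candidates at FDR < 0.01", {
  co <- simulate_cohort(cohort_config(n_regions = 500, n_de = 0,
                                      n_separators = 0, seed = 17))
  de <- de_screen(co$counts, co$samples)
  expect_lte(sum(de$candidate), 2)
  expect_equal(sum(de$separator), sum(de$candidate & de$separator))
})

test_that("planted fold-change regions are recovered by the screen", {
  # pilot-run regression: recovered fraction frozen from a seeded run
  co <- simulate_cohort(cohort_config(n_regions = 2000, n_de = 50,
                                      de_log2fc = 3, seed = 20160929))
  de <- de_screen(co$counts, co$samples)
  planted <- co$truth$region_id[co$truth$role == "de"]
  recovered <- mean(planted %in% de$region_id[de$candidate])
  expect_equal(recovered, FROZEN_DE_RECOVERY, tolerance = 1e-12)
  expect_gt(recovered, 0.5)
})
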
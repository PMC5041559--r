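# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# frozen regression value from a seeded pilot run of the planted
# fold-change screen (seed 20160929, 2000 regions, 50 planted at log2fc 3)
FROZEN_DE_RECOVERY <- 1

# double-loop inactivity-filter oracle: literal reading of the rule
oracle_filter_inactive <- function(cpm_mat, group_a, group_b,
                                   cpm_threshold = 1, frac = 0.77) {
  keep <- character()
  for (r in rownames(cpm_mat)) {
    inactive_in <- function(ids) {
      n_low <- 0
      for (s in ids) if (cpm_mat[r, s] <= cpm_threshold) n_low <- n_low + 1
      n_low / length(ids) > frac
    }
    if (!(inactive_in(group_a) && inactive_in(group_b)))
      keep <- c(keep, r)
  }
  keep
}

# Clopper-Pearson by bisection on the binomial tail probabilities
oracle_clopper_pearson <- function(x, n, conf = 0.95, tol = 1e-12) {
  alpha <- 1 - conf
  lo <- if (x == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) -
                     alpha / 2,
                   c(tol, 1 - tol), tol = tol)$root
  hi <- if (x == n) 1 else
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(tol, 1 - tol), tol = tol)$root
  c(low = lo, high = hi)
}

# two-sided binomial test, minimum-likelihood method, by direct summation
oracle_binom_twosided <- function(x, size, prob = 0.5) {
  d <- stats::dbinom(0:size, size, prob)
  sum(d[d <= d[x + 1] * (1 + 1e-9)])
}

# NB exact-test oracle: enumerate all splits of the total using dnbinom
# group-sum pmfs at an arbitrary fixed mean (the conditional law is free of
# the mean; any positive value works)
oracle_nb_exact <- function(sa, sb, na, nb, phi, mu = 7) {
  t <- sa + sb
  f <- function(s, n) stats::dnbinom(s, size = n / phi, mu = n * mu)
  w <- f(0:t, na) * f(t - (0:t), nb)
  w <- w / sum(w)
  sum(w[w <= w[sa + 1] * (1 + 1e-9)])
}

# complete separation by brute-force scan over all candidate thresholds
oracle_separates <- function(x_a, x_b) {
  for (thr in sort(unique(c(x_a, x_b)))) {
    if (all(x_a <= thr) && all(x_b > thr)) return(TRUE)
    if (all(x_b <= thr) && all(x_a > thr)) return(TRUE)
  }
  FALSE
}

# brute-force UPGMA: clusters as index sets, cross-cluster mean distance
# recomputed from the original matrix at every step (no incremental update)
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  avg <- function(ci, cj) mean(d[ci, cj])
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        a <- avg(clusters[[i]], clusters[[j]])
        if (a < best - 1e-12) { best <- a; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# cophenetic matrix of an hclust tree, for representation-free comparison
tree_cophenetic <- function(h) as.matrix(stats::cophenetic(h))

# hand-rolled BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# deterministic 74-sample validation-style fixture: 45 AD + 29 SCC samples,
# four markers. The stage-1 pair (ST6x, CK5x) is the unique best panel: it
# classifies 67 correctly and leaves 7 inconclusive (2 AD double-negative,
# 5 SCC double-positive). The stage-2 pair (TTF1x, SPATS2x) misses some
# stage-1-classified samples (so it is not best overall) but resolves all
# 7 residual inconclusive cases correctly.
fixture_validation_calls <- function() {
  n_ad <- 45; n_scc <- 29
  ids <- c(sprintf("AD%02d", seq_len(n_ad)), sprintf("SCC%02d", seq_len(n_scc)))
  supertype <- rep(c("AD", "SCC"), c(n_ad, n_scc))
  ad_inc <- 1:2          # AD cases inconclusive at stage 1 (double negative)
  scc_inc <- n_ad + 1:5  # SCC cases inconclusive at stage 1 (double positive)
  st6 <- c(rep(TRUE, n_ad), rep(FALSE, n_scc))
  ck5 <- c(rep(FALSE, n_ad), rep(TRUE, n_scc))
  st6[ad_inc] <- FALSE
  st6[scc_inc] <- TRUE
  ttf1 <- c(rep(TRUE, n_ad), rep(FALSE, n_scc))
  ttf1[3:10] <- FALSE    # TTF1x misses 8 stage-1-classified AD cases
  spats2 <- c(rep(FALSE, n_ad), rep(TRUE, n_scc))
  spats2[20] <- TRUE     # one SPATS2x false positive outside the residuals
  calls <- cbind(ST6x = st6, CK5x = ck5, TTF1x = ttf1, SPATS2x = spats2)
  rownames(calls) <- ids
  list(calls = calls, supertype = supertype,
       markers = data.frame(name = colnames(calls),
                            marker_class = c("AD", "SCC", "AD", "SCC"),
                            stringsAsFactors = FALSE))
}

# printed 2x2 counts and table cells of the published marker evaluations
# (counts are the inputs; metrics and CIs are recomputed from them)
published_marker_tables <- function() {
  row <- function(set, marker, class, a, b, c, d, sens, spec, ppv, npv, acc,
                  skip_accuracy_ci = FALSE) {
    data.frame(set = set, marker = marker, class = class,
               a = a, b = b, c = c, d = d,
               sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
               accuracy = acc, skip_accuracy_ci = skip_accuracy_ci,
               stringsAsFactors = FALSE)
  }
  rbind(
    # discovery set: 12 non-lepidic AD vs 3 PDSCC
    row("discovery", "ST6GALNAC1", "AD", 8, 0, 4, 3,
        "0.667 (0.349-0.901)", "1.000 (0.292-1.000)", "1.000 (0.631-1.000)",
        "0.429 (0.099-0.816)", "0.733", skip_accuracy_ci = TRUE),
    row("discovery", "TTF-1", "AD", 5, 0, 7, 3,
        "0.417 (0.152-0.723)", "1.000 (0.292-1.000)", "1.000 (0.478-1.000)",
        "0.300 (0.067-0.652)", "0.533 (0.266-0.787)"),
    row("discovery", "napsinA", "AD", 2, 0, 10, 3,
        "0.167 (0.021-0.484)", "1.000 (0.292-1.000)", "1.000 (0.158-1.000)",
        "0.231 (0.050-0.538)", "0.333 (0.118-0.616)"),
    row("discovery", "SPATS2", "SCC", 2, 0, 1, 12,
        "0.667 (0.094-0.992)", "1.000 (0.735-1.000)", "1.000 (0.158-1.000)",
        "0.923 (0.640-0.998)", "0.933 (0.681-0.998)"),
    row("discovery", "CK5", "SCC", 1, 0, 2, 12,
        "0.333 (0.008-0.906)", "1.000 (0.735-1.000)", "1.000 (0.025-1.000)",
        "0.857 (0.572-0.982)", "0.867 (0.595-0.983)"),
    row("discovery", "DSG3", "SCC", 0, 0, 3, 12,
        "0.000 (0.000-0.708)", "1.000 (0.735-1.000)", "N.A.",
        "0.800 (0.519-0.957)", "0.800 (0.519-0.957)"),
    row("discovery", "p40", "SCC", 1, 0, 2, 12,
        "0.333 (0.008-0.906)", "1.000 (0.735-1.000)", "1.000 (0.025-1.000)",
        "0.857 (0.572-0.982)", "0.867 (0.595-0.983)"),
    row("discovery", "CK6", "SCC", 0, 0, 3, 12,
        "0.000 (0.000-0.708)", "1.000 (0.735-1.000)", "N.A.",
        "0.800 (0.519-0.957)", "0.800 (0.519-0.957)"),
    # validation set: 16 non-lepidic AD vs 11 PDSCC
    row("validation", "ST6GALNAC1", "AD", 15, 0, 1, 11,
        "0.938 (0.698-0.998)", "1.000 (0.715-1.000)", "1.000 (0.782-1.000)",
        "0.917 (0.615-0.998)", "0.963 (0.810-0.999)"),
    row("validation", "TTF-1", "AD", 10, 0, 6, 11,
        "0.625 (0.354-0.848)", "1.000 (0.715-1.000)", "1.000 (0.692-1.000)",
        "0.647 (0.383-0.858)", "0.778 (0.577-0.914)"),
    row("validation", "napsinA", "AD", 12, 0, 4, 11,
        "0.750 (0.476-0.927)", "1.000 (0.715-1.000)", "1.000 (0.735-1.000)",
        "0.733 (0.449-0.922)", "0.852 (0.663-0.958)"),
    row("validation", "SPATS2", "SCC", 7, 0, 4, 16,
        "0.636 (0.308-0.891)", "1.000 (0.794-1.000)", "1.000 (0.590-1.000)",
        "0.800 (0.563-0.943)", "0.852 (0.663-0.958)"),
    row("validation", "CK5", "SCC", 7, 0, 4, 16,
        "0.636 (0.308-0.891)", "1.000 (0.794-1.000)", "1.000 (0.590-1.000)",
        "0.800 (0.563-0.943)", "0.852 (0.663-0.958)"),
    row("validation", "DSG3", "SCC", 6, 0, 5, 16,
        "0.545 (0.234-0.833)", "1.000 (0.794-1.000)", "1.000 (0.541-1.000)",
        "0.762 (0.528-0.918)", "0.815 (0.619-0.937)"),
    row("validation", "p40", "SCC", 7, 0, 4, 16,
        "0.636 (0.308-0.891)", "1.000 (0.794-1.000)", "1.000 (0.590-1.000)",
        "0.800 (0.563-0.943)", "0.852 (0.663-0.958)"),
    row("validation", "CK6", "SCC", 5, 9, 6, 7,
        "0.455 (0.167-0.766)", "0.438 (0.198-0.701)", "0.357 (0.128-0.649)",
        "0.538 (0.251-0.808)", "0.444 (0.255-0.647)")
  )
}
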
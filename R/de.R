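#' Pooled common-dispersion estimate for NB counts
#'
#' Method-of-moments estimator: counts are first scaled to a common
#' effective library size (the geometric mean of the library sizes) and
#' rounded; for each region, a dispersion estimate
#' `phi_r = (var - mean) / mean^2` is formed within each group and combined
#' with degrees-of-freedom weights; the common value is the median over
#' regions with positive mean, floored at zero.
#'
#' @param counts regions x samples count matrix (or [cage_counts]).
#' @param groups factor/character of length `ncol(counts)` with exactly two
#'   levels; each group needs at least two samples.
#' @param lib_sizes per-sample library sizes (taken from a [cage_counts]
#'   input, else column sums).
#' @return non-negative scalar dispersion phi (variance = mu + phi mu^2).
#' @export
estimate_common_dispersion <- function(counts, groups, lib_sizes = NULL) {
  if (inherits(counts, "cage_counts")) {
    if (is.null(lib_sizes)) lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  sc <- equalize_libsizes(counts, lib_sizes)
  phis <- vapply(seq_len(nrow(sc)), function(r) {
    est <- 0; w <- 0
    for (g in levels(groups)) {
      x <- sc[r, groups == g]
      m <- mean(x)
      if (m > 0) {
        v <- stats::var(x)
        est <- est + (length(x) - 1) * (v - m) / m^2
        w <- w + length(x) - 1
      }
    }
    if (w > 0) est / w else NA_real_
  }, numeric(1))
  max(0, stats::median(phis, na.rm = TRUE))
}

# scale every sample's counts to the geometric mean library size, rounded
equalize_libsizes <- function(counts, lib_sizes) {
  eff <- exp(mean(log(lib_sizes)))
  round(sweep(counts, 2, eff / lib_sizes, "*"))
}

#' Two-sided NB exact test for a two-group count comparison
#'
#' Counts are scaled to a common effective library size (geometric mean of
#' `lib_sizes`, rounded) and summed within groups. Conditional on the
#' region total, the split between the groups under equal means follows a
#' negative hypergeometric law that does not depend on the mean, so the
#' two-sided p-value is the sum of the probabilities of all splits no more
#' probable than the observed one (minimum-likelihood method). With
#' `phi = 0` this reduces to a two-sided binomial test on the total.
#'
#' @param counts_a,counts_b per-sample counts in each group.
#' @param phi common NB dispersion (>= 0).
#' @param lib_sizes library sizes for `c(counts_a, counts_b)`; `NULL` means
#'   the counts are already on a common scale.
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(counts_a, counts_b, phi, lib_sizes = NULL) {
  if (phi < 0) stop("phi must be >= 0")
  if (any(c(counts_a, counts_b) < 0)) stop("counts must be non-negative")
  if (!is.null(lib_sizes)) {
    stopifnot(length(lib_sizes) == length(counts_a) + length(counts_b))
    sc <- equalize_libsizes(rbind(c(counts_a, counts_b)), lib_sizes)
    counts_a <- sc[seq_along(counts_a)]
    counts_b <- sc[length(counts_a) + seq_along(counts_b)]
  }
  nb_exact_pvalue(sum(counts_a), sum(counts_b),
                  length(counts_a), length(counts_b), phi)
}

# p-value for observed group sums (sa, sb) with group sizes (na, nb)
nb_exact_pvalue <- function(sa, sb, na, nb, phi) {
  t <- sa + sb
  if (t == 0) return(1)
  a <- 0:t
  if (phi <= 0) {
    lw <- stats::dbinom(a, t, na / (na + nb), log = TRUE)
  } else {
    ra <- na / phi; rb <- nb / phi
    lw <- lchoose(a + ra - 1, a) + lchoose(t - a + rb - 1, t - a)
    lw <- lw - max(lw)
    lw <- lw - log(sum(exp(lw)))
  }
  p_obs <- lw[sa + 1]
  min(1, sum(exp(lw[lw <= p_obs + 1e-10])))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1), delegating to
#' [stats::p.adjust()] after validating the input range.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted values in [0, 1].
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Screening thresholds for candidate markers
#'
#' Defaults follow the published screen: FDR < 0.01, fold change > 4 in
#' either direction, mean expression > 4 CPM — all strict inequalities.
#'
#' @param max_fdr,min_fold,min_cpm positive thresholds.
#' @export
screen_thresholds <- function(max_fdr = 0.01, min_fold = 4, min_cpm = 4) {
  if (any(c(max_fdr, min_fold, min_cpm) <= 0))
    stop("thresholds must be positive")
  list(max_fdr = max_fdr, min_fold = min_fold, min_cpm = min_cpm)
}

#' Partition differential results into candidate marker lists
#'
#' Keeps regions with `fdr < max_fdr`, `|fold change| > min_fold` and
#' `mean_cpm > min_cpm` (all strict), split by fold-change sign:
#' `up_group1` (log2fc < 0) and `up_group2` (log2fc > 0).
#'
#' @param results data.frame with columns `region_id`, `mean_cpm`, `log2fc`,
#'   `pvalue`, `fdr` (as from [de_screen()]).
#' @param thresholds a [screen_thresholds()] list.
#' @return list with data.frames `up_group1` and `up_group2`.
#' @export
candidate_filter <- function(results, thresholds = screen_thresholds()) {
  keep <- results$fdr < thresholds$max_fdr &
    2^abs(results$log2fc) > thresholds$min_fold &
    results$mean_cpm > thresholds$min_cpm
  keep[is.na(keep)] <- FALSE
  list(up_group1 = results[keep & results$log2fc < 0, , drop = FALSE],
       up_group2 = results[keep & results$log2fc > 0, , drop = FALSE])
}

#' Detect complete separation of a region's expression between two groups
#'
#' Reports a separator iff the maximum CPM in one group is strictly below
#' the minimum CPM in the other. The discriminating threshold is the
#' geometric mean of the two boundary values (arithmetic midpoint when the
#' lower boundary is 0); the margin is `log2(min_high / max_low)`
#' (`Inf` when `max_low` is 0). Equal boundary values yield no separator.
#'
#' @param x_a,x_b CPM values of the region in each group.
#' @return `NULL`, or a list with `direction` (`"A"`/`"B"`, the high group),
#'   `threshold` and `margin`.
#' @export
complete_separation <- function(x_a, x_b) {
  if (!length(x_a) || !length(x_b)) stop("both groups must be non-empty")
  if (max(x_a) < min(x_b)) {
    lo <- max(x_a); hi <- min(x_b); dir <- "B"
  } else if (max(x_b) < min(x_a)) {
    lo <- max(x_b); hi <- min(x_a); dir <- "A"
  } else return(NULL)
  thr <- if (lo == 0) (lo + hi) / 2 else sqrt(lo * hi)
  margin <- if (lo == 0) Inf else log2(hi / lo)
  list(direction = dir, threshold = thr, margin = margin)
}

#' Differential screen between two sample groups
#'
#' Runs the full candidate-marker screen between two subtype (or supertype)
#' groups: common-dispersion estimation, per-region NB exact tests on
#' library-size-equalised counts, BH adjustment, threshold filtering, and a
#' complete-separation scan over the candidate regions. Positive `log2fc`
#' means higher expression in `group2`.
#'
#' @param m a [cage_counts] object (typically QC'd and inactivity-filtered).
#' @param samples sample table.
#' @param group1,group2 subtype or supertype labels naming the two groups.
#' @param thresholds a [screen_thresholds()] list.
#' @param min_sep_margin minimum log2 margin for a reported separator.
#' @return data.frame of class `de_result` with one row per region:
#'   `region_id`, `mean_cpm`, `log2fc`, `pvalue`, `fdr`, `candidate`,
#'   `separator`, `sep_margin`, `sep_threshold`, `high_group`; dispersion in
#'   attribute `"dispersion"`.
#' @export
de_screen <- function(m, samples, group1 = "non_lepidic_AD",
                      group2 = "PDSCC", thresholds = screen_thresholds(),
                      min_sep_margin = 0) {
  stopifnot(inherits(m, "cage_counts"))
  pick <- function(g) samples$sample_id[samples$subtype == g |
                                          samples$supertype == g]
  ids1 <- intersect(pick(group1), colnames(m$counts))
  ids2 <- intersect(pick(group2), colnames(m$counts))
  if (length(ids1) < 2 || length(ids2) < 2)
    stop("each group needs at least 2 samples present in the matrix")
  sub <- m$counts[, c(ids1, ids2), drop = FALSE]
  lib <- m$lib_sizes[c(ids1, ids2)]
  grp <- rep(c("g1", "g2"), c(length(ids1), length(ids2)))
  phi <- estimate_common_dispersion(sub, grp, lib)

  sc <- equalize_libsizes(sub, lib)
  na <- length(ids1); nb <- length(ids2)
  pv <- vapply(seq_len(nrow(sc)), function(r)
    nb_exact_pvalue(sum(sc[r, seq_len(na)]), sum(sc[r, na + seq_len(nb)]),
                    na, nb, phi), numeric(1))

  cpm_sub <- sweep(sub, 2, lib, "/") * 1e6
  m1 <- rowMeans(cpm_sub[, seq_len(na), drop = FALSE])
  m2 <- rowMeans(cpm_sub[, na + seq_len(nb), drop = FALSE])
  # prior of 0.5 reads at the mean library size stabilises the fold change
  prior <- 0.5e6 / exp(mean(log(lib)))
  res <- data.frame(region_id = rownames(sub),
                    mean_cpm = rowMeans(cpm_sub),
                    log2fc = log2((m2 + prior) / (m1 + prior)),
                    pvalue = pv, fdr = bh_adjust(pv),
                    stringsAsFactors = FALSE)
  cand <- candidate_filter(res, thresholds)
  res$candidate <- res$region_id %in% c(cand$up_group1$region_id,
                                        cand$up_group2$region_id)
  res$separator <- FALSE
  res$sep_margin <- NA_real_
  res$sep_threshold <- NA_real_
  res$high_group <- NA_character_
  for (r in which(res$candidate)) {
    sep <- complete_separation(cpm_sub[r, seq_len(na)],
                               cpm_sub[r, na + seq_len(nb)])
    if (!is.null(sep) && sep$margin >= min_sep_margin) {
      res$separator[r] <- TRUE
      res$sep_margin[r] <- sep$margin
      res$sep_threshold[r] <- sep$threshold
      res$high_group[r] <- if (sep$direction == "A") group1 else group2
    }
  }
  attr(res, "dispersion") <- phi
  attr(res, "groups") <- c(group1 = group1, group2 = group2)
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  g <- attr(x, "groups")
  if (is.null(g)) return(NextMethod())  # subsets print as plain tables
  cat(sprintf("differential screen: %s vs %s (log2fc > 0 = higher in %s)\n",
              g[1], g[2], g[2]))
  cat(sprintf("common dispersion: %.4f\n", attr(x, "dispersion")))
  cat(sprintf("%d regions tested; %d candidates (%d up in %s, %d up in %s); %d complete separators\n",
              nrow(x), sum(x$candidate),
              sum(x$candidate & x$log2fc < 0), g[1],
              sum(x$candidate & x$log2fc > 0), g[2],
              sum(x$separator)))
  invisible(x)
}
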
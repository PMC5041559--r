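#' Configuration for a synthetic CAGE cohort
#'
#' Defaults mirror the discovery cohort used for marker exploration:
#' 97 tumours — 5 WDSCC, 14 MDSCC, 3 PDSCC, 7 pure-lepidic AD, 56
#' mixed-lepidic AD, 12 non-lepidic AD. Counts follow a negative binomial
#' with common dispersion `phi` (variance mu + phi * mu^2); library sizes
#' are log-normal. Fold-change regions and completely separating regions
#' are planted between the two hard-to-diagnose groups, PDSCC and
#' non-lepidic AD.
#'
#' @param n_regions number of promoter regions.
#' @param group_sizes named integer vector, subtype label -> sample count.
#' @param baseline_mean_log_range range (natural log) of the unnormalised
#'   baseline expression drawn per region; relative abundances are these
#'   values normalised to sum to one.
#' @param dispersion NB dispersion phi >= 0 (phi = 0 gives Poisson counts).
#' @param libsize_log_sd standard deviation of log library size.
#' @param libsize_mean mean library size (mapped reads) on the natural scale.
#' @param n_de number of planted fold-change regions.
#' @param de_log2fc planted log2 fold change (PDSCC relative to
#'   non-lepidic AD; positive means higher in PDSCC).
#' @param n_separators number of planted completely separating regions.
#' @param separator_log2fc log2 shift applied to the high group of a planted
#'   separator.
#' @param separator_margin required realised log2 gap between the groups'
#'   CPM ranges; regions violating it are resampled (bounded retries).
#' @param seed integer seed; all randomness flows from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_regions = 2000,
                          group_sizes = c(WDSCC = 5, MDSCC = 14, PDSCC = 3,
                                          pure_lepidic_AD = 7,
                                          mixed_lepidic_AD = 56,
                                          non_lepidic_AD = 12),
                          baseline_mean_log_range = c(0, log(1000)),
                          dispersion = 0.1,
                          libsize_log_sd = 0.3,
                          libsize_mean = 4e6,
                          n_de = 0, de_log2fc = 3,
                          n_separators = 0, separator_log2fc = 6,
                          separator_margin = 1,
                          seed = 1L) {
  if (n_regions < 1) stop("n_regions must be positive")
  if (!length(group_sizes)) stop("group_sizes must be non-empty")
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% names(SUBTYPE_SUPERTYPE)))
    stop("group_sizes must be named by subtype label")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (libsize_log_sd < 0) stop("libsize_log_sd must be >= 0")
  if (n_de + n_separators > n_regions)
    stop("n_de + n_separators must not exceed n_regions")
  structure(list(n_regions = as.integer(n_regions),
                 group_sizes = group_sizes,
                 baseline_mean_log_range = baseline_mean_log_range,
                 dispersion = dispersion,
                 libsize_log_sd = libsize_log_sd,
                 libsize_mean = libsize_mean,
                 n_de = as.integer(n_de), de_log2fc = de_log2fc,
                 n_separators = as.integer(n_separators),
                 separator_log2fc = separator_log2fc,
                 separator_margin = separator_margin,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

rnbinom_disp <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a CAGE-like tumour cohort with known ground truth
#'
#' Draws a regions x samples count matrix: counts are NB with mean
#' `lib_size_i * rel_abundance_r * fc_term` and common dispersion. Planted
#' fold-change regions have expected CPM fold change `2^de_log2fc` between
#' PDSCC and non-lepidic AD; planted separator regions are shifted until
#' the two groups' realised CPM ranges are disjoint by at least
#' `separator_margin` on the log2 scale (complete separation is a property
#' of the realised data, so it is verified post hoc and violating regions
#' are redrawn, at most 25 times).
#'
#' @param config a [cohort_config].
#' @return list of class `cage_cohort` with elements `counts`
#'   ([cage_counts]), `samples` (sample table), `truth` (data.frame of
#'   planted regions: region_id, role, log2fc, high_group) and
#'   `rel_abundance` (the configured per-region relative abundances; the
#'   expected baseline CPM of a region is `rel_abundance * 1e6`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  gs <- config$group_sizes[config$group_sizes > 0]
  samples <- sample_table(
    sprintf("S%03d", seq_len(sum(gs))),
    rep(names(gs), gs))
  n <- config$n_regions
  m <- nrow(samples)
  lib <- round(exp(stats::rnorm(m, log(config$libsize_mean),
                                config$libsize_log_sd)))
  names(lib) <- samples$sample_id

  raw <- exp(stats::runif(n, config$baseline_mean_log_range[1],
                          config$baseline_mean_log_range[2]))
  rel <- raw / sum(raw)
  region_id <- sprintf("region_%05d", seq_len(n))
  start <- sample.int(1e8, n)
  regions <- data.frame(
    chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
    start = start,
    end = start + sample(200:1200, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    region_id = region_id, stringsAsFactors = FALSE)

  pd <- samples$subtype == "PDSCC"
  nl <- samples$subtype == "non_lepidic_AD"
  planted <- if (config$n_de + config$n_separators > 0)
    sample.int(n, config$n_de + config$n_separators) else integer()
  de_idx <- utils::head(planted, config$n_de)
  sep_idx <- utils::tail(planted, config$n_separators)

  # per-region, per-sample mean multiplier relative to baseline
  fc <- matrix(1, n, m)
  if (length(de_idx)) fc[de_idx, pd] <- 2^config$de_log2fc
  sep_dir <- rep(c("PDSCC", "non_lepidic_AD"), length.out = length(sep_idx))
  for (k in seq_along(sep_idx)) {
    hi <- if (sep_dir[k] == "PDSCC") pd else nl
    fc[sep_idx[k], hi] <- 2^config$separator_log2fc
  }

  mu <- (rel %o% lib) * fc
  counts <- matrix(rnbinom_disp(length(mu), mu, config$dispersion), n, m,
                   dimnames = list(region_id, samples$sample_id))

  # verify planted separators on realised CPM; redraw violating regions
  for (k in seq_along(sep_idx)) {
    r <- sep_idx[k]
    hi <- if (sep_dir[k] == "PDSCC") pd else nl
    lo <- if (sep_dir[k] == "PDSCC") nl else pd
    for (try in seq_len(25)) {
      cpm_r <- counts[r, ] * 1e6 / lib
      gap_ok <- min(cpm_r[hi]) > 0 &&
        (max(cpm_r[lo]) == 0 ||
           log2(min(cpm_r[hi]) / max(cpm_r[lo])) >= config$separator_margin)
      if (gap_ok) break
      counts[r, hi | lo] <- rnbinom_disp(sum(hi | lo), mu[r, hi | lo],
                                         config$dispersion)
      if (try == 25)
        stop("could not realise planted separator ", region_id[r],
             " within 25 redraws; widen separator_log2fc")
    }
  }

  truth <- rbind(
    if (length(de_idx)) data.frame(region_id = region_id[de_idx], role = "de",
                                   log2fc = config$de_log2fc,
                                   high_group = if (config$de_log2fc >= 0)
                                     "PDSCC" else "non_lepidic_AD",
                                   stringsAsFactors = FALSE),
    if (length(sep_idx)) data.frame(region_id = region_id[sep_idx],
                                    role = "separator",
                                    log2fc = config$separator_log2fc,
                                    high_group = sep_dir,
                                    stringsAsFactors = FALSE))
  if (is.null(truth))
    truth <- data.frame(region_id = character(), role = character(),
                        log2fc = numeric(), high_group = character(),
                        stringsAsFactors = FALSE)

  rel_abundance <- stats::setNames(rel, region_id)
  structure(list(counts = cage_counts(counts, regions, lib),
                 samples = samples, truth = truth,
                 rel_abundance = rel_abundance, config = config),
            class = "cage_cohort")
}

#' @export
print.cage_cohort <- function(x, ...) {
  cat(sprintf("cage_cohort: %d regions x %d samples (%s)\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              paste(sprintf("%s=%d", names(table(x$samples$subtype)),
                            as.integer(table(x$samples$subtype))),
                    collapse = ", ")))
  cat(sprintf("planted: %d fold-change, %d separator regions\n",
              sum(x$truth$role == "de"), sum(x$truth$role == "separator")))
  invisible(x)
}

#' Marker definitions for IHC simulation
#'
#' @param name marker name.
#' @param marker_class `"AD"` or `"SCC"` (which supertype the marker is
#'   positive in).
#' @param scheme `"novel"` or `"established"` scoring scheme.
#' @param sensitivity P(score 2 | condition-positive sample).
#' @param specificity 1 - P(score 2 | condition-negative sample).
#' @param score1_fraction among sub-threshold (non-positive) outcomes, the
#'   fraction assigned score 1 rather than 0.
#' @return one-row data.frame; rbind rows to form a panel.
#' @export
ihc_marker <- function(name, marker_class, scheme = "novel",
                       sensitivity = 0.9, specificity = 0.95,
                       score1_fraction = 0.3) {
  stopifnot(marker_class %in% c("AD", "SCC"),
            scheme %in% c("novel", "established"))
  probs <- c(sensitivity, specificity, score1_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  data.frame(name = name, marker_class = marker_class, scheme = scheme,
             sensitivity = sensitivity, specificity = specificity,
             score1_fraction = score1_fraction, stringsAsFactors = FALSE)
}

#' Default simulated marker panel (2 AD + 2 SCC markers per scheme style)
#' @export
default_marker_panel <- function() {
  rbind(
    ihc_marker("ST6GALNAC1", "AD", "novel", 0.90, 0.98),
    ihc_marker("TTF-1", "AD", "established", 0.65, 0.99),
    ihc_marker("napsinA", "AD", "established", 0.70, 0.97),
    ihc_marker("SPATS2", "SCC", "novel", 0.70, 0.98),
    ihc_marker("CK5", "SCC", "established", 0.60, 0.99),
    ihc_marker("p40", "SCC", "established", 0.60, 0.98)
  )
}

#' Simulate an IHC score table for a sample cohort
#'
#' For an AD marker with sensitivity s and specificity p,
#' P(score 2 | AD) = s and P(score 2 | SCC) = 1 - p; SCC markers are
#' symmetric. Sub-threshold outcomes are split between scores 1 and 0 by
#' `score1_fraction`.
#'
#' @param markers data.frame of [ihc_marker()] rows with unique names.
#' @param samples sample table from [sample_table()].
#' @param seed integer seed.
#' @return an [ihc_table] (samples x markers scores in 0/1/2 with marker
#'   metadata attached).
#' @export
simulate_ihc <- function(markers, samples, seed = 1L) {
  if (anyDuplicated(markers$name)) stop("marker names must be unique")
  bad <- setdiff(unique(samples$subtype), names(SUBTYPE_SUPERTYPE))
  if (length(bad)) stop("unknown subtype label(s): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  n <- nrow(samples)
  scores <- matrix(0L, n, nrow(markers),
                   dimnames = list(samples$sample_id, markers$name))
  for (j in seq_len(nrow(markers))) {
    mk <- markers[j, ]
    pos <- samples$supertype == mk$marker_class
    p2 <- ifelse(pos, mk$sensitivity, 1 - mk$specificity)
    u <- stats::runif(n)
    s <- ifelse(u < p2, 2L,
                ifelse(stats::runif(n) < mk$score1_fraction, 1L, 0L))
    scores[, j] <- s
  }
  ihc_table(scores, markers[, c("name", "marker_class", "scheme")], samples)
}
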
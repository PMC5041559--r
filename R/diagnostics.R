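#' 2x2 confusion table for a binary marker call
#'
#' Tallies marker calls against the condition defined by the marker class:
#' for an AD marker the condition-positive class is AD, for an SCC marker
#' it is SCC. Cells: `a` condition-positive called positive, `b`
#' condition-negative called positive, `c` condition-positive called
#' negative, `d` condition-negative called negative.
#'
#' @param calls logical vector of marker calls named by sample id (or a
#'   samples x markers call matrix plus `marker` naming the column).
#' @param samples sample table with supertype labels.
#' @param marker_class `"AD"` or `"SCC"`.
#' @param marker column name when `calls` is a matrix.
#' @param restrict optional character vector of subtype labels; only
#'   samples of these subtypes are tallied (e.g. the hard-to-diagnose
#'   `c("non_lepidic_AD", "PDSCC")` cohort).
#' @return object of class `confusion_table` with fields a, b, c, d.
#' @export
confusion <- function(calls, samples, marker_class, marker = NULL,
                      restrict = NULL) {
  stopifnot(marker_class %in% c("AD", "SCC"))
  if (is.matrix(calls)) {
    if (is.null(marker)) stop("marker column required for a call matrix")
    calls <- calls[, marker]
  }
  if (!is.null(restrict))
    samples <- samples[samples$subtype %in% restrict, , drop = FALSE]
  if (!nrow(samples)) stop("empty cohort after restriction")
  if (!all(samples$sample_id %in% names(calls)))
    stop("every sample in the cohort needs a call")
  calls <- calls[samples$sample_id]
  cond <- samples$supertype == marker_class
  structure(list(a = sum(cond & calls), b = sum(!cond & calls),
                 c = sum(cond & !calls), d = sum(!cond & !calls),
                 marker_class = marker_class),
            class = "confusion_table")
}

#' Construct a confusion table directly from its four counts
#' @param a,b,c,d non-negative integer cell counts (see [confusion()]).
#' @export
confusion_table <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("confusion table must have a positive total")
  structure(list(a = a, b = b, c = c, d = d, marker_class = NA_character_),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(call = c("+", "-"),
                              condition = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Exact Clopper-Pearson confidence interval for a binomial proportion
#'
#' Inverts the binomial tails: the lower bound is the Beta(x, n - x + 1)
#' lower quantile (0 when x = 0) and the upper bound the Beta(x + 1, n - x)
#' upper quantile (1 when x = n), at level `conf`.
#'
#' @param x number of successes (vectorised).
#' @param n number of trials, `n >= 1`.
#' @param conf confidence level in (0, 1). Default 0.95.
#' @return matrix with columns `low`, `high`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (conf <= 0 || conf >= 1) stop("conf must be in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n")
  k <- max(length(x), length(n))
  x <- rep_len(x, k); n <- rep_len(n, k)
  alpha <- 1 - conf
  low <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  high <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  cbind(low = low, high = high)
}

#' Diagnostic performance of a marker from its confusion table
#'
#' Sensitivity a/(a+c), specificity d/(b+d), PPV a/(a+b), NPV d/(c+d) and
#' accuracy (a+d)/total, each with its own exact Clopper-Pearson interval
#' on its own numerator/denominator. A metric whose denominator is zero is
#' undefined (rendered "N.A.").
#'
#' @param t a [confusion_table].
#' @param conf confidence level. Default 0.95.
#' @return data.frame of class `diagnostic_performance` with columns
#'   `metric`, `numerator`, `denominator`, `estimate`, `ci_low`, `ci_high`
#'   (NA where undefined).
#' @export
performance <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "confusion_table"))
  total <- t$a + t$b + t$c + t$d
  if (total == 0) stop("confusion table total must be positive")
  num <- c(sensitivity = t$a, specificity = t$d, ppv = t$a, npv = t$d,
           accuracy = t$a + t$d)
  den <- c(sensitivity = t$a + t$c, specificity = t$b + t$d,
           ppv = t$a + t$b, npv = t$c + t$d, accuracy = total)
  res <- data.frame(metric = names(num), numerator = unname(num),
                    denominator = unname(den),
                    estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, stringsAsFactors = FALSE)
  ok <- res$denominator > 0
  res$estimate[ok] <- res$numerator[ok] / res$denominator[ok]
  ci <- clopper_pearson(res$numerator[ok], res$denominator[ok], conf)
  res$ci_low[ok] <- ci[, "low"]
  res$ci_high[ok] <- ci[, "high"]
  class(res) <- c("diagnostic_performance", "data.frame")
  res
}

# round half up, as printed in the result tables
round_half_up <- function(x, digits = 3) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format diagnostic performance as a publication-style table row
#'
#' Values are rounded half-up to three decimals; undefined metrics are
#' printed "N.A.".
#'
#' @param p a `diagnostic_performance` data.frame.
#' @return named character vector `metric = "est (low-high)"`.
#' @export
format_performance <- function(p) {
  out <- vapply(seq_len(nrow(p)), function(i) {
    if (is.na(p$estimate[i])) return("N.A.")
    sprintf("%.3f (%.3f-%.3f)", round_half_up(p$estimate[i]),
            round_half_up(p$ci_low[i]), round_half_up(p$ci_high[i]))
  }, character(1))
  names(out) <- p$metric
  out
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  fm <- format_performance(x)
  for (i in seq_along(fm))
    cat(sprintf("%-12s %s\n", names(fm)[i], fm[i]))
  invisible(x)
}

#' Evaluate every marker of an IHC table against the histological diagnosis
#'
#' Binarizes the table and computes per-marker confusion tables and
#' diagnostic performance (optionally on a subtype-restricted cohort, as in
#' the published discovery-set evaluation of 12 non-lepidic AD and 3 PDSCC
#' tumours).
#'
#' @param table an [ihc_table].
#' @param restrict optional subtype labels to restrict the cohort.
#' @param conf confidence level.
#' @return data.frame with one row per marker x metric: marker, class, a,
#'   b, c, d, metric, numerator, denominator, estimate, ci_low, ci_high,
#'   formatted.
#' @export
evaluate_markers <- function(table, restrict = NULL, conf = 0.95) {
  calls <- binarize(table)
  out <- lapply(seq_len(nrow(table$markers)), function(j) {
    mk <- table$markers[j, ]
    ct <- confusion(calls[, mk$name], table$samples, mk$marker_class,
                    restrict = restrict)
    perf <- performance(ct, conf)
    data.frame(marker = mk$name, marker_class = mk$marker_class,
               a = ct$a, b = ct$b, c = ct$c, d = ct$d, perf,
               formatted = unname(format_performance(perf)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
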
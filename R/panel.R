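#' Two-marker definitive-diagnosis rule
#'
#' Pairs one AD marker with one SCC marker. A sample positive for the AD
#' marker and negative for the SCC marker is diagnosed AD; the mirror
#' pattern is diagnosed SCC; double-positive and double-negative patterns
#' are inconclusive.
#'
#' @param ad_marker,scc_marker marker names.
#' @export
panel_rule <- function(ad_marker, scc_marker) {
  structure(list(ad_marker = ad_marker, scc_marker = scc_marker),
            class = "panel_rule")
}

#' @export
print.panel_rule <- function(x, ...) {
  cat(sprintf("panel rule: %s (AD) + %s (SCC)\n", x$ad_marker, x$scc_marker))
  invisible(x)
}

#' Apply a two-marker rule to binary marker calls
#'
#' @param rule a [panel_rule].
#' @param calls logical samples x markers call matrix (from [binarize()]).
#' @return character vector per sample: `"AD"`, `"SCC"` or
#'   `"inconclusive"`, named by sample id.
#' @export
apply_rule <- function(rule, calls) {
  for (mk in c(rule$ad_marker, rule$scc_marker))
    if (!mk %in% colnames(calls)) stop("missing call for marker ", mk)
  ad <- calls[, rule$ad_marker]
  sc <- calls[, rule$scc_marker]
  if (anyNA(ad) || anyNA(sc)) stop("missing call for some sample")
  out <- rep("inconclusive", nrow(calls))
  out[ad & !sc] <- "AD"
  out[sc & !ad] <- "SCC"
  names(out) <- rownames(calls)
  out
}

#' Evaluate a two-marker rule against the histological diagnosis
#'
#' Accuracy counts inconclusive samples in the denominator and never as
#' correct, matching the definitive-diagnosis arithmetic (e.g. 67 correct
#' of 74 with 7 inconclusive gives accuracy 0.905 and inconclusive rate
#' 0.095).
#'
#' @param rule a [panel_rule].
#' @param calls logical call matrix.
#' @param labels character vector of supertypes (`AD`/`SCC`) aligned to the
#'   rows of `calls`, or a sample table.
#' @return object of class `panel_outcome`: classification, n_correct,
#'   n_incorrect, n_inconclusive, accuracy, inconclusive_rate.
#' @export
evaluate_rule <- function(rule, calls, labels) {
  if (is.data.frame(labels))
    labels <- labels$supertype[match(rownames(calls), labels$sample_id)]
  stopifnot(length(labels) == nrow(calls), all(labels %in% c("AD", "SCC")))
  cls <- apply_rule(rule, calls)
  n <- length(cls)
  n_inc <- sum(cls == "inconclusive")
  n_cor <- sum(cls == labels)
  structure(list(rule = rule, classification = cls,
                 n_correct = n_cor,
                 n_incorrect = n - n_cor - n_inc,
                 n_inconclusive = n_inc,
                 accuracy = n_cor / n,
                 inconclusive_rate = n_inc / n),
            class = "panel_outcome")
}

#' @export
print.panel_outcome <- function(x, ...) {
  print(x$rule)
  n <- length(x$classification)
  cat(sprintf("%d/%d correct (accuracy %.3f), %d incorrect, %d inconclusive (rate %.3f)\n",
              x$n_correct, n, x$accuracy, x$n_incorrect,
              x$n_inconclusive, x$inconclusive_rate))
  invisible(x)
}

#' Exhaustive search over all AD x SCC two-marker panels
#'
#' Evaluates every pair of one AD marker and one SCC marker and ranks the
#' rules by accuracy (descending), then fewer inconclusive samples, then
#' lexicographic pair name.
#'
#' @param markers data.frame with columns `name` and `marker_class`.
#' @param calls logical call matrix.
#' @param labels supertype labels or sample table (see [evaluate_rule()]).
#' @return data.frame: ad_marker, scc_marker, n_correct, n_incorrect,
#'   n_inconclusive, accuracy, inconclusive_rate, rank.
#' @export
exhaustive_search <- function(markers, calls, labels) {
  ad <- markers$name[markers$marker_class == "AD"]
  sc <- markers$name[markers$marker_class == "SCC"]
  if (!length(ad) || !length(sc))
    stop("need at least one AD marker and one SCC marker")
  grid <- expand.grid(ad_marker = ad, scc_marker = sc,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    o <- evaluate_rule(panel_rule(grid$ad_marker[i], grid$scc_marker[i]),
                       calls, labels)
    data.frame(ad_marker = grid$ad_marker[i], scc_marker = grid$scc_marker[i],
               n_correct = o$n_correct, n_incorrect = o$n_incorrect,
               n_inconclusive = o$n_inconclusive, accuracy = o$accuracy,
               inconclusive_rate = o$inconclusive_rate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  ord <- order(-res$accuracy, res$n_inconclusive, res$ad_marker,
               res$scc_marker)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Sequential two-step definitive-diagnosis panel
#'
#' Applies `first`; samples it leaves inconclusive are re-examined with
#' `second` (mirroring the proposed workflow: ST6GALNAC1 + CK5 first, then
#' TTF-1 + SPATS2 on the residual inconclusive cases). Overall accuracy
#' counts residual inconclusive samples as not correct; the second-stage
#' accuracy among stage-1-inconclusive samples is reported separately.
#'
#' @param first,second [panel_rule]s.
#' @param calls logical call matrix.
#' @param labels supertype labels or sample table.
#' @return list of class `sequential_outcome`: classification, stage
#'   assignments, overall counts/accuracy, and `stage2` (a [panel_outcome]
#'   restricted to the stage-1 inconclusive samples, or NULL if none).
#' @export
sequential_panel <- function(first, second, calls, labels) {
  if (is.data.frame(labels))
    labels <- labels$supertype[match(rownames(calls), labels$sample_id)]
  o1 <- evaluate_rule(first, calls, labels)
  cls <- o1$classification
  stage <- ifelse(cls == "inconclusive", 2L, 1L)
  resid <- which(cls == "inconclusive")
  stage2 <- NULL
  if (length(resid)) {
    stage2 <- evaluate_rule(second, calls[resid, , drop = FALSE],
                            labels[resid])
    cls[resid] <- stage2$classification
  }
  n <- length(cls)
  n_inc <- sum(cls == "inconclusive")
  n_cor <- sum(cls == labels)
  structure(list(first = first, second = second, classification = cls,
                 stage = stage, n_correct = n_cor,
                 n_incorrect = n - n_cor - n_inc, n_inconclusive = n_inc,
                 accuracy = n_cor / n, inconclusive_rate = n_inc / n,
                 stage1 = o1, stage2 = stage2),
            class = "sequential_outcome")
}

#' @export
print.sequential_outcome <- function(x, ...) {
  cat("sequential panel\n")
  cat(sprintf("  stage 1 rule %s+%s, stage 2 rule %s+%s\n",
              x$first$ad_marker, x$first$scc_marker,
              x$second$ad_marker, x$second$scc_marker))
  n <- length(x$classification)
  cat(sprintf("  overall: %d/%d correct (accuracy %.3f), %d residual inconclusive\n",
              x$n_correct, n, x$accuracy, x$n_inconclusive))
  if (!is.null(x$stage2))
    cat(sprintf("  stage 2 on %d stage-1 inconclusive: accuracy %.3f\n",
                length(x$stage2$classification), x$stage2$accuracy))
  invisible(x)
}
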
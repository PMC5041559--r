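#' IHC score table
#'
#' Samples x markers ordinal immunostaining scores in {0, 1, 2}, with marker
#' metadata (class AD/SCC, scoring scheme) and the sample table attached.
#' Score 2 is the positive call under both scoring schemes.
#'
#' @param scores integer matrix, samples x markers, values in {0, 1, 2},
#'   with sample ids as rownames and marker names as colnames.
#' @param markers data.frame with columns `name`, `marker_class`
#'   (`AD`/`SCC`), `scheme` (`novel`/`established`).
#' @param samples sample table as from [sample_table()].
#' @return object of class `ihc_table`.
#' @export
ihc_table <- function(scores, markers, samples) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (!all(scores %in% 0:2)) stop("IHC scores must be in {0, 1, 2}")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores must carry sample ids (rownames) and marker names (colnames)")
  if (anyDuplicated(markers$name)) stop("marker names must be unique")
  if (!setequal(colnames(scores), markers$name))
    stop("marker metadata does not match score columns")
  if (!all(rownames(scores) %in% samples$sample_id))
    stop("every scored sample needs a subtype label")
  if (!all(markers$marker_class %in% c("AD", "SCC")))
    stop("marker_class must be AD or SCC")
  markers <- markers[match(colnames(scores), markers$name), , drop = FALSE]
  samples <- samples[match(rownames(scores), samples$sample_id), , drop = FALSE]
  structure(list(scores = scores, markers = markers, samples = samples),
            class = "ihc_table")
}

#' @export
print.ihc_table <- function(x, ...) {
  cat(sprintf("ihc_table: %d samples x %d markers (%d AD, %d SCC)\n",
              nrow(x$scores), ncol(x$scores),
              sum(x$markers$marker_class == "AD"),
              sum(x$markers$marker_class == "SCC")))
  invisible(x)
}

#' Binarize IHC scores into marker calls
#'
#' Scores 0 and 1 are negative; score 2 is positive.
#'
#' @param table an [ihc_table] or a score matrix with values in {0, 1, 2}.
#' @return logical samples x markers call matrix.
#' @export
binarize <- function(table) {
  scores <- if (inherits(table, "ihc_table")) table$scores else as.matrix(table)
  if (!all(scores %in% 0:2)) stop("IHC scores must be in {0, 1, 2}")
  scores == 2
}

#' Convert a stained-cell percentage and intensity to an IHC score
#'
#' Novel-marker scheme: score 0 iff no tumour cells stain; score 2 iff more
#' than 50 % of tumour cells show moderate or stronger immunoreactivity
#' (strict); otherwise score 1. Established-marker scheme: score 0 iff no
#' cells stain; score 2 iff 10 % or more stain (inclusive); otherwise 1.
#'
#' @param percent_positive percentage of tumour cells staining, in [0, 100].
#' @param intensity one of `"none"`, `"weak"`, `"moderate-or-stronger"`.
#' @param scheme `"novel"` or `"established"`.
#' @return integer score 0, 1 or 2. Vectorised over `percent_positive` and
#'   `intensity`.
#' @export
percent_to_score <- function(percent_positive,
                             intensity = c("none", "weak",
                                           "moderate-or-stronger"),
                             scheme = c("novel", "established")) {
  scheme <- match.arg(scheme)
  intensity <- match.arg(intensity, several.ok = TRUE)
  if (any(percent_positive < 0 | percent_positive > 100))
    stop("percent_positive must be in [0, 100]")
  n <- length(percent_positive)
  intensity <- rep_len(intensity, n)
  score <- rep.int(1L, n)
  score[percent_positive == 0] <- 0L
  if (scheme == "novel") {
    score[percent_positive > 50 & intensity == "moderate-or-stronger"] <- 2L
  } else {
    score[percent_positive >= 10] <- 2L
  }
  score
}

#' Read/write IHC score tables
#'
#' Score TSV: first column `sample_id`, remaining columns one per marker.
#' Marker metadata TSV: columns `name`, `marker_class`, `scheme`.
#'
#' @param score_path,marker_path,sample_path TSV paths.
#' @return an [ihc_table].
#' @export
read_ihc_table <- function(score_path, marker_path, sample_path) {
  sc <- utils::read.table(score_path, sep = "\t", header = TRUE,
                          row.names = 1, check.names = FALSE)
  mk <- utils::read.table(marker_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ihc_table(as.matrix(sc), mk, read_sample_table(sample_path))
}

#' @rdname read_ihc_table
#' @param table an [ihc_table].
#' @param dir output directory.
#' @export
write_ihc_table <- function(table, dir) {
  utils::write.table(data.frame(sample_id = rownames(table$scores),
                                table$scores, check.names = FALSE),
                     file.path(dir, "ihc_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$markers, file.path(dir, "ihc_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
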
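#' Promoter count matrix with region annotation and library sizes
#'
#' Bundles a regions x samples matrix of non-negative integer CAGE tag
#' counts with its promoter-region annotation (BED-like) and per-sample
#' library sizes. Library sizes default to column sums but may exceed them:
#' the library size is the total number of mapped reads, not only those
#' starting inside the annotated TSS regions.
#'
#' @param counts integer matrix, regions x samples, with rownames (region
#'   ids) and colnames (sample ids).
#' @param regions data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `region_id` (0-based half-open coordinates). Defaults to a minimal
#'   annotation synthesised from the rownames.
#' @param lib_sizes numeric vector of per-sample total mapped reads; column
#'   sums when `NULL`.
#' @return An object of class `cage_counts`: a list with elements `counts`,
#'   `regions`, `lib_sizes`.
#' @export
cage_counts <- function(counts, regions = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have region ids as rownames and sample ids as colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(regions)) {
    regions <- data.frame(
      chrom = "chrUn", start = 0L, end = 1L, strand = "+",
      region_id = rownames(counts), stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(regions$region_id))
    stop("region ids must be unique")
  if (any(regions$start >= regions$end))
    stop("regions must satisfy start < end (0-based half-open)")
  if (!setequal(regions$region_id, rownames(counts)))
    stop("region annotation does not match count matrix rownames")
  regions <- regions[match(rownames(counts), regions$region_id), , drop = FALSE]
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- as.numeric(lib_sizes)
  if (length(lib_sizes) != ncol(counts))
    stop("lib_sizes length must equal the number of samples")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  names(lib_sizes) <- colnames(counts)
  structure(list(counts = counts, regions = regions, lib_sizes = lib_sizes),
            class = "cage_counts")
}

#' @export
print.cage_counts <- function(x, ...) {
  cat(sprintf("cage_counts: %d regions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("library sizes: %s .. %s mapped reads\n",
              format(min(x$lib_sizes), big.mark = ","),
              format(max(x$lib_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.cage_counts <- function(x) dim(x$counts)

#' Build a sample table with subtype and derived supertype labels
#'
#' The histological subtypes follow the two-supertype scheme used for
#' non-small cell lung cancer: three SCC grades (well, moderately, poorly
#' differentiated) and three AD grades defined by the lepidic growth
#' component.
#'
#' @param sample_id character vector of sample ids.
#' @param subtype character vector; one of `WDSCC`, `MDSCC`, `PDSCC`,
#'   `pure_lepidic_AD`, `mixed_lepidic_AD`, `non_lepidic_AD`.
#' @return data.frame with columns `sample_id`, `subtype`, `supertype`.
#' @export
sample_table <- function(sample_id, subtype) {
  if (length(sample_id) != length(subtype))
    stop("sample_id and subtype must have equal length")
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  st <- as.character(subtype)
  bad <- setdiff(unique(st), names(SUBTYPE_SUPERTYPE))
  if (length(bad))
    stop("unknown subtype label(s): ", paste(bad, collapse = ", "))
  data.frame(sample_id = as.character(sample_id), subtype = st,
             supertype = unname(SUBTYPE_SUPERTYPE[st]),
             stringsAsFactors = FALSE)
}

SUBTYPE_SUPERTYPE <- c(
  WDSCC = "SCC", MDSCC = "SCC", PDSCC = "SCC",
  pure_lepidic_AD = "AD", mixed_lepidic_AD = "AD", non_lepidic_AD = "AD"
)

#' Drop low-depth libraries
#'
#' Retains only samples whose library size strictly exceeds `min_mapped`
#' mapped reads (default two million). Removed sample ids are reported via
#' `message()`.
#'
#' @param m a [cage_counts] object.
#' @param min_mapped minimum mapped-read count; retention requires
#'   `lib_size > min_mapped` (strict).
#' @return a [cage_counts] restricted to the retained samples.
#' @export
qc_libraries <- function(m, min_mapped = 2e6) {
  stopifnot(inherits(m, "cage_counts"))
  keep <- m$lib_sizes > min_mapped
  if (!any(keep))
    stop(sprintf("all samples removed: no library exceeds %g mapped reads",
                 min_mapped))
  if (any(!keep))
    message("qc_libraries: removed ",
            paste(colnames(m$counts)[!keep], collapse = ", "))
  cage_counts(m$counts[, keep, drop = FALSE], m$regions, m$lib_sizes[keep])
}

#' Counts per million
#'
#' CPM normalisation without pseudocount: `count * 1e6 / lib_size`, using
#' the stored library sizes (total mapped reads).
#'
#' @param m a [cage_counts] object.
#' @return numeric matrix with the same dimnames as the counts.
#' @export
cpm <- function(m) {
  stopifnot(inherits(m, "cage_counts"))
  if (any(m$lib_sizes <= 0)) stop("zero or negative library size")
  sweep(m$counts, 2, m$lib_sizes, "/") * 1e6
}

#' Filter inactive promoter regions
#'
#' A region is removed iff it is inactive in *both* supertype groups: within
#' each group, the fraction of samples with CPM at or below `cpm_threshold`
#' strictly exceeds `frac`. With `pooled = TRUE` the rule is instead applied
#' once over the union of the two groups.
#'
#' @param cpm_mat CPM matrix (regions x samples).
#' @param samples sample table as from [sample_table()].
#' @param cpm_threshold inactivity CPM cut (inclusive: CPM <= threshold
#'   counts as inactive). Default 1.
#' @param frac fraction of inactive samples that must be strictly exceeded.
#'   Default 0.77.
#' @param groups length-2 character vector of supertype labels.
#' @param pooled apply the rule over the pooled samples instead of per group.
#' @return character vector of retained region ids.
#' @export
filter_inactive <- function(cpm_mat, samples, cpm_threshold = 1, frac = 0.77,
                            groups = c("SCC", "AD"), pooled = FALSE) {
  if (frac < 0 || frac > 1) stop("frac must be in [0, 1]")
  idx <- lapply(groups, function(g) {
    ids <- samples$sample_id[samples$supertype == g |
                               samples$subtype == g]
    ids <- intersect(ids, colnames(cpm_mat))
    if (!length(ids)) stop("empty group: ", g)
    ids
  })
  low <- cpm_mat <= cpm_threshold
  if (pooled) {
    ids <- unique(unlist(idx))
    remove <- rowMeans(low[, ids, drop = FALSE]) > frac
  } else {
    remove <- Reduce(`&`, lapply(idx, function(ids)
      rowMeans(low[, ids, drop = FALSE]) > frac))
  }
  rownames(cpm_mat)[!remove]
}

#' Multidimensional scaling of samples by leading log-fold-change distance
#'
#' The distance between two samples is the root mean square of the `top_n`
#' largest absolute log2 fold changes of shifted log-CPM between them
#' (a "leading log-fold-change" distance); the embedding is classical
#' (Torgerson) MDS of that distance matrix. A prior count of 0.5 is added to
#' each CPM value before taking log2. Axis signs are canonicalised so the
#' largest-magnitude coordinate on each axis is positive.
#'
#' @param cpm_mat CPM matrix (regions x samples).
#' @param top_n number of leading fold changes per pair. Default 500.
#' @param dims embedding dimension. Default 2.
#' @return list with `coords` (samples x dims) and `dist` (the pairwise
#'   distance matrix).
#' @export
mds_cage <- function(cpm_mat, top_n = 500, dims = 2) {
  n <- ncol(cpm_mat)
  if (n < 3) stop("MDS needs at least 3 samples")
  if (n < dims + 1) stop("need at least dims + 1 samples")
  lg <- log2(cpm_mat + 0.5)
  top_n <- min(top_n, nrow(cpm_mat))
  d <- matrix(0, n, n, dimnames = list(colnames(cpm_mat), colnames(cpm_mat)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    dif <- abs(lg[, i] - lg[, j])
    lead <- sort(dif, decreasing = TRUE)[seq_len(top_n)]
    d[i, j] <- d[j, i] <- sqrt(mean(lead^2))
  }
  co <- stats::cmdscale(stats::as.dist(d), k = dims)
  for (k in seq_len(ncol(co))) {
    if (co[which.max(abs(co[, k])), k] < 0) co[, k] <- -co[, k]
  }
  colnames(co) <- paste0("dim", seq_len(ncol(co)))
  list(coords = co, dist = d)
}

# ---- readers / writers ----------------------------------------------------

#' Read a BED6 promoter-region annotation
#'
#' Columns: chrom, start, end, name (region id), score (ignored), strand.
#' Coordinates are 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end, strand, region_id.
#' @export
read_bed_regions <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(b) < 6) stop("expected BED6: chrom start end name score strand")
  data.frame(chrom = b[[1]], start = as.integer(b[[2]]),
             end = as.integer(b[[3]]), strand = b[[6]],
             region_id = as.character(b[[4]]), stringsAsFactors = FALSE)
}

#' @rdname read_bed_regions
#' @param regions region data.frame.
#' @export
write_bed_regions <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, regions$start, regions$end, regions$region_id,
               0L, regions$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a TSV count matrix (first column region id, header sample ids)
#' @param path TSV path.
#' @param regions optional BED-derived annotation to attach.
#' @param lib_sizes optional named library sizes (else column sums).
#' @return a [cage_counts] object.
#' @export
read_count_matrix <- function(path, regions = NULL, lib_sizes = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  cage_counts(as.matrix(tab), regions, lib_sizes)
}

#' @rdname read_count_matrix
#' @param m matrix or [cage_counts] to write.
#' @export
write_tsv_matrix <- function(m, path) {
  if (inherits(m, "cage_counts")) m <- m$counts
  utils::write.table(data.frame(region_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a sample table TSV (sample_id, subtype)
#' @param path TSV path.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  sample_table(tab$sample_id, tab$subtype)
}

#' @rdname read_sample_table
#' @param samples sample table data.frame.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
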
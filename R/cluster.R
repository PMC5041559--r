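#' Binary positive/negative marker profiles from IHC scores
#'
#' State 1 (positive) iff the IHC score is 2, 0 (negative) otherwise.
#'
#' @param table an [ihc_table] or score matrix.
#' @return integer 0/1 matrix, samples x markers.
#' @export
binary_profile <- function(table) {
  scores <- if (inherits(table, "ihc_table")) table$scores else as.matrix(table)
  if (!ncol(scores)) stop("empty marker set")
  if (!all(scores %in% 0:2)) stop("IHC scores must be in {0, 1, 2}")
  m <- (scores == 2) + 0L
  dimnames(m) <- dimnames(scores)
  m
}

#' Euclidean distance between binary profiles
#'
#' On 0/1 rows the Euclidean distance equals the square root of the Hamming
#' distance; computed with [stats::dist()] after validating that the input
#' is binary.
#'
#' @param m 0/1 matrix (items in rows).
#' @return symmetric distance matrix with zero diagonal.
#' @export
euclidean_binary <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1))) stop("matrix must be binary (0/1)")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Deterministic UPGMA (average linkage) clustering
#'
#' Agglomerates the closest pair at each step; the distance between merged
#' clusters is the unweighted mean of all cross-pair item distances. Ties
#' are broken by the smallest item (clusters compared by their
#' smallest-ranked member, items ranked by label so the rule survives input
#' reordering; rank equals input position for already-sorted or unlabelled
#' input), and within each merge the subtree containing the smaller-ranked
#' item is placed first, so the tree is fully deterministic.
#'
#' @param d symmetric distance matrix or [stats::dist] object over n >= 2
#'   items.
#' @return an object of class [stats::hclust] (method `"average"`).
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items")
  if (!isSymmetric(unname(d)) || any(diag(d) != 0))
    stop("d must be a symmetric distance matrix with zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) {
    labels <- as.character(seq_len(n))
    lr <- seq_len(n)
  } else {
    if (anyDuplicated(labels)) stop("item labels must be unique")
    lr <- rank(labels)   # tie-break rank follows label order
  }

  # active clusters: id (negative = singleton item, positive = merge row),
  # member item indices
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  active <- seq_len(n)
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  ord_of <- as.list(seq_len(n))   # leaf order per active cluster

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      dij <- cur[i, j]
      cand_min <- sort(c(min(lr[members[[active[i]]]]),
                         min(lr[members[[active[j]]]])))
      if (dij < best[1] - 1e-12 ||
          (abs(dij - best[1]) <= 1e-12 &&
           (cand_min[1] < best[2] ||
            (cand_min[1] == best[2] && cand_min[2] < best[3])))) {
        best <- c(dij, cand_min)
        pick <- c(i, j)
      }
    }
    i <- pick[1]; j <- pick[2]
    ci <- active[i]; cj <- active[j]
    # smaller-ranked subtree first
    first_i <- min(lr[members[[ci]]]) < min(lr[members[[cj]]])
    pair <- if (first_i) c(ids[ci], ids[cj]) else c(ids[cj], ids[ci])
    merge[step, ] <- pair
    height[step] <- cur[i, j]

    ni <- length(members[[ci]]); nj <- length(members[[cj]])
    newd <- (ni * cur[i, ] + nj * cur[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    new_members <- c(members[[ci]], members[[cj]])
    new_order <- if (first_i) c(ord_of[[ci]], ord_of[[cj]])
                 else c(ord_of[[cj]], ord_of[[ci]])
    members[[length(members) + 1L]] <- new_members
    ord_of[[length(ord_of) + 1L]] <- new_order
    ids <- c(ids, step)
    active <- c(active[keep], length(members))
  }

  structure(list(merge = merge, height = height,
                 order = ord_of[[length(ord_of)]], labels = labels,
                 method = "average", call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Cluster IHC samples and markers by their binary profiles
#'
#' Both axes use the binary Euclidean distance: samples over their marker
#' profiles, markers over their sample vectors.
#'
#' @param table an [ihc_table].
#' @return list with `sample_tree`, `marker_tree` (hclust objects) and
#'   `profile` (the 0/1 matrix).
#' @export
cluster_ihc <- function(table) {
  prof <- binary_profile(table)
  list(sample_tree = average_linkage(euclidean_binary(prof)),
       marker_tree = average_linkage(euclidean_binary(t(prof))),
       profile = prof)
}

#' Reorder a score matrix to dendrogram leaf order
#'
#' @param table an [ihc_table] or score matrix.
#' @param sample_tree,marker_tree hclust trees over the table's samples and
#'   markers.
#' @return the score matrix with rows and columns permuted to leaf order.
#' @export
heatmap_order <- function(table, sample_tree, marker_tree) {
  scores <- if (inherits(table, "ihc_table")) table$scores else as.matrix(table)
  if (!setequal(sample_tree$labels, rownames(scores)) ||
      !setequal(marker_tree$labels, colnames(scores)))
    stop("tree labels do not match the score matrix")
  scores[sample_tree$labels[sample_tree$order],
         marker_tree$labels[marker_tree$order], drop = FALSE]
}

#' Serialise a dendrogram as Newick
#'
#' Branch lengths are merge-height differences (node depth equals merge
#' height), via [ape::as.phylo()].
#'
#' @param tree an hclust object.
#' @param path optional file to write to.
#' @return the Newick string (invisibly when written to file).
#' @export
tree_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  # as.phylo.hclust halves merge heights (cophenetic convention); rescale so
  # node depths equal merge heights and edges are height differences
  phy$edge.length <- phy$edge.length * 2
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}
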
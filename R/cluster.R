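#' Euclidean distance matrix between items
#'
#' `d(a, b) = sqrt(sum_i (a_i - b_i)^2)` over log2-transformed values.
#'
#' @param X Items x features numeric matrix with no undefined values
#'   (floor-impute and log-transform upstream).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
euclidean_distances <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) abort("X must be finite; impute upstream")
  as.matrix(dist(X, method = "euclidean"))
}

#' Agglomerative complete-linkage clustering
#'
#' Iteratively merges the pair of clusters at minimal inter-cluster
#' distance, where the inter-cluster distance is the maximum pairwise
#' member distance, recording merge heights. Complete linkage guarantees
#' non-decreasing merge heights (no inversions). Ties are resolved by the
#' deterministic internal ordering of the agglomeration, so the same input
#' always produces the same tree.
#'
#' @param d Symmetric distance matrix (or `dist` object).
#' @return A `dendro` object: `merge` (n-1 x 2 merge list), `height`,
#'   `order` (leaf order), `labels`, `n_leaves`, plus the underlying
#'   `hclust` in `$hclust`.
#' @export
complete_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- stats::as.dist(as.matrix(d))
  }
  if (attr(d, "Size") < 2) abort("need at least 2 items")
  hc <- hclust(d, method = "complete")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, n_leaves = length(hc$order), hclust = hc),
            class = "dendro")
}

#' Cut a dendrogram into k clusters
#'
#' @param dendro A `dendro` object.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(dendro, k) {
  stopifnot(inherits(dendro, "dendro"))
  cutree(dendro$hclust, k = k)
}

#' Export a dendrogram with branch heights in Newick format
#'
#' @param dendro A `dendro` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(dendro, path) {
  stopifnot(inherits(dendro, "dendro"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the 'ape' package")
  }
  phylo <- ape::as.phylo(dendro$hclust)
  ape::write.tree(phylo, file = path)
  invisible(path)
}

#' @export
print.dendro <- function(x, ...) {
  cat(sprintf("Complete-linkage dendrogram: %d leaves, %d merges, max height %.3g\n",
              x$n_leaves, length(x$height), max(x$height)))
  invisible(x)
}
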
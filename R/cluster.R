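# Complete-linkage hierarchical clustering of LDA-space coordinates,
# dendrogram export (Newick / JSON) and cluster purity at a tree cut.

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with the complete-linkage rule: the distance
#' between two clusters is the maximum Euclidean distance between their
#' points, and at each step the pair with the smallest such distance is
#' merged. Complete linkage is monotone, so merge heights are
#' non-decreasing. Duplicate points merge at height 0.
#'
#' @param points Numeric matrix of coordinates (items in rows), e.g.
#'   discriminant-space coordinates from [predict.pcalda()].
#' @param labels Leaf labels (default row names or indices).
#' @return An object of class `"linkage_result"`: `merge` (n-1 x 2 table in
#'   [stats::hclust()] convention), `height`, `labels`, `order`, `sizes`
#'   (new-cluster size per merge) and the underlying `hclust` object.
#' @export
complete_linkage <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop2("clustering needs at least 2 points")
  if (is.null(labels)) {
    labels <- rownames(points)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(points)))
  }
  hc <- stats::hclust(stats::dist(points, method = "euclidean"),
                      method = "complete")
  hc$labels <- as.character(labels)
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(k) if (k < 0) 1L else sizes[k]
    sizes[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  structure(list(merge = hc$merge, height = hc$height,
                 labels = hc$labels, order = hc$order, sizes = sizes,
                 hclust = hc),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("Complete-linkage tree: %d leaves, merge heights %.3g-%.3g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Export a dendrogram as Newick or JSON
#'
#' Newick export uses the ultrametric convention: a leaf sits at depth
#' `merge height / 2`, so two leaves merged at height 2 give
#' `"(A:1,B:1);"`. JSON export mirrors the merge table exactly and can be
#' re-imported with [dendrogram_from_json()].
#'
#' @param result A `"linkage_result"`.
#' @param format `"newick"` or `"json"`.
#' @return A character scalar.
#' @export
dendrogram_export <- function(result, format = c("newick", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(merge = result$merge, height = result$height,
           labels = result$labels, order = result$order),
      digits = NA)))
  }
  build <- function(node) {
    # node < 0: leaf index; node > 0: merge row
    if (node < 0) return(list(txt = result$labels[-node], h = 0))
    l <- build(result$merge[node, 1])
    r <- build(result$merge[node, 2])
    h <- result$height[node] / 2
    list(txt = sprintf("(%s:%.10g,%s:%.10g)", l$txt, h - l$h, r$txt, h - r$h),
         h = h)
  }
  paste0(build(nrow(result$merge))$txt, ";")
}

#' Re-import a JSON dendrogram export
#'
#' @param txt JSON text from `dendrogram_export(..., "json")`.
#' @return A `"linkage_result"` (without the `hclust` component).
#' @export
dendrogram_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  structure(list(merge = matrix(obj$merge, ncol = 2), height = obj$height,
                 labels = obj$labels, order = obj$order),
            class = "linkage_result")
}

#' Class composition of a tree cut
#'
#' Cuts the tree into `k` clusters and reports each cluster's label
#' composition and majority-label purity, plus the overall purity (the
#' fraction of items matching their cluster's majority label).
#'
#' @param result A `"linkage_result"` from [complete_linkage()].
#' @param labels Class label per leaf (in leaf order).
#' @param k Number of clusters, `2 <= k <= n_leaves`.
#' @return List with `composition` (cluster x label count table),
#'   `cluster` (leaf assignments), `purity_per_cluster`, `purity`.
#' @export
cluster_purity <- function(result, labels, k) {
  n <- length(result$labels)
  if (k < 1L || k > n) stop2("k must lie in [1, %d]", n)
  if (length(labels) != n) stop2("one label per leaf required")
  if (is.null(result$hclust)) stop2("linkage_result lacks its hclust component")
  cl <- stats::cutree(result$hclust, k = k)
  tab <- table(cluster = cl, label = labels)
  per <- apply(tab, 1, function(r) max(r) / sum(r))
  list(composition = tab, cluster = cl, purity_per_cluster = per,
       purity = sum(apply(tab, 1, max)) / n)
}

#' Per-sample discriminant coordinates
#'
#' Projects a spectra set through a fitted PCA-LDA model and averages the
#' discriminant coordinates over each sample's replicates — the entities
#' clustered by the pipeline (dendrogram leaves are samples).
#'
#' @param model A `"pcalda"` fit.
#' @param set A labelled `spectra_set`.
#' @return List with `coords` (samples x discriminant axes) and `classes`
#'   (per-sample class labels).
#' @export
sample_discriminant_coords <- function(model, set) {
  co <- predict(model, set, type = "discriminant")
  ids <- unique(set$meta$sample_id)
  m <- t(vapply(ids, function(s)
    colMeans(co[set$meta$sample_id == s, , drop = FALSE]),
    numeric(ncol(co))))
  rownames(m) <- ids
  classes <- vapply(ids, function(s)
    set$meta$class[set$meta$sample_id == s][1L], character(1))
  list(coords = m, classes = classes)
}
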
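# Clustering of response-gene expression signatures: best-of-restarts
# k-means over genes (rows), the elbow curve of within-cluster sums of
# squares, and hierarchical ordering of genes and samples for heatmap
# export. Gene rows are mean-centered by default so clusters capture
# expression pattern rather than baseline intensity.

prep_cluster_input <- function(expr, center = TRUE, scale = FALSE) {
  M <- unclass(expr)
  if (center) M <- M - rowMeans(M)
  if (scale) {
    sds <- apply(M, 1L, stats::sd)
    sds[sds == 0] <- 1
    M <- M / sds
  }
  M
}

#' Best-of-restarts k-means over genes
#'
#' Runs R's k-means (Hartigan-Wong, the stock `kmeans()` engine) from
#' `restarts` seeded random initializations and keeps the model with the
#' lowest total within-cluster sum of squares. Deterministic for a fixed
#' seed. A restart that produces an empty cluster is retried with a fresh
#' initialization (counted, not fatal).
#'
#' @param expr `ExpressionMatrix` subset (genes as observations).
#' @param k number of clusters, <= number of genes.
#' @param restarts random starts, default 50.
#' @param seed RNG seed.
#' @param center,scale per-gene row standardization before clustering
#'   (default: center only).
#' @param algorithm passed to [stats::kmeans()]; Hartigan-Wong by default.
#' @return list of class `ClusterModel`: `k`, `assignments` (named integer
#'   vector), `centroids` (k x samples), `wss` (total within-cluster sum of
#'   squares), `restarts_used`, `seed`.
#' @export
kmeans_cluster <- function(expr, k, restarts = 50L, seed = 1L,
                           center = TRUE, scale = FALSE,
                           algorithm = "Hartigan-Wong") {
  M <- prep_cluster_input(expr, center, scale)
  if (k > nrow(M))
    stop("k (", k, ") exceeds the number of genes (", nrow(M), ")",
         call. = FALSE)
  if (k == nrow(M)) {
    # one gene per cluster: the optimum is trivially wss = 0
    centroids <- M
    rownames(centroids) <- NULL
    return(structure(list(k = as.integer(k),
                          assignments = stats::setNames(seq_len(nrow(M)),
                                                        rownames(M)),
                          centroids = centroids, wss = 0,
                          restarts_used = 0L, seed = as.integer(seed)),
                     class = "ClusterModel"))
  }
  set.seed(seed)
  best <- NULL
  used <- 0L
  for (i in seq_len(restarts)) {
    fit <- NULL
    for (attempt in 1:5) {   # empty-cluster repair: reseed and retry
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(M, centers = k, nstart = 1L,
                                       iter.max = 100L,
                                       algorithm = algorithm)),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0L)) break
      fit <- NULL
    }
    if (is.null(fit)) next
    used <- used + 1L
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means failed for every restart", call. = FALSE)
  assignments <- stats::setNames(as.integer(best$cluster), rownames(M))
  structure(list(k = as.integer(k), assignments = assignments,
                 centroids = best$centers, wss = best$tot.withinss,
                 restarts_used = used, seed = as.integer(seed)),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel: k = %d over %d genes, wss = %.4g (best of %d restarts)\n",
              x$k, length(x$assignments), x$wss, x$restarts_used))
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Within-cluster sum-of-squares curve over a k range
#'
#' The elbow diagnostic: best-of-restarts total within-cluster sum of
#' squares for each k in `k_range` (default 2..20).
#'
#' @inheritParams kmeans_cluster
#' @param k_range integer vector of candidate k.
#' @return data.frame with columns `k` and `wss`.
#' @export
elbow_curve <- function(expr, k_range = 2:20, restarts = 50L, seed = 1L,
                        center = TRUE, scale = FALSE) {
  if (max(k_range) > nrow(expr))
    stop("max(k_range) exceeds the number of genes", call. = FALSE)
  wss <- vapply(k_range, function(k)
    kmeans_cluster(expr, k, restarts = restarts, seed = seed + k,
                   center = center, scale = scale)$wss, 0)
  data.frame(k = as.integer(k_range), wss = wss)
}

#' Hierarchical ordering of rows or columns
#'
#' Agglomerative clustering of matrix rows (`axis = "rows"`) or columns
#' with either euclidean distance or Pearson-correlation distance
#' (`1 - r`), returning the merge tree and the leaf order. Items are
#' pre-sorted by identifier so distance ties break deterministically by
#' name.
#'
#' @param m numeric matrix with dimnames.
#' @param axis `"rows"` or `"cols"`.
#' @param metric `"euclidean"` or `"pearson"`.
#' @param linkage one of `"complete"` (default), `"single"`, `"average"`.
#' @return list with `order` (identifiers in leaf order), `merge`,
#'   `height` (as in [stats::hclust()]).
#' @export
hierarchical_order <- function(m, axis = c("rows", "cols"),
                               metric = c("euclidean", "pearson"),
                               linkage = c("complete", "single", "average")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  X <- if (axis == "rows") m else t(m)
  if (nrow(X) < 2L) stop("need at least 2 items to order", call. = FALSE)
  X <- X[order(rownames(X)), , drop = FALSE]
  if (metric == "pearson") {
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero variance under pearson metric for item '",
           rownames(X)[sds == 0][1L], "'", call. = FALSE)
    d <- stats::as.dist(1 - stats::cor(t(X)))
  } else {
    d <- stats::dist(X)
  }
  hc <- stats::hclust(d, method = linkage)
  list(order = rownames(X)[hc$order], merge = hc$merge, height = hc$height,
       labels = rownames(X))
}

#' Gene and sample ordering for heatmap export
#'
#' Samples are ordered by hierarchical clustering on Pearson-correlation
#' distance; genes are grouped by k-means cluster (clusters in index
#' order), hierarchically ordered by euclidean distance within each
#' cluster. Returns the permutations plus cluster boundaries, i.e. all the
#' structure a heatmap renderer needs.
#'
#' @param expr `ExpressionMatrix` subset the model was fitted on.
#' @param model a [kmeans_cluster()] `ClusterModel` over the same genes.
#' @param center,scale row standardization applied before distance
#'   computations (match what the model saw).
#' @param linkage linkage method for both dendrograms.
#' @return list of class `HeatmapLayout`: `gene_order`, `sample_order`,
#'   `cluster_boundaries` (last row index of each cluster block), and
#'   `gene_cluster` (named cluster label per gene, in `gene_order`).
#' @export
build_heatmap_layout <- function(expr, model, center = TRUE, scale = FALSE,
                                 linkage = "complete") {
  if (!setequal(rownames(expr), names(model$assignments)))
    stop("model gene set does not match the expression subset",
         call. = FALSE)
  M <- prep_cluster_input(expr, center, scale)
  samp <- hierarchical_order(M, axis = "cols", metric = "pearson",
                             linkage = linkage)
  gene_order <- character(0)
  boundaries <- integer(0)
  for (cl in seq_len(model$k)) {
    members <- names(model$assignments)[model$assignments == cl]
    if (length(members) == 0L) next
    ord <- if (length(members) == 1L) members
           else hierarchical_order(M[members, , drop = FALSE], axis = "rows",
                                   metric = "euclidean",
                                   linkage = linkage)$order
    gene_order <- c(gene_order, ord)
    boundaries <- c(boundaries, length(gene_order))
  }
  structure(list(gene_order = gene_order, sample_order = samp$order,
                 cluster_boundaries = boundaries,
                 gene_cluster = model$assignments[gene_order]),
            class = "HeatmapLayout")
}
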
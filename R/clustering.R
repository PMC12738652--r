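#' Barcode set of a Turing-space node
#'
#' Bundles the four diagrams summarising one parameter point: degree-0 and
#' degree-1 barcodes for each species, computed from the model's filtration
#' convention (lower-star u / upper-star v for pure kinetics such as CIMA;
#' upper-star for both species for cross kinetics such as Schnakenberg).
#'
#' @param node_id identifier.
#' @param B0u,B1u,B0v,B1v [persistence_diagram()]s.
#' @param params optional originating [model_params()].
#' @param meta optional named list of extra per-node diagnostics.
#' @return object of class `barcode_set`.
#' @export
barcode_set <- function(node_id, B0u, B1u, B0v, B1v, params = NULL,
                        meta = list()) {
  for (d in list(B0u, B1u, B0v, B1v))
    stopifnot(inherits(d, "persistence_diagram"))
  structure(list(node_id = node_id, B0u = B0u, B1u = B1u, B0v = B0v,
                 B1v = B1v, params = params, meta = meta),
            class = "barcode_set")
}

#' Clean all four channels of a barcode set
#'
#' Applies per-channel length cutoffs. The defaults keep every bar of the
#' degree-1 u channel (whose long bars would be lost to any useful cutoff) and
#' drop bars shorter than 5 levels elsewhere.
#'
#' @param bs a [barcode_set()].
#' @param cutoffs named numeric vector over `B0u`, `B1u`, `B0v`, `B1v`.
#' @return a cleaned [barcode_set()].
#' @export
clean_barcode_set <- function(bs, cutoffs = c(B0u = 5, B1u = 0, B0v = 5,
                                              B1v = 5)) {
  stopifnot(inherits(bs, "barcode_set"))
  for (ch in c("B0u", "B1u", "B0v", "B1v"))
    bs[[ch]] <- clean_barcode(bs[[ch]], cutoffs[[ch]])
  bs
}

#' Composite distance between two nodes' barcode sets
#'
#' Combines the four channel-wise \eqn{W_{2,2}} distances:
#' `d1` is their sum (the pipeline's default metric), `d2` the square root of
#' the sum of squares, and `dinf` their maximum. `literal_d2 = TRUE` selects
#' the channel-wise \eqn{\sqrt{W^2}} reading, which collapses to `d1`.
#'
#' @param a,b [barcode_set()]s.
#' @param variant `"d1"`, `"d2"` or `"dinf"`.
#' @param literal_d2 see above.
#' @return nonnegative number.
#' @export
node_distance <- function(a, b, variant = c("d1", "d2", "dinf"),
                          literal_d2 = FALSE) {
  variant <- match.arg(variant)
  w <- vapply(c("B0u", "B1u", "B0v", "B1v"), function(ch)
    wasserstein_distance(a[[ch]], b[[ch]], p = 2, q = 2), numeric(1))
  switch(variant,
         d1 = sum(w),
         d2 = if (literal_d2) sum(sqrt(w^2)) else sqrt(sum(w^2)),
         dinf = max(w))
}

#' Pairwise distance matrix over barcode sets
#'
#' @param nodes list of [barcode_set()]s (length >= 2).
#' @param variant,literal_d2 as in [node_distance()].
#' @return symmetric matrix with zero diagonal; dimnames are the node ids.
#' @export
distance_matrix <- function(nodes, variant = "d1", literal_d2 = FALSE) {
  stopifnot(length(nodes) >= 2L)
  n <- length(nodes)
  ids <- vapply(nodes, function(x) as.character(x$node_id), character(1))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    D[i, j] <- D[j, i] <- node_distance(nodes[[i]], nodes[[j]], variant,
                                        literal_d2)
  }
  D
}

#' Agglomerative clustering on a precomputed distance matrix
#'
#' @param dmat symmetric distance matrix.
#' @param linkage `"single"`, `"complete"` or `"average"` (linkages requiring
#'   a Euclidean embedding, such as Ward or centroid, are not meaningful for a
#'   general diagram metric and are not offered).
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer labels in `1..k`, named by node id.
#' @export
cluster_nodes <- function(dmat, linkage = c("average", "complete", "single"),
                          k) {
  linkage <- match.arg(linkage)
  n <- nrow(dmat)
  if (k > n) stop("k exceeds the number of nodes")
  hc <- stats::hclust(stats::as.dist(dmat), method = linkage)
  stats::cutree(hc, k = k)
}

#' Mean silhouette score of a clustering
#'
#' For each point, with `a` its mean distance to its own cluster and `b` the
#' smallest mean distance to another cluster, the silhouette width is
#' `(b - a) / max(a, b)`; singleton clusters contribute 0. Returns the mean
#' width, in `[-1, 1]`.
#'
#' @param dmat symmetric distance matrix.
#' @param labels integer cluster labels (at least 2 distinct values).
#' @return mean silhouette width.
#' @export
silhouette_score <- function(dmat, labels) {
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = dmat)
  mean(sil[, "sil_width"])
}

#' Select linkage and cluster count by silhouette score
#'
#' Grid-searches the linkage methods and cluster counts and returns the
#' clustering with the highest mean silhouette; ties are broken towards the
#' smaller `k`, then the earlier linkage in `linkages`.
#'
#' @param dmat symmetric distance matrix.
#' @param linkages character vector of linkage methods.
#' @param k_range integer vector of candidate cluster counts, within
#'   `[2, n-1]`.
#' @return list of class `clustering_result` with `labels`, `linkage`, `k`,
#'   `silhouette` and the full `scores` table.
#' @export
select_clustering <- function(dmat,
                              linkages = c("average", "complete", "single"),
                              k_range = 2:12) {
  n <- nrow(dmat)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0L) stop("k_range is empty after clipping to [2, n-1]")
  scores <- expand.grid(linkage = linkages, k = k_range,
                        stringsAsFactors = FALSE)
  scores$silhouette <- NA_real_
  labs <- vector("list", nrow(scores))
  for (i in seq_len(nrow(scores))) {
    labs[[i]] <- cluster_nodes(dmat, scores$linkage[i], scores$k[i])
    scores$silhouette[i] <- silhouette_score(dmat, labs[[i]])
  }
  best <- order(-scores$silhouette, scores$k,
                match(scores$linkage, linkages))[1L]
  structure(list(labels = labs[[best]], linkage = scores$linkage[best],
                 k = scores$k[best], silhouette = scores$silhouette[best],
                 scores = scores),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k=%d, linkage=%s, silhouette=%.3f\n",
              x$k, x$linkage, x$silhouette))
  invisible(x)
}
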
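#' Euclidean distance between feature vectors
#'
#' @param a,b Numeric vectors of length 110 (normalized features).
#' @return Non-negative distance.
#' @export
feature_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("feature vectors differ in length: ", length(a), " vs ", length(b))
  sqrt(sum((a - b)^2))
}

#' Cluster negative examples by k-means
#'
#' Partitions the negative feature rows into `k` groups (default 10) with
#' seeded k-means under Euclidean distance, so that centroid-nearest
#' representatives can be drawn from each group.
#'
#' @param neg_matrix Normalized feature matrix of negatives (rows keyed by
#'   sample key).
#' @param k Number of clusters.
#' @param seed Integer seed for the initialization.
#' @param iter_max Iteration cap.
#' @return List with `assignments` (named integer vector) and `centroids`
#'   (k x p matrix).
#' @export
cluster_negatives <- function(neg_matrix, k = 10L, seed = 1L,
                              iter_max = 50L) {
  if (nrow(neg_matrix) < k)
    stop("need at least k = ", k, " negatives, have ", nrow(neg_matrix))
  # canonical row order so results depend on sample keys, not input order
  neg_matrix <- neg_matrix[order(rownames(neg_matrix)), , drop = FALSE]
  set.seed(as.integer(seed))
  km <- suppressWarnings(
    stats::kmeans(neg_matrix, centers = k, iter.max = iter_max,
                  nstart = 5L))
  list(assignments = stats::setNames(km$cluster, rownames(neg_matrix)),
       centroids = km$centers)
}

#' Select centroid-nearest representative negatives
#'
#' From each cluster, takes the `ceiling(n_total / k)` members closest to
#' the cluster centroid (ties broken by sample-key order), then trims the
#' pooled selection to exactly `n_total` by dropping the farthest-from-
#' centroid members last-first. With `n_total` equal to the number of
#' positives this yields the balanced round-1 negative set.
#'
#' @param neg_matrix Normalized feature matrix of negatives.
#' @param clustering From [cluster_negatives()].
#' @param n_total Number of representatives to return.
#' @return Character vector of selected sample keys.
#' @export
select_representatives <- function(neg_matrix, clustering, n_total) {
  n_total <- as.integer(n_total)
  if (n_total > nrow(neg_matrix))
    stop("n_total exceeds number of negatives")
  assign <- clustering$assignments
  # align rows with the clustering's key order
  neg_matrix <- neg_matrix[names(assign), , drop = FALSE]
  cents <- clustering$centroids
  k <- nrow(cents)
  per <- as.integer(ceiling(n_total / k))
  sel_key <- character(0); sel_dist <- numeric(0)
  keys <- rownames(neg_matrix)
  for (cl in seq_len(k)) {
    members <- which(assign == cl)
    if (length(members) == 0L) next
    d <- sqrt(rowSums(sweep(neg_matrix[members, , drop = FALSE], 2L,
                            cents[cl, ])^2))
    ord <- order(d, keys[members])  # deterministic tie-break by key
    take <- seq_len(min(per, length(members)))
    sel_key <- c(sel_key, keys[members[ord]][take])
    sel_dist <- c(sel_dist, d[ord][take])
  }
  if (length(sel_key) > n_total) {
    keep <- order(sel_dist, sel_key)[seq_len(n_total)]
    sel_key <- sel_key[keep]
  }
  sort(sel_key)
}

#' Grow a training subset with misclassified examples
#'
#' The next round's training subset is the deduplicated union of the
#' previous subset and the keys misclassified by the previous round on the
#' full training set. Positives are always retained.
#'
#' @param prev_keys Character vector of current subset keys.
#' @param incorrect_keys Keys misclassified by the previous round.
#' @param positive_keys All positive keys (always included).
#' @return Sorted character vector of subset keys.
#' @export
assemble_round_subset <- function(prev_keys, incorrect_keys,
                                  positive_keys = character(0)) {
  sort(unique(c(prev_keys, incorrect_keys, positive_keys)))
}

#' Build the balanced round-1 training subset
#'
#' Clusters the negatives into `k` groups and keeps, per cluster, the
#' members nearest the centroid, totalling one representative negative per
#' positive: a balanced subset of all positives plus centroid-nearest
#' negatives.
#'
#' @param x Normalized feature matrix, all training rows.
#' @param labels Integer labels (+1/-1) parallel to rows.
#' @param k Number of negative clusters.
#' @param seed Seed for clustering.
#' @param n_neg Number of negatives to keep (default: number of positives).
#' @return Sorted character vector of subset sample keys.
#' @export
balanced_subset <- function(x, labels, k = 10L, seed = 1L, n_neg = NULL) {
  pos_keys <- rownames(x)[labels == 1L]
  neg <- x[labels == -1L, , drop = FALSE]
  if (is.null(n_neg)) n_neg <- length(pos_keys)
  cl <- cluster_negatives(neg, k = k, seed = seed)
  reps <- select_representatives(neg, cl, n_neg)
  assemble_round_subset(reps, character(0), pos_keys)
}
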
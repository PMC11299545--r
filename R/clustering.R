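#' Mini-batch k-means
#'
#' Web-scale k-means variant: centers are initialized by k-means++ on the
#' full data, then refined with small random batches using per-center
#' learning rates 1/n_c (n_c = number of samples the center has absorbed),
#' so each update is a running mean. Several restarts are run and the
#' solution with the lowest full-data inertia is kept.
#'
#' @param x numeric matrix, one row per point.
#' @param k number of clusters (>= 2, and at most the number of distinct
#'   rows).
#' @param batch_size points sampled per update step.
#' @param iters number of batch updates per restart.
#' @param restarts independent restarts; best inertia wins.
#' @param seed integer seed (mandatory: the algorithm is stochastic).
#' @return list with `cluster` (integer assignments), `centers`, `inertia`.
#' @export
minibatch_kmeans <- function(x, k, batch_size = 32L, iters = 100L,
                             restarts = 10L, seed) {
  x <- as.matrix(x)
  if (k < 2) stopf("k must be >= 2")
  ndistinct <- nrow(unique(x))
  if (ndistinct < k) {
    stopf("fewer distinct points (%d) than clusters (%d)", ndistinct, k)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_init(x, k)
      counts <- rep(0L, k)
      for (it in seq_len(iters)) {
        idx <- sample.int(nrow(x), min(batch_size, nrow(x)))
        d <- pairwise_distances(x[idx, , drop = FALSE], centers, "euclidean")
        assign <- max.col(-d, ties.method = "first")
        for (j in seq_along(idx)) {
          c_j <- assign[[j]]
          counts[c_j] <- counts[c_j] + 1L
          eta <- 1 / counts[c_j]
          centers[c_j, ] <- (1 - eta) * centers[c_j, ] + eta * x[idx[j], ]
        }
      }
      d <- pairwise_distances(x, centers, "euclidean")
      cl <- max.col(-d, ties.method = "first")
      inertia <- sum(d[cbind(seq_len(nrow(x)), cl)]^2)
      if (is.null(best) || inertia < best$inertia) {
        best <- list(cluster = cl, centers = centers, inertia = inertia)
      }
    }
    best
  })
}

# k-means++ seeding: first center uniform, then D^2-weighted draws
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    centers[j + 1L, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1L, ])^2))
  }
  centers
}

#' Entropy-based clustering scores
#'
#' Homogeneity `h = 1 - H(class|cluster)/H(class)` rewards clusters whose
#' members share a class; completeness `c = 1 - H(cluster|class)/H(cluster)`
#' rewards classes whose members share a cluster; the v-measure is their
#' harmonic mean `v = 2hc/(h + c)`. Degenerate conventions follow the
#' standard implementation: a zero entropy denominator yields a score of 1,
#' and `v = 0` when `h + c = 0`. All three lie in `[0, 1]` and are invariant
#' to permutations of cluster labels.
#'
#' @param clusters vector of cluster assignments.
#' @param classes vector of ground-truth class labels, same length.
#' @return list with `homogeneity`, `completeness`, `v_measure`.
#' @export
v_measure <- function(clusters, classes) {
  if (length(clusters) != length(classes)) {
    stopf("clusters and classes must have equal length")
  }
  tab <- table(cluster = as.character(clusters), class = as.character(classes))
  n <- sum(tab)
  h_class <- entropy2(colSums(tab))
  h_clust <- entropy2(rowSums(tab))
  # conditional entropies from the joint table
  h_class_given_clust <- 0
  h_clust_given_class <- 0
  for (i in seq_len(nrow(tab))) {
    h_class_given_clust <- h_class_given_clust +
      (rowSums(tab)[i] / n) * entropy2(tab[i, ])
  }
  for (j in seq_len(ncol(tab))) {
    h_clust_given_class <- h_clust_given_class +
      (colSums(tab)[j] / n) * entropy2(tab[, j])
  }
  h <- if (h_class == 0) 1 else 1 - h_class_given_clust / h_class
  cm <- if (h_clust == 0) 1 else 1 - h_clust_given_class / h_clust
  v <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  list(homogeneity = unname(h), completeness = unname(cm),
       v_measure = unname(v))
}

#' Clustering-quality evaluation of an embedding space
#'
#' Runs mini-batch k-means on the embeddings with k set to the known number
#' of families (the protocol assumes the class count is given) and scores
#' the resulting partition against the family labels with the v-measure.
#'
#' @param emb numeric embedding matrix, protein ids as row names.
#' @param families named character vector or named factor: protein id ->
#'   family label. Every embedded protein must be labelled.
#' @param n_clusters number of clusters (conventionally the number of
#'   families).
#' @param batch_size mini-batch size (default 32).
#' @param seed integer seed.
#' @param iters,restarts passed to [minibatch_kmeans()].
#' @return object of class `cluster_eval`: v-measure, homogeneity,
#'   completeness, cluster assignments and the run parameters.
#' @export
clustering_eval <- function(emb, families, n_clusters, batch_size = 32L,
                            seed, iters = 100L, restarts = 10L) {
  emb <- validate_embeddings(emb)
  if (n_clusters < 2) stopf("n_clusters must be >= 2")
  miss <- setdiff(rownames(emb), names(families))
  if (length(miss) > 0) {
    stopf("embedded protein(s) without family label: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  fam <- as.character(families[rownames(emb)])
  km <- minibatch_kmeans(emb, k = n_clusters, batch_size = batch_size,
                         iters = iters, restarts = restarts, seed = seed)
  vm <- v_measure(km$cluster, fam)
  structure(
    list(v_measure = vm$v_measure, homogeneity = vm$homogeneity,
         completeness = vm$completeness,
         cluster = stats::setNames(km$cluster, rownames(emb)),
         inertia = km$inertia, n_clusters = n_clusters,
         batch_size = batch_size, seed = seed),
    class = "cluster_eval"
  )
}

#' @export
print.cluster_eval <- function(x, ...) {
  cat(sprintf(
    "cluster_eval: v = %.4f (h = %.4f, c = %.4f), k = %d, batch = %d\n",
    x$v_measure, x$homogeneity, x$completeness, x$n_clusters, x$batch_size))
  invisible(x)
}
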
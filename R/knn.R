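#' Build a reference index for KNN annotation
#'
#' Training embeddings act as a reference database: every indexed protein is
#' associated with its (propagated, vocabulary-restricted) term set.
#' Neighbour search is exact; metric is fixed at build time. Proteins with
#' labels but no embedding are an error; embedded proteins without any
#' vocabulary term are excluded from the index.
#'
#' @param train numeric embedding matrix, protein ids as row names.
#' @param labels a propagated [annotation_set()] for the training proteins.
#' @param vocab a [term_vocabulary()].
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return an object of class `reference_index`.
#' @export
build_index <- function(train, labels, vocab,
                        metric = c("euclidean", "cosine")) {
  train <- validate_embeddings(train)
  stopifnot(inherits(labels, "annotation_set"),
            inherits(vocab, "term_vocabulary"))
  metric <- match.arg(metric)
  labels <- restrict_annotations(labels, vocab)
  miss <- setdiff(names(labels$sets), rownames(train))
  if (length(miss) > 0) {
    stopf("labelled protein(s) without an embedding: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  ids <- sort(names(labels$sets))   # id order fixes the tie-break
  structure(
    list(emb = train[ids, , drop = FALSE],
         labels = annotation_matrix(labels, vocab, proteins = ids),
         vocab = vocab, metric = metric, k_default = 5L),
    class = "reference_index"
  )
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("reference_index: %d proteins, d = %d, %d terms, metric = %s\n",
              nrow(x$emb), ncol(x$emb), ncol(x$labels), x$metric))
  invisible(x)
}

# dense pairwise distances, queries x reference
pairwise_distances <- function(q, r, metric) {
  if (metric == "euclidean") {
    d2 <- outer(rowSums(q^2), rowSums(r^2), `+`) - 2 * tcrossprod(q, r)
    sqrt(pmax(d2, 0))
  } else {
    qn <- sqrt(rowSums(q^2)); rn <- sqrt(rowSums(r^2))
    qn[qn == 0] <- 1; rn[rn == 0] <- 1
    1 - tcrossprod(q / qn, r / rn)
  }
}

#' Multilabel KNN annotation transfer
#'
#' For each query the `k` reference embeddings at smallest distance are
#' found (exact search; ties at the k-th distance broken by ascending
#' protein id). Each term's score is the weighted fraction of those
#' neighbours annotated with it:
#' `score(g) = sum_i w_i I(g in labels(i)) / sum_i w_i`, with
#' `w_i = 1 / max(d_i, eps)` for inverse-distance weighting and `w_i = 1`
#' for uniform weighting. If one or more neighbours sit at distance below
#' `eps` (exact duplicates of the query), scores become the uniform average
#' over only those neighbours. Scores always lie in `[0, 1]`.
#'
#' @param idx a [build_index()] result.
#' @param queries numeric embedding matrix, protein ids as row names.
#' @param k number of neighbours, `1 <= k <=` index size (default 5).
#' @param weighting `"inverse_distance"` (default) or `"uniform"`.
#' @param eps weight floor for inverse-distance weighting.
#' @return a prediction matrix, queries x vocabulary terms.
#' @export
knn_predict <- function(idx, queries, k = 5L,
                        weighting = c("inverse_distance", "uniform"),
                        eps = 1e-12) {
  stopifnot(inherits(idx, "reference_index"))
  queries <- validate_embeddings(queries)
  weighting <- match.arg(weighting)
  if (k < 1 || k > nrow(idx$emb)) {
    stopf("k = %d out of range for index of size %d", k, nrow(idx$emb))
  }
  if (ncol(queries) != ncol(idx$emb)) {
    stopf("query dimension %d != index dimension %d",
          ncol(queries), ncol(idx$emb))
  }
  dmat <- pairwise_distances(queries, idx$emb, idx$metric)
  ref_ids <- rownames(idx$emb)
  out <- matrix(0, nrow(queries), ncol(idx$labels),
                dimnames = list(rownames(queries), colnames(idx$labels)))
  for (i in seq_len(nrow(queries))) {
    d <- dmat[i, ]
    ord <- order(d, ref_ids)[seq_len(k)]
    dk <- d[ord]
    dup <- dk < eps
    if (any(dup)) {
      sel <- ord[dup]
      out[i, ] <- colSums(idx$labels[sel, , drop = FALSE]) / length(sel)
    } else {
      w <- if (weighting == "uniform") rep(1, k) else 1 / pmax(dk, eps)
      out[i, ] <- as.numeric(w %*% idx$labels[ord, , drop = FALSE]) / sum(w)
    }
  }
  out
}
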
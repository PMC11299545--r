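# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route than the package (loops + explicit sums, no
# shared helpers) so agreement is evidence, not tautology.

# -- toy ontologies ----------------------------------------------------------

# chain: d -> c -> b -> root
chain_ontology <- function() {
  ontology(c("root", "b", "c", "d"),
           list(root = character(), b = "root", c = "b", d = "c"))
}

# diamond: d -> {b, c}, b -> a, c -> a
diamond_ontology <- function() {
  ontology(c("a", "b", "c", "d"),
           list(a = character(), b = "a", c = "a", d = c("b", "c")))
}

# breadth-first reflexive closure over an edge list; independent of the
# package's topological-order implementation
closure_oracle <- function(edges_child, edges_parent, term) {
  out <- term
  repeat {
    new <- unique(c(out, edges_parent[edges_child %in% out]))
    if (length(new) == length(out)) return(sort(out))
    out <- new
  }
}

# -- KNN brute force ---------------------------------------------------------

# all-pairs distances + sort + direct formula; shares only the documented
# tie-break (ascending protein id at equal distance) and duplicate rule
knn_oracle <- function(train_emb, label_sets, vocab_terms, queries, k,
                       metric = "euclidean", weighting = "inverse_distance",
                       eps = 1e-12) {
  ids <- sort(names(label_sets))
  out <- matrix(0, nrow(queries), length(vocab_terms),
                dimnames = list(rownames(queries), vocab_terms))
  for (qi in seq_len(nrow(queries))) {
    d <- numeric(length(ids))
    for (j in seq_along(ids)) {
      a <- queries[qi, ]; b <- train_emb[ids[j], ]
      d[j] <- if (metric == "euclidean") {
        sqrt(sum((a - b)^2))
      } else {
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na == 0) na <- 1
        if (nb == 0) nb <- 1
        1 - sum(a * b) / (na * nb)
      }
    }
    ord <- order(d, ids)[seq_len(k)]
    dk <- d[ord]
    if (any(dk < eps)) {
      sel <- ids[ord][dk < eps]
      for (g in vocab_terms) {
        out[qi, g] <- sum(vapply(sel, function(s) g %in% label_sets[[s]],
                                 logical(1))) / length(sel)
      }
    } else {
      w <- if (weighting == "uniform") rep(1, k) else 1 / pmax(dk, eps)
      for (g in vocab_terms) {
        y <- vapply(ids[ord], function(s) g %in% label_sets[[s]], logical(1))
        out[qi, g] <- sum(w * y) / sum(w)
      }
    }
  }
  out
}

# -- bitscore-weighted transfer ---------------------------------------------

blast_oracle <- function(hits, label_sets, vocab_terms, queries) {
  out <- matrix(0, length(queries), length(vocab_terms),
                dimnames = list(queries, vocab_terms))
  for (q in queries) {
    h <- hits[hits$query == q & hits$subject %in% names(label_sets), ]
    if (nrow(h) == 0) next
    denom <- sum(h$bitscore)
    if (denom == 0) next
    for (g in vocab_terms) {
      num <- 0
      for (r in seq_len(nrow(h))) {
        if (g %in% label_sets[[h$subject[r]]]) num <- num + h$bitscore[r]
      }
      out[q, g] <- num / denom
    }
  }
  out
}

# -- confusion-count evaluation oracle ---------------------------------------

# protein-centric precision/recall/F at one threshold by explicit counting;
# prediction rule: score >= tau and score > 0
pr_oracle_at <- function(pred, truth_sets, tau) {
  prots <- rownames(pred)
  prs <- c(); rcs <- c()
  for (p in prots) {
    predicted <- colnames(pred)[pred[p, ] >= tau & pred[p, ] > 0]
    truth <- truth_sets[[p]]
    tp <- length(intersect(predicted, truth))
    if (length(predicted) > 0) prs <- c(prs, tp / length(predicted))
    rcs <- c(rcs, if (length(truth) > 0) tp / length(truth) else 0)
  }
  pr <- if (length(prs) > 0) mean(prs) else 0
  rc <- mean(rcs)
  f <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  c(precision = pr, recall = rc, f = f)
}

# entropy arithmetic straight from the contingency table definitions
vmeasure_oracle <- function(clusters, classes) {
  tab <- table(clusters, classes)
  n <- sum(tab)
  ent <- function(x) {
    p <- x[x > 0] / sum(x)
    if (length(p) <= 1) 0 else -sum(p * log2(p))
  }
  hc <- ent(colSums(tab)); hk <- ent(rowSums(tab))
  h_c_k <- sum(vapply(seq_len(nrow(tab)), function(i) {
    sum(tab[i, ]) / n * ent(tab[i, ])
  }, numeric(1)))
  h_k_c <- sum(vapply(seq_len(ncol(tab)), function(j) {
    sum(tab[, j]) / n * ent(tab[, j])
  }, numeric(1)))
  h <- if (hc == 0) 1 else 1 - h_c_k / hc
  cm <- if (hk == 0) 1 else 1 - h_k_c / hk
  v <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  c(h = h, c = cm, v = v)
}

# -- canned synthetic datasets ----------------------------------------------

default_dataset <- function(seed = 7, ...) {
  cfg <- synth_config(seed = seed, ...)
  g <- gen_ontology(cfg)
  ds <- gen_dataset(cfg, g)
  list(cfg = cfg, g = g, ds = ds,
       vocab = build_vocabulary(ds$annotations, min_count = 1))
}

# deterministic within-family half split: even members train, odd test
half_split <- function(families) {
  prots <- names(families)
  test <- unlist(lapply(split(prots, families), function(m) {
    m[seq_along(m) %% 2 == 1]
  }), use.names = FALSE)
  list(train = setdiff(prots, test), test = test)
}

knn_fmax_heldout <- function(ds, vocab, k = 5) {
  sp <- half_split(ds$families)
  idx <- build_index(ds$embeddings[sp$train, , drop = FALSE],
                     subset_annotations(ds$annotations, sp$train), vocab)
  pred <- knn_predict(idx, ds$embeddings[sp$test, , drop = FALSE], k = k)
  truth <- subset_annotations(restrict_annotations(ds$annotations, vocab),
                              sp$test)
  pr_curve(pred, truth)$summary
}
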
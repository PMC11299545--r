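#' Train/test split regimes
#'
#' A `split_spec` records a disjoint train/test partition of proteins and,
#' for the term-holdout regime, a disjoint partition of vocabulary terms.
#'
#' @param train,test character vectors of protein ids (disjoint, nonempty).
#' @param train_terms,holdout_terms optional disjoint term id vectors.
#' @param seed the seed used to build the split.
#' @param regime free-text tag (`"family"`, `"term"`, ...).
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(train, test, train_terms = NULL, holdout_terms = NULL,
                       seed = NA_integer_, regime = "custom") {
  if (length(train) == 0 || length(test) == 0) {
    stopf("both sides of a split must be nonempty")
  }
  if (length(intersect(train, test)) > 0) {
    stopf("train and test protein sets overlap")
  }
  if (!is.null(train_terms) && length(intersect(train_terms, holdout_terms)) > 0) {
    stopf("train and holdout term sets overlap")
  }
  structure(list(train = sort(train), test = sort(test),
                 train_terms = train_terms, holdout_terms = holdout_terms,
                 seed = seed, regime = regime),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec [%s]: %d train / %d test proteins%s\n",
              x$regime, length(x$train), length(x$test),
              if (is.null(x$train_terms)) "" else
                sprintf("; %d train / %d holdout terms",
                        length(x$train_terms), length(x$holdout_terms))))
  invisible(x)
}

#' Family-aware protein split
#'
#' Whole families are assigned to one side, preventing contamination of the
#' test set by close homologs of training proteins. Families are shuffled
#' (seeded) and filled greedily into the test side until the test protein
#' fraction reaches the target; the overshoot is therefore bounded by the
#' largest family size minus one.
#'
#' @param families named vector: protein id -> family label.
#' @param test_fraction target fraction of proteins in the test side,
#'   in (0, 1).
#' @param seed integer seed.
#' @return a [split_spec()].
#' @export
family_split <- function(families, test_fraction = 0.2, seed) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must be in (0, 1)")
  }
  fam <- split(names(families), as.character(families))
  if (length(fam) < 2) stopf("cannot split a single family")
  n <- length(families)
  target <- test_fraction * n
  with_seed(seed, {
    ord <- sample(names(fam))
    test_fams <- character()
    size <- 0
    for (f in ord) {
      if (size >= target) break
      test_fams <- c(test_fams, f)
      size <- size + length(fam[[f]])
    }
    if (size >= n) {  # greedy fill consumed everything; keep one family back
      test_fams <- test_fams[-length(test_fams)]
      if (length(test_fams) == 0) stopf("cannot split: one family dominates")
    }
    test <- unlist(fam[test_fams], use.names = FALSE)
    train <- setdiff(names(families), test)
    split_spec(train, test, seed = seed, regime = "family")
  })
}

#' Random GO-term holdout split
#'
#' Partitions the vocabulary uniformly at random into a training-term set
#' and a held-out set (default 50/50), the regime for testing whether an
#' annotator generalizes to GO classes never seen in training.
#'
#' @param vocab a [term_vocabulary()].
#' @param holdout_fraction fraction of terms held out, in (0, 1);
#'   default 0.5.
#' @param seed integer seed.
#' @return list with `train_terms` and `holdout_terms` (disjoint, exact
#'   partition of the vocabulary).
#' @export
term_split <- function(vocab, holdout_fraction = 0.5, seed) {
  stopifnot(inherits(vocab, "term_vocabulary"))
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stopf("holdout_fraction must be in (0, 1)")
  }
  nterm <- length(vocab$terms)
  nhold <- round(holdout_fraction * nterm)
  if (nhold == 0 || nhold == nterm) {
    stopf("holdout_fraction %g leaves one side empty for %d terms",
          holdout_fraction, nterm)
  }
  with_seed(seed, {
    hold <- sort(sample(vocab$terms, nhold))
    list(train_terms = setdiff(vocab$terms, hold), holdout_terms = hold)
  })
}

#' Novel-protein subset of a split
#'
#' The test proteins with no significant similarity hit (e-value below
#' `evalue_max`) against the training side: the regime where alignment-based
#' transfer is uninformative and embedding methods must stand on their own.
#'
#' @param split a [split_spec()].
#' @param hits a [hit_table()] of test-vs-train hits.
#' @param evalue_max significance threshold (default 0.001).
#' @return character vector of novel test protein ids.
#' @export
novel_subset <- function(split, hits, evalue_max = 0.001) {
  stopifnot(inherits(split, "split_spec"))
  sig <- filter_significant(hits, evalue_max)
  sig <- sig[sig$subject %in% split$train, , drop = FALSE]
  novel_queries(sig, split$test)
}

#' Derive family labels from a significant-hit graph
#'
#' When no curated family file is available, connected components of the
#' graph whose edges are significant hits give a serviceable family
#' structure for contamination-free splitting.
#'
#' @param hits a [hit_table()].
#' @param proteins all protein ids (singletons allowed).
#' @param evalue_max significance threshold for an edge.
#' @return named character vector protein id -> family label.
#' @export
families_from_hits <- function(hits, proteins, evalue_max = 0.001) {
  sig <- filter_significant(hits, evalue_max)
  # union-find over proteins
  parent <- stats::setNames(seq_along(proteins), proteins)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (r in seq_len(nrow(sig))) {
    q <- match(sig$query[r], proteins)
    s <- match(sig$subject[r], proteins)
    if (is.na(q) || is.na(s)) next
    rq <- find(q); rs <- find(s)
    if (rq != rs) parent[[rq]] <- rs
  }
  roots <- vapply(seq_along(proteins), find, numeric(1))
  stats::setNames(paste0("FAM", match(roots, unique(roots))), proteins)
}
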
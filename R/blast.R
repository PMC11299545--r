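#' Load a BLAST/DIAMOND tabular hit file
#'
#' Parses 12-column tab-separated alignment output (outfmt 6: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore).
#' Multiple HSPs for the same (query, subject) pair are collapsed to the
#' maximum bitscore.
#'
#' @param path path to the tabular file.
#' @return a `hit_table` data frame with columns `query`, `subject`,
#'   `bitscore`, `evalue`.
#' @export
load_hits <- function(path) {
  if (!file.exists(path)) stopf("hit file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(hit_table(character(), character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0) {
    stopf("format error at line %d: expected 12 tab-separated columns, got %d",
          bad[1], lengths(fields)[bad[1]])
  }
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  bitscore <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 12L)))
  if (anyNA(evalue) || anyNA(bitscore)) {
    stopf("format error at line %d: non-numeric e-value or bitscore",
          which(is.na(evalue) | is.na(bitscore))[1])
  }
  hit_table(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L),
            bitscore, evalue)
}

#' Construct a hit table
#'
#' @param query,subject character vectors of protein ids.
#' @param bitscore non-negative finite alignment bitscores.
#' @param evalue non-negative alignment e-values.
#' @return a `hit_table` data frame, deduplicated to max bitscore per
#'   (query, subject) pair (keeping that row's e-value).
#' @export
hit_table <- function(query, subject, bitscore, evalue) {
  if (length(bitscore) > 0 &&
      (!all(is.finite(bitscore)) || any(bitscore < 0) || any(evalue < 0))) {
    stopf("bitscores must be finite and non-negative, e-values non-negative")
  }
  df <- data.frame(query = as.character(query),
                   subject = as.character(subject),
                   bitscore = as.numeric(bitscore),
                   evalue = as.numeric(evalue),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    df <- df[order(df$query, df$subject, -df$bitscore), , drop = FALSE]
    df <- df[!duplicated(df[c("query", "subject")]), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Bitscore-weighted annotation transfer
#'
#' For a query protein the score of a term `g` is the bitscore-weighted
#' average of the indicator that each hit subject carries `g`:
#' `s(q, g) = sum_B bitscore(q, B) I(B has g) / sum_B bitscore(q, B)`,
#' where the sum runs over hit subjects present in the labelled training
#' set (unlabelled subjects are excluded from numerator and denominator and
#' counted in the attached report). Queries with no labelled hit receive an
#' all-zero row and are listed in the report.
#'
#' @param hits a [hit_table()].
#' @param train_labels a propagated [annotation_set()] of training proteins.
#' @param vocab a [term_vocabulary()].
#' @param queries optional protein ids fixing the output rows; defaults to
#'   the distinct query ids in `hits`.
#' @return a prediction matrix with attribute `"report"` (skipped-subject
#'   count, zero-hit queries).
#' @export
blast_predict <- function(hits, train_labels, vocab, queries = NULL) {
  stopifnot(inherits(hits, "data.frame"),
            inherits(train_labels, "annotation_set"),
            inherits(vocab, "term_vocabulary"))
  labels <- restrict_annotations(train_labels, vocab)
  queries <- queries %||% sort(unique(hits$query))
  if (length(queries) == 0) stopf("no query to score")
  labelled <- hits$subject %in% names(labels$sets)
  skipped <- sum(!labelled)
  hits <- hits[labelled, , drop = FALSE]
  lab_mat <- annotation_matrix(labels, vocab)
  out <- matrix(0, length(queries), length(vocab$terms),
                dimnames = list(queries, vocab$terms))
  zero_hit <- character()
  for (q in queries) {
    h <- hits[hits$query == q, , drop = FALSE]
    if (nrow(h) == 0 || sum(h$bitscore) == 0) {
      zero_hit <- c(zero_hit, q)
      next
    }
    w <- h$bitscore
    out[q, ] <- as.numeric(w %*% lab_mat[h$subject, , drop = FALSE]) / sum(w)
  }
  attr(out, "report") <- list(unlabelled_subject_hits = skipped,
                              zero_hit_queries = zero_hit)
  out
}

#' Naive prior baseline
#'
#' Every query receives, for each term, the term's training frequency
#' (count / number of training proteins); rows are identical across queries.
#'
#' @param train_labels a propagated [annotation_set()].
#' @param vocab a [term_vocabulary()].
#' @param queries character vector of query protein ids.
#' @return a prediction matrix.
#' @export
naive_predict <- function(train_labels, vocab, queries) {
  stopifnot(inherits(train_labels, "annotation_set"),
            inherits(vocab, "term_vocabulary"))
  if (length(queries) == 0) stopf("no query to score")
  n <- length(train_labels$sets)
  counts <- term_counts(train_labels)
  freq <- counts[vocab$terms] / n
  freq[is.na(freq)] <- 0
  out <- matrix(rep(freq, each = length(queries)),
                nrow = length(queries),
                dimnames = list(queries, vocab$terms))
  out
}

#' Filter hits by significance
#'
#' Keeps records with e-value strictly below `evalue_max` (the novel-protein
#' regime uses the conventional 0.001 cutoff).
#'
#' @param hits a [hit_table()].
#' @param evalue_max strictly positive significance threshold.
#' @return a filtered [hit_table()].
#' @export
filter_significant <- function(hits, evalue_max = 0.001) {
  if (evalue_max <= 0) stopf("evalue_max must be > 0")
  out <- hits[hits$evalue < evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Queries with no surviving hit
#'
#' @param hits a [hit_table()] (typically already passed through
#'   [filter_significant()]).
#' @param all_queries character vector of candidate query ids.
#' @return character vector: the queries of `all_queries` absent from
#'   `hits$query`.
#' @export
novel_queries <- function(hits, all_queries) {
  sort(setdiff(all_queries, unique(hits$query)))
}
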
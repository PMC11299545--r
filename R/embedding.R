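#' Pool token-level embeddings into a protein vector
#'
#' Language models emit one embedding per residue plus a designated global
#' (CLS-role) summary vector. The protein representation used throughout
#' this toolkit is the elementwise mean of the residue embeddings added to
#' the global vector. `pool()` is the only language-model-facing contract:
#' any exported token-embedding table can be pooled identically regardless
#' of which model produced it.
#'
#' @param residues numeric matrix, one row per residue (L x d), L >= 1.
#' @param global numeric vector of length d (the CLS-role embedding).
#' @return numeric vector of length d: `colMeans(residues) + global`.
#' @export
pool <- function(residues, global) {
  residues <- as.matrix(residues)
  if (nrow(residues) < 1) stopf("need at least one residue embedding")
  if (length(global) != ncol(residues)) {
    stopf("dimension mismatch: residues have d = %d, global has length %d",
          ncol(residues), length(global))
  }
  if (!all(is.finite(residues)) || !all(is.finite(global))) {
    stopf("non-finite values in token embeddings")
  }
  colMeans(residues) + as.numeric(global)
}

#' Read a protein embedding table
#'
#' Delimited text, first column protein id, remaining columns numeric; one
#' row per protein. Values are stored at 8 significant digits by
#' [write_embeddings()], so a round trip is exact to that precision.
#'
#' @param path path to the table.
#' @param sep field separator (default tab).
#' @return numeric matrix with protein ids as row names.
#' @export
read_embeddings <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("embedding file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("empty embedding file: %s", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    stopf("ragged embedding table: rows have %s fields",
          paste(unique(widths), collapse = "/"))
  }
  if (widths[[1]] < 2) stopf("embedding table needs an id column plus values")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stopf("duplicate protein id in embedding table: %s",
          ids[duplicated(ids)][1])
  }
  m <- t(vapply(fields, function(f) as.numeric(f[-1L]),
                numeric(widths[[1]] - 1L)))
  if (!all(is.finite(m))) stopf("non-numeric or non-finite embedding values")
  rownames(m) <- ids
  m
}

#' Write a protein embedding table
#'
#' @param m numeric matrix with protein ids as row names.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_embeddings <- function(m, path, sep = "\t") {
  m <- validate_embeddings(m)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 8)),
          collapse = sep)
  }, "")
  writeLines(rows, path)
  invisible(path)
}

validate_embeddings <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stopf("embedding matrix must have protein row names")
  if (anyDuplicated(rownames(m))) stopf("duplicate protein ids in embeddings")
  if (!all(is.finite(m))) stopf("non-finite embedding values")
  m
}

#' Prediction matrices
#'
#' A prediction matrix holds one score per (protein, term) pair: rows are
#' query proteins, columns follow the order of a [term_vocabulary()].
#' Probability-valued annotators produce scores in `[0, 1]`; logit-valued
#' matrices are permitted by the evaluation suite, whose threshold grids
#' adapt to the achieved score range.
#'
#' @param scores numeric matrix, rows named by protein id.
#' @param vocab a [term_vocabulary()]; must match the column count.
#' @return the score matrix with vocabulary terms as column names.
#' @export
prediction_matrix <- function(scores, vocab) {
  scores <- as.matrix(scores)
  stopifnot(inherits(vocab, "term_vocabulary"))
  if (ncol(scores) != length(vocab$terms)) {
    stopf("score matrix has %d columns but vocabulary has %d terms",
          ncol(scores), length(vocab$terms))
  }
  if (is.null(rownames(scores))) stopf("scores must have protein row names")
  if (!all(is.finite(scores))) stopf("non-finite prediction scores")
  colnames(scores) <- vocab$terms
  scores
}

#' Write predictions as a sparse TSV
#'
#' Emits `protein_id<TAB>term_id<TAB>score` rows, omitting scores at or
#' below `min_score` (the default 0 emits every strictly positive score).
#'
#' @param pred a prediction matrix (see [prediction_matrix()]).
#' @param path output path.
#' @param min_score scores `<= min_score` are omitted; with the default 0,
#'   exact zeros are omitted.
#' @export
write_predictions <- function(pred, path, min_score = 0) {
  idx <- which(pred > min_score, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(protein = rownames(pred)[idx[, 1]],
                   term = colnames(pred)[idx[, 2]],
                   score = formatC(pred[idx], format = "g", digits = 8))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sparse prediction TSV into a matrix
#'
#' @param path `protein_id<TAB>term_id<TAB>score` file.
#' @param vocab a [term_vocabulary()] fixing the columns; terms outside it
#'   are dropped.
#' @return a prediction matrix (absent pairs score 0).
#' @export
read_predictions <- function(path, vocab) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein", "term", "score"),
                          colClasses = c("character", "character", "numeric"))
  prots <- sort(unique(df$protein))
  m <- matrix(0, length(prots), length(vocab$terms),
              dimnames = list(prots, vocab$terms))
  keep <- df$term %in% vocab$terms
  df <- df[keep, , drop = FALSE]
  m[cbind(match(df$protein, prots), match(df$term, vocab$terms))] <- df$score
  prediction_matrix(m, vocab)
}

#' Annotation set as a binary target matrix
#'
#' @param a a (typically propagated) [annotation_set()].
#' @param vocab a [term_vocabulary()].
#' @param proteins optional protein order; defaults to all proteins of `a`.
#' @return 0/1 matrix, proteins x vocabulary terms.
#' @export
annotation_matrix <- function(a, vocab, proteins = NULL) {
  stopifnot(inherits(a, "annotation_set"), inherits(vocab, "term_vocabulary"))
  proteins <- proteins %||% names(a$sets)
  miss <- setdiff(proteins, names(a$sets))
  if (length(miss) > 0) {
    stopf("protein(s) absent from annotations: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  m <- matrix(0, length(proteins), length(vocab$terms),
              dimnames = list(proteins, vocab$terms))
  for (p in proteins) {
    hit <- intersect(a$sets[[p]], vocab$terms)
    m[p, hit] <- 1
  }
  m
}
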
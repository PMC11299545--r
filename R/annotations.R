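#' Protein annotation sets
#'
#' An `annotation_set` maps protein ids to sets of ontology term ids, with a
#' flag recording whether the sets are closed under ontology ancestors
#' (propagated). Every protein carries at least one term; proteins whose
#' annotations are entirely filtered away are removed, matching the
#' at-least-one-annotation dataset rule.
#'
#' @param sets named list mapping protein id to a character vector of term ids.
#' @param propagated logical; whether each set is ancestor-closed.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(sets, propagated = FALSE) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stopf("annotation sets must be named by protein id")
  }
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) stopf("empty annotation set: no protein has a term")
  structure(list(sets = sets, propagated = isTRUE(propagated)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d proteins, %d distinct terms, %s\n",
              length(x$sets), length(unique(unlist(x$sets))),
              if (x$propagated) "propagated" else "unpropagated"))
  invisible(x)
}

# GAF evidence codes conventionally treated as experimental
EXPERIMENTAL_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")

#' Load protein-to-term annotations
#'
#' Reads either GAF 2.1/2.2 (tab-separated; column 2 protein accession,
#' column 4 qualifier, column 5 GO id, column 7 evidence code; `!` comment
#' lines skipped; rows with qualifier `NOT` dropped) or a plain two-column
#' `protein_id<TAB>term_id` TSV. For the GAF dialect an evidence filter is
#' applied; `"experimental"` selects the conventional experimental code set
#' (EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC). Malformed rows are skipped with
#' a warning and counted in the attached load report. Proteins left without
#' any annotation are removed.
#'
#' @param path path to the annotation file.
#' @param dialect `"gaf"` or `"tsv"`.
#' @param evidence_filter `"experimental"`, `"all"`, or a character vector of
#'   evidence codes to keep (GAF dialect only).
#' @return an unpropagated [annotation_set()] with attribute `"report"`
#'   (rows read / kept / skipped).
#' @export
load_annotations <- function(path, dialect = c("gaf", "tsv"),
                             evidence_filter = "experimental") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  skipped <- 0L
  prot <- character(length(fields)); term <- character(length(fields))
  keep <- logical(length(fields))
  if (dialect == "tsv") {
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 2 || !nzchar(f[[1]]) || !nzchar(f[[2]])) {
        skipped <- skipped + 1L
        next
      }
      prot[i] <- f[[1]]; term[i] <- f[[2]]; keep[i] <- TRUE
    }
  } else {
    codes <- if (identical(evidence_filter, "experimental")) EXPERIMENTAL_CODES
             else if (identical(evidence_filter, "all")) NULL
             else as.character(evidence_filter)
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 7 || !nzchar(f[[2]]) || !nzchar(f[[5]])) {
        skipped <- skipped + 1L
        next
      }
      if (grepl("(^|\\|)NOT($|\\|)", f[[4]])) next
      if (!is.null(codes) && !(f[[7]] %in% codes)) next
      prot[i] <- f[[2]]; term[i] <- f[[5]]; keep[i] <- TRUE
    }
  }
  if (skipped > 0) warnf("skipped %d malformed row(s) in %s", skipped, path)
  prot <- prot[keep]; term <- term[keep]
  if (length(prot) == 0) {
    stopf("no annotations remain after filtering %s", path)
  }
  sets <- split(term, prot)
  a <- annotation_set(sets, propagated = FALSE)
  attr(a, "report") <- list(rows = length(fields), kept = sum(keep),
                            skipped = skipped)
  a
}

#' Propagate annotations up the ontology
#'
#' Replaces every protein's term set with the union of the ancestors of its
#' terms (annotating a term implies all its parents). Idempotent. Terms
#' absent from the ontology are dropped with a warning by default, or raise
#' an error with `missing = "error"`.
#'
#' @param a an [annotation_set()].
#' @param g a [ontology()].
#' @param missing `"drop"` (default) or `"error"` for terms not in `g`.
#' @return a propagated [annotation_set()].
#' @export
propagate <- function(a, g, missing = c("drop", "error")) {
  stopifnot(inherits(a, "annotation_set"), inherits(g, "go_ontology"))
  missing <- match.arg(missing)
  anc <- ancestor_closure(g)
  unknown <- setdiff(unique(unlist(a$sets)), g$terms)
  if (length(unknown) > 0) {
    if (missing == "error") {
      stopf("term(s) absent from ontology: %s", paste(unknown, collapse = ", "))
    }
    warnf("dropping %d term(s) absent from ontology", length(unknown))
  }
  sets <- lapply(a$sets, function(s) {
    s <- intersect(s, g$terms)
    unique(unlist(anc[s], use.names = FALSE))
  })
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) stopf("no protein retains any in-ontology term")
  annotation_set(sets, propagated = TRUE)
}

# how many proteins carry each term
term_counts <- function(a) {
  tab <- table(unlist(a$sets, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Term vocabularies
#'
#' A `term_vocabulary` is the ordered, frequency-filtered term list that
#' fixes the column index of every prediction matrix. Order is deterministic
#' (lexicographic by term id).
#'
#' @param terms character vector of term ids.
#' @param min_count the minimum count used to build the vocabulary (metadata).
#' @return an object of class `term_vocabulary`.
#' @export
term_vocabulary <- function(terms, min_count = 1L) {
  terms <- sort(unique(as.character(terms)))
  if (length(terms) == 0) stopf("empty vocabulary")
  structure(list(terms = terms,
                 index = stats::setNames(seq_along(terms), terms),
                 min_count = as.integer(min_count)),
            class = "term_vocabulary")
}

#' @export
print.term_vocabulary <- function(x, ...) {
  cat(sprintf("term_vocabulary: %d terms (min_count = %d)\n",
              length(x$terms), x$min_count))
  invisible(x)
}

#' Build the term vocabulary from annotation counts
#'
#' Keeps terms annotated to at least `min_count` proteins, sorted
#' lexicographically. Counting is done on the annotation set as given;
#' counting after propagation (so ancestors inherit the counts of their
#' descendants) is the standard choice for hierarchy-consistent classifier
#' targets, so pass a propagated set unless you have a reason not to.
#'
#' @param a an [annotation_set()].
#' @param min_count integer >= 1; frequency threshold, inclusive.
#' @return a [term_vocabulary()].
#' @export
build_vocabulary <- function(a, min_count = 50L) {
  stopifnot(inherits(a, "annotation_set"))
  if (min_count < 1) stopf("min_count must be >= 1")
  counts <- term_counts(a)
  kept <- names(counts)[counts >= min_count]
  if (length(kept) == 0) {
    stopf("no term reaches min_count = %d", min_count)
  }
  term_vocabulary(kept, min_count = min_count)
}

#' Restrict an annotation set to a vocabulary
#'
#' Drops terms outside the vocabulary; proteins left with no vocabulary term
#' are removed. Restriction is applied after propagation in all pipelines in
#' this package.
#'
#' @param a an [annotation_set()].
#' @param vocab a [term_vocabulary()].
#' @return an [annotation_set()] with the same `propagated` flag.
#' @export
restrict_annotations <- function(a, vocab) {
  stopifnot(inherits(a, "annotation_set"), inherits(vocab, "term_vocabulary"))
  sets <- lapply(a$sets, function(s) intersect(s, vocab$terms))
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) stopf("no protein has any vocabulary term")
  annotation_set(sets, propagated = a$propagated)
}

#' Subset an annotation set to chosen proteins
#'
#' @param a an [annotation_set()].
#' @param proteins character vector of protein ids to keep.
#' @return an [annotation_set()].
#' @export
subset_annotations <- function(a, proteins) {
  stopifnot(inherits(a, "annotation_set"))
  keep <- intersect(names(a$sets), proteins)
  if (length(keep) == 0) stopf("no requested protein present in annotations")
  annotation_set(a$sets[keep], propagated = a$propagated)
}

#' Write annotations as a two-column TSV
#'
#' @param a an [annotation_set()].
#' @param path output path (`protein_id<TAB>term_id`, one row per pair).
#' @export
write_annotations <- function(a, path) {
  stopifnot(inherits(a, "annotation_set"))
  prot <- rep(names(a$sets), lengths(a$sets))
  df <- data.frame(protein = prot, term = unlist(a$sets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
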
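#' Ontology graphs
#'
#' A `go_ontology` is a directed acyclic graph over GO-style terms. Edges
#' point from child to parent and are restricted at construction time to a
#' chosen relation set (by default `is_a` and `part_of`, the usual GOA
#' propagation convention). Obsolete terms and cross-namespace edges are
#' dropped when parsing OBO files.
#'
#' @param terms character vector of term ids.
#' @param parents named list mapping each term id to a character vector of
#'   parent term ids (empty vector for roots).
#' @param name,namespace optional named character vectors of term names and
#'   namespace labels, keyed by term id.
#' @return an object of class `go_ontology`.
#' @export
ontology <- function(terms, parents, name = NULL, namespace = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stopf("duplicate term ids in ontology")
  parents <- parents[terms]
  names(parents) <- terms
  parents <- lapply(parents, function(p) {
    p <- unique(as.character(p %||% character()))
    p
  })
  bad <- setdiff(unlist(parents), terms)
  if (length(bad) > 0) {
    stopf("parent term(s) absent from ontology: %s", paste(bad, collapse = ", "))
  }
  g <- structure(
    list(
      terms = terms,
      parents = parents,
      name = name %||% stats::setNames(terms, terms),
      namespace = namespace %||% stats::setNames(rep("unknown", length(terms)), terms)
    ),
    class = "go_ontology"
  )
  cyc <- find_cycle_member(g)
  if (!is.null(cyc)) {
    stopf("ontology contains a cycle through term %s", cyc)
  }
  g
}

# Kahn topological sort over child->parent edges. Returns NULL if acyclic,
# otherwise one term id on a cycle.
find_cycle_member <- function(g) {
  nparents <- lengths(g$parents)
  children <- ontology_children(g)
  # process terms whose parents are all processed: peel roots of reversed graph
  outdeg <- nparents
  queue <- g$terms[outdeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(g$terms)) return(NULL)
  g$terms[outdeg > 0L][[1L]]
}

# child lists (reverse edges), named list keyed by term id
ontology_children <- function(g) {
  ch <- lapply(g$terms, function(x) character())
  names(ch) <- g$terms
  for (t in g$terms) {
    for (p in g$parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  }
  ch
}

#' @export
print.go_ontology <- function(x, ...) {
  nedges <- sum(lengths(x$parents))
  roots <- sum(lengths(x$parents) == 0L)
  cat(sprintf("go_ontology: %d terms, %d edges, %d root(s)\n",
              length(x$terms), nedges, roots))
  invisible(x)
}

#' Load an ontology from an OBO file
#'
#' Parses OBO 1.2/1.4 flat files. Only `[Term]` stanzas are read; obsolete
#' terms are excluded, and edges are restricted to the requested relation
#' types. Edges crossing namespaces, or pointing at terms absent from the
#' file (e.g. obsolete parents), are dropped. Acyclicity is verified.
#'
#' @param path path to an OBO file.
#' @param relations character subset of `c("is_a", "part_of")`; which
#'   relations become edges.
#' @return a [ontology()] object.
#' @export
load_obo <- function(path, relations = c("is_a", "part_of")) {
  if (!file.exists(path)) stopf("OBO file not found: %s", path)
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(trimws(lines) == "[Term]")
  if (length(term_starts) == 0) {
    stopf("format error: no [Term] stanza found in %s", path)
  }
  stanza_starts <- which(grepl("^\\[.*\\]\\s*$", lines))
  ids <- character(); nm <- character(); ns <- character()
  parents <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    kv <- regmatches(block, regexec("^([A-Za-z_]+):\\s*(.*)$", block))
    keys <- vapply(kv, function(m) if (length(m) == 3) m[[2]] else NA_character_, "")
    vals <- vapply(kv, function(m) if (length(m) == 3) m[[3]] else NA_character_, "")
    id <- vals[keys == "id"][1]
    if (is.na(id)) stopf("format error: [Term] stanza without id near line %d", s)
    id <- strip_obo_comment(id)
    if (any(keys == "is_obsolete" & grepl("^true", vals))) next
    ids <- c(ids, id)
    nm[id] <- strip_obo_comment(vals[keys == "name"][1] %||% id)
    ns[id] <- strip_obo_comment(vals[keys == "namespace"][1] %||% "unknown")
    par <- character()
    if ("is_a" %in% relations) {
      par <- c(par, vapply(vals[keys == "is_a"], strip_obo_comment, ""))
    }
    if ("part_of" %in% relations) {
      rel <- vals[keys == "relationship"]
      rel <- rel[grepl("^part_of\\s", rel)]
      par <- c(par, vapply(sub("^part_of\\s+", "", rel), strip_obo_comment, ""))
    }
    parents[[id]] <- unname(par)
  }
  if (anyDuplicated(ids)) stopf("format error: duplicate term id %s",
                                ids[duplicated(ids)][1])
  # drop edges to absent (e.g. obsolete) terms and across namespaces
  parents <- lapply(ids, function(id) {
    p <- intersect(parents[[id]], ids)
    p[ns[p] == ns[[id]]]
  })
  names(parents) <- ids
  ontology(ids, parents, name = nm[ids], namespace = ns[ids])
}

strip_obo_comment <- function(x) {
  if (is.na(x)) return(x)
  trimws(sub("\\s*!.*$", "", x))
}

#' Ancestors of a term
#'
#' Reflexive transitive closure over parent edges: the returned set always
#' contains the query term itself.
#'
#' @param g a [ontology()] object.
#' @param term a term id present in `g`.
#' @return character vector of ancestor term ids (including `term`).
#' @export
ancestors <- function(g, term) {
  stopifnot(inherits(g, "go_ontology"))
  if (!term %in% g$terms) stopf("unknown term: %s", term)
  out <- character()
  queue <- term
  while (length(queue) > 0) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    if (t %in% out) next
    out <- c(out, t)
    queue <- c(queue, setdiff(g$parents[[t]], out))
  }
  sort(out)
}

# Ancestor closure for every term, computed bottom-up in topological order.
# Returns a named list id -> character vector (reflexive).
ancestor_closure <- function(g) {
  order <- topo_order(g)
  anc <- vector("list", length(g$terms))
  names(anc) <- g$terms
  for (t in order) {  # parents before children
    a <- t
    for (p in g$parents[[t]]) a <- c(a, anc[[p]])
    anc[[t]] <- unique(a)
  }
  anc
}

# terms ordered so that every parent precedes its children
topo_order <- function(g) {
  remaining_parents <- lengths(g$parents)
  children <- ontology_children(g)
  queue <- g$terms[remaining_parents == 0L]
  out <- character()
  while (length(queue) > 0) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, t)
    for (ch in children[[t]]) {
      remaining_parents[[ch]] <- remaining_parents[[ch]] - 1L
      if (remaining_parents[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Information content of vocabulary terms
#'
#' Computes per-term information content (bits) from propagated training
#' annotations: `IC(t) = -log2(count(t) / N)` with `N` the number of
#' annotated proteins (marginal mode). Conditional mode instead divides by
#' the number of proteins annotated with all of the term's parents,
#' `IC(t) = -log2(count(t) / count(parents all present))`, the convention of
#' several CAFA evaluations; it requires `g`.
#'
#' @param annotations a propagated [annotation_set()].
#' @param vocab a [term_vocabulary()]; every vocabulary term must occur at
#'   least once in `annotations`.
#' @param mode `"marginal"` (default) or `"conditional"`.
#' @param g ontology, required for `mode = "conditional"`.
#' @return named numeric vector of information content values (bits).
#' @export
information_content <- function(annotations, vocab,
                                mode = c("marginal", "conditional"),
                                g = NULL) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(vocab, "term_vocabulary"))
  mode <- match.arg(mode)
  if (!annotations$propagated) {
    stopf("information_content requires propagated annotations")
  }
  n <- length(annotations$sets)
  counts <- term_counts(annotations)
  cnt <- counts[vocab$terms]
  cnt[is.na(cnt)] <- 0
  if (any(cnt == 0)) {
    stopf("vocabulary term(s) with zero occurrences: %s",
          paste(vocab$terms[cnt == 0], collapse = ", "))
  }
  if (mode == "marginal") {
    ic <- -log2(cnt / n)
  } else {
    if (is.null(g)) stopf("conditional IC requires the ontology `g`")
    denom <- vapply(vocab$terms, function(t) {
      par <- g$parents[[t]] %||% character()
      if (length(par) == 0) return(n)
      sum(vapply(annotations$sets, function(s) all(par %in% s), logical(1)))
    }, numeric(1))
    ic <- -log2(cnt / denom)
  }
  names(ic) <- vocab$terms
  pmax(ic, 0)
}
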
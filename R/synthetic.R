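#' Synthetic dataset configuration
#'
#' Fixes the generating conditions for fully self-contained fixtures with
#' the statistical structure the toolkit assumes: a toy GO-like DAG,
#' family-structured proteins whose family determines the annotation
#' template, embeddings as separable point clouds per family, sequences
#' carrying family-specific motifs, and a similarity hit table.
#'
#' @param n_families number of protein families.
#' @param proteins_per_family members per family.
#' @param dim embedding dimension.
#' @param separation ratio of between-family center distance to
#'   within-family spread; family centers are placed with pairwise
#'   distances of at least `separation * within_sd`.
#' @param n_terms number of ontology terms (including the root).
#' @param depth depth of the generated DAG.
#' @param terms_per_family base (pre-closure) terms in a family's template.
#' @param seq_length sequence length.
#' @param motif_length length of the family motif implanted in sequences.
#' @param noise label flip-noise rate in `[0, 1)`, applied to the
#'   ancestor-closed template before re-closure.
#' @param within_sd within-family embedding standard deviation.
#' @param cross_edge_frac fraction of terms receiving an extra cross edge
#'   to a shallower level.
#' @param cross_hit_rate probability that a cross-family protein pair gets
#'   an insignificant similarity hit.
#' @param seed integer seed; every generated artifact is a deterministic
#'   function of the full configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_families = 5L, proteins_per_family = 20L,
                         dim = 16L, separation = 5, n_terms = 30L,
                         depth = 3L, terms_per_family = 3L,
                         seq_length = 120L, motif_length = 10L,
                         noise = 0, within_sd = 1,
                         cross_edge_frac = 0.1, cross_hit_rate = 0.05,
                         seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              proteins_per_family = as.integer(proteins_per_family),
              dim = as.integer(dim), separation = separation,
              n_terms = as.integer(n_terms), depth = as.integer(depth),
              terms_per_family = as.integer(terms_per_family),
              seq_length = as.integer(seq_length),
              motif_length = as.integer(motif_length),
              noise = noise, within_sd = within_sd,
              cross_edge_frac = cross_edge_frac,
              cross_hit_rate = cross_hit_rate, seed = as.integer(seed))
  stopifnot(cfg$n_families >= 1, cfg$proteins_per_family >= 1, cfg$dim >= 1,
            cfg$separation > 0, cfg$n_terms > cfg$depth,
            cfg$terms_per_family >= 1, cfg$noise >= 0, cfg$noise < 1,
            cfg$motif_length <= cfg$seq_length)
  structure(cfg, class = "synth_config")
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a toy GO-like ontology
#'
#' A rooted random DAG: terms are spread over `depth` levels below a single
#' root, each term gets one parent on the level above, and a seeded
#' fraction of terms receive one extra edge to a strictly shallower level.
#' Edges only point toward shallower levels, so the graph is acyclic by
#' construction.
#'
#' @param cfg a [synth_config()].
#' @return a [ontology()] object.
#' @export
gen_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  ids <- sprintf("GO:%07d", seq_len(cfg$n_terms))
  with_seed(cfg$seed, {
    # level 0 = root; every level 1..depth nonempty
    level <- c(0L, rep(seq_len(cfg$depth), length.out = cfg$n_terms - 1L))
    if (cfg$n_terms > cfg$depth + 1L) {
      extra <- sample(seq_len(cfg$depth), cfg$n_terms - 1L - cfg$depth,
                      replace = TRUE)
      level <- c(0L, seq_len(cfg$depth), sort(extra))
    }
    parents <- vector("list", cfg$n_terms)
    names(parents) <- ids
    for (i in seq_along(ids)) {
      if (level[i] == 0L) {
        parents[[i]] <- character()
        next
      }
      above <- ids[level == level[i] - 1L]
      p <- if (length(above) == 1L) above else sample(above, 1L)
      shallower <- setdiff(ids[level < level[i]], p)
      if (length(shallower) > 0 && stats::runif(1) < cfg$cross_edge_frac) {
        extra_p <- if (length(shallower) == 1L) shallower
                   else sample(shallower, 1L)
        p <- c(p, extra_p)
      }
      parents[[i]] <- p
    }
    ontology(ids, parents,
             name = stats::setNames(paste("term", seq_along(ids)), ids),
             namespace = stats::setNames(rep("toy_process", length(ids)), ids))
  })
}

#' Generate a family-structured synthetic dataset
#'
#' Each family receives: a label template (a random subset of non-root
#' terms plus their ancestors) applied to every member with independent
#' flip noise and then re-closed under ancestors; an embedding center on a
#' sphere whose pairwise center distances are at least
#' `separation * within_sd`, members scattered isotropically around it; and
#' a family-specific motif implanted at a random position in otherwise
#' uniform-random amino-acid sequences.
#'
#' @param cfg a [synth_config()].
#' @param g the ontology from [gen_ontology()] (or any [ontology()] whose
#'   term count matches `cfg`).
#' @return list with `sequences` (named character vector), `annotations`
#'   (propagated [annotation_set()]), `embeddings` (matrix), `families`
#'   (named vector), `templates` (per-family closed term sets), `config`.
#' @export
gen_dataset <- function(cfg, g) {
  stopifnot(inherits(cfg, "synth_config"), inherits(g, "go_ontology"))
  non_root <- g$terms[lengths(g$parents) > 0]
  if (length(non_root) < cfg$terms_per_family) {
    stopf("ontology too small for %d terms per family", cfg$terms_per_family)
  }
  anc <- ancestor_closure(g)
  n <- cfg$n_families * cfg$proteins_per_family
  prot <- sprintf("P%04d", seq_len(n))
  fams <- sprintf("FAM%02d", seq_len(cfg$n_families))
  families <- stats::setNames(rep(fams, each = cfg$proteins_per_family), prot)
  with_seed(cfg$seed + 1L, {
    centers <- sample_separated_centers(cfg)
    templates <- lapply(fams, function(f) {
      base <- sample(non_root, cfg$terms_per_family)
      sort(unique(unlist(anc[base], use.names = FALSE)))
    })
    names(templates) <- fams
    emb <- matrix(0, n, cfg$dim, dimnames = list(prot, NULL))
    sets <- vector("list", n)
    names(sets) <- prot
    motifs <- vapply(fams, function(f) {
      paste(sample(AA_ALPHABET, cfg$motif_length, replace = TRUE),
            collapse = "")
    }, "")
    seqs <- character(n)
    names(seqs) <- prot
    for (i in seq_len(n)) {
      f <- families[[i]]
      fi <- match(f, fams)
      emb[i, ] <- centers[fi, ] + stats::rnorm(cfg$dim, sd = cfg$within_sd)
      tpl <- templates[[f]]
      s <- tpl
      if (cfg$noise > 0) {
        s <- tpl[stats::runif(length(tpl)) >= cfg$noise]
        others <- setdiff(non_root, tpl)
        add_p <- cfg$noise * length(tpl) / max(length(others), 1L)
        s <- c(s, others[stats::runif(length(others)) < add_p])
        if (length(s) == 0) s <- sample(tpl, 1L)
      }
      sets[[i]] <- sort(unique(unlist(anc[s], use.names = FALSE)))
      body <- sample(AA_ALPHABET, cfg$seq_length, replace = TRUE)
      pos <- sample.int(cfg$seq_length - cfg$motif_length + 1L, 1L)
      body[pos:(pos + cfg$motif_length - 1L)] <-
        strsplit(motifs[[fi]], "")[[1]]
      seqs[[i]] <- paste(body, collapse = "")
    }
    list(sequences = seqs,
         annotations = annotation_set(sets, propagated = TRUE),
         embeddings = emb, families = families,
         templates = templates, motifs = motifs, config = cfg)
  })
}

# family centers on a sphere of radius separation * within_sd; resample
# directions until the pairwise chord distances clear the target
sample_separated_centers <- function(cfg, max_tries = 100L) {
  target <- cfg$separation * cfg$within_sd
  radius <- target
  for (try in seq_len(max_tries)) {
    dirs <- matrix(stats::rnorm(cfg$n_families * cfg$dim), cfg$n_families)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    centers <- dirs * radius
    if (cfg$n_families == 1L) return(centers)
    d <- as.matrix(stats::dist(centers))
    if (min(d[upper.tri(d)]) >= target) return(centers)
    if (try %% 10L == 0L) radius <- radius * 1.5
  }
  stopf(paste0("could not place %d family centers at separation %g in ",
               "%d dimensions; try a higher embedding dimension"),
        cfg$n_families, cfg$separation, cfg$dim)
}

#' Generate a synthetic similarity hit table
#'
#' Within-family pairs receive significant hits (e-value 1e-30) with
#' bitscores decreasing in embedding distance,
#' `b = max(round(200 exp(-d / sigma)), 1)` with `sigma` the within-family
#' spread; a seeded fraction of cross-family pairs receive low-bitscore
#' hits with e-values above 0.001, so novel-subset logic is exercisable.
#'
#' @param emb embedding matrix with protein row names.
#' @param families named vector protein id -> family.
#' @param cfg a [synth_config()].
#' @param queries,subjects optional id subsets (default: all proteins);
#'   self-hits are never emitted.
#' @return a [hit_table()].
#' @export
gen_hits <- function(emb, families, cfg, queries = NULL, subjects = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  emb <- validate_embeddings(emb)
  queries <- queries %||% rownames(emb)
  subjects <- subjects %||% rownames(emb)
  with_seed(cfg$seed + 2L, {
    q <- character(); s <- character(); b <- numeric(); e <- numeric()
    for (qq in queries) {
      for (ss in subjects) {
        if (qq == ss) next
        if (families[[qq]] == families[[ss]]) {
          d <- sqrt(sum((emb[qq, ] - emb[ss, ])^2))
          q <- c(q, qq); s <- c(s, ss)
          b <- c(b, max(round(200 * exp(-d / cfg$within_sd)), 1))
          e <- c(e, 1e-30)
        } else if (stats::runif(1) < cfg$cross_hit_rate) {
          q <- c(q, qq); s <- c(s, ss)
          b <- c(b, sample(20:40, 1L))
          e <- c(e, stats::runif(1, 0.01, 10))
        }
      }
    }
    hit_table(q, s, b, e)
  })
}

#' Write a synthetic dataset to a fixture directory
#'
#' Emits `go.obo` (toy OBO dialect), `proteins.fasta`, `annotations.tsv`,
#' `embeddings.tsv`, `families.tsv` and `hits.tsv`.
#'
#' @param ds a [gen_dataset()] result.
#' @param g the matching ontology.
#' @param dir output directory (created if absent).
#' @param hits optional [gen_hits()] table to include.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, g, dir, hits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(g, file.path(dir, "go.obo"))
  aa <- Biostrings::AAStringSet(ds$sequences)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.fasta"))
  write_annotations(ds$annotations, file.path(dir, "annotations.tsv"))
  write_embeddings(ds$embeddings, file.path(dir, "embeddings.tsv"))
  utils::write.table(
    data.frame(protein = names(ds$families), family = unname(ds$families)),
    file.path(dir, "families.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  if (!is.null(hits)) write_hits(hits, file.path(dir, "hits.tsv"))
  invisible(dir)
}

#' Write an ontology as a minimal OBO file
#'
#' @param g a [ontology()].
#' @param path output path.
#' @export
write_obo <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in g$terms) {
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", g$name[[t]]),
                 paste0("namespace: ", g$namespace[[t]]),
                 paste0("is_a: ", g$parents[[t]]),
                 ""), con)
  }
  invisible(path)
}

#' Write a hit table as 12-column BLAST tabular output
#'
#' Alignment coordinate columns not modelled by the generator are filled
#' with placeholder values; e-value and bitscore occupy their standard
#' positions 11 and 12.
#'
#' @param hits a [hit_table()].
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  df <- data.frame(q = hits$query, s = hits$subject,
                   pident = rep(90, n), len = rep(100, n),
                   mm = rep(0, n), go = rep(0, n),
                   qs = rep(1, n), qe = rep(100, n),
                   ss = rep(1, n), se = rep(100, n),
                   evalue = formatC(hits$evalue, format = "g", digits = 6),
                   bitscore = hits$bitscore)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
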
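test_that("OBO parsing keeps non-obsolete terms and requested relations", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: toy", "",
    "[Term]", "id: GO:0000002", "name: a", "namespace: toy",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: b", "namespace: toy",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: c", "namespace: toy",
    "relationship: part_of GO:0000002", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000005", "name: gone", "namespace: toy",
    "is_a: GO:0000001", "is_obsolete: true", ""
  ), obo)
  g <- load_obo(obo)
  expect_length(g$terms, 4)
  expect_false("GO:0000005" %in% g$terms)
  expect_equal(sum(lengths(g$parents)), 4)  # 3 is_a + 1 part_of
  g_isa <- load_obo(obo, relations = "is_a")
  expect_equal(sum(lengths(g_isa$parents)), 3)
  expect_setequal(g_isa$parents[["GO:0000004"]], "GO:0000001")
})

test_that("OBO cycles are rejected with a named cycle member", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: a", "name: a", "namespace: toy", "is_a: b", "",
    "[Term]", "id: b", "name: b", "namespace: toy", "is_a: a", ""
  ), obo)
  expect_error(load_obo(obo), "cycle")
  expect_error(load_obo(tempfile()), "not found")
  empty <- tempfile(); writeLines("format-version: 1.2", empty)
  expect_error(load_obo(empty), "format error")
})

test_that("cross-namespace edges are dropped at parse time", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: r1", "name: r1", "namespace: ns1", "",
    "[Term]", "id: r2", "name: r2", "namespace: ns2", "",
    "[Term]", "id: x", "name: x", "namespace: ns1",
    "is_a: r1", "is_a: r2", ""
  ), obo)
  g <- load_obo(obo)
  expect_equal(g$parents[["x"]], "r1")
})

test_that("ancestors returns the reflexive transitive closure", {
  expect_equal(ancestors(chain_ontology(), "root"), "root")
  expect_setequal(ancestors(chain_ontology(), "d"), c("d", "c", "b", "root"))
  expect_setequal(ancestors(diamond_ontology(), "d"), c("d", "b", "c", "a"))
  expect_error(ancestors(chain_ontology(), "nope"), "unknown term")
})

test_that("ancestors agrees with a breadth-first closure oracle on random DAGs", {
  for (seed in 1:3) {
    cfg <- synth_config(n_terms = 40, depth = 4, seed = seed)
    g <- gen_ontology(cfg)
    child <- rep(g$terms, lengths(g$parents))
    parent <- unlist(g$parents, use.names = FALSE)
    for (t in sample(g$terms, 10)) {
      expect_equal(ancestors(g, t), closure_oracle(child, parent, t))
    }
  }
})

test_that("ancestor sets contain every parent's ancestor set", {
  g <- gen_ontology(synth_config(n_terms = 30, depth = 3, seed = 2))
  for (t in g$terms) {
    a <- ancestors(g, t)
    for (p in g$parents[[t]]) {
      expect_true(all(ancestors(g, p) %in% a))
    }
  }
})

test_that("information content matches -log2 frequency and its edge cases", {
  g <- chain_ontology()
  sets <- list(P1 = c("d", "c", "b", "root"), P2 = c("c", "b", "root"),
               P3 = c("b", "root"), P4 = c("b", "root"),
               P5 = "root", P6 = "root", P7 = "root", P8 = "root")
  a <- annotation_set(sets, propagated = TRUE)
  vocab <- term_vocabulary(c("root", "b", "c", "d"))
  ic <- information_content(a, vocab)
  expect_equal(unname(ic["root"]), 0)          # in all 8 proteins
  expect_equal(unname(ic["b"]), 1)             # in 4 of 8
  expect_equal(unname(ic["c"]), 2)             # in 2 of 8
  expect_equal(unname(ic["d"]), 3)             # in 1 of 8
  expect_error(information_content(annotation_set(sets), vocab), "propagated")
  expect_error(
    information_content(a, term_vocabulary(c("root", "zz"))), "zero")
})

test_that("IC is antitone in term frequency and child-monotone after propagation", {
  fx <- default_dataset(seed = 4, noise = 0.1)
  ic <- information_content(fx$ds$annotations, fx$vocab)
  counts <- table(unlist(fx$ds$annotations$sets))[fx$vocab$terms]
  ord <- order(counts)
  expect_true(all(diff(ic[fx$vocab$terms[ord]]) <= 1e-12))
  for (t in fx$vocab$terms) {
    for (p in intersect(fx$g$parents[[t]], fx$vocab$terms)) {
      expect_lte(ic[[p]], ic[[t]] + 1e-12)
    }
  }
})

test_that("conditional IC is relative to parents being present", {
  g <- chain_ontology()
  a <- annotation_set(list(P1 = c("d", "c", "b", "root"),
                           P2 = c("c", "b", "root"),
                           P3 = c("b", "root"), P4 = "root"),
                      propagated = TRUE)
  vocab <- term_vocabulary(c("root", "b", "c", "d"))
  ic <- information_content(a, vocab, mode = "conditional", g = g)
  # d occurs in 1 of the 2 proteins that have its parent c
  expect_equal(unname(ic["d"]), 1)
  expect_equal(unname(ic["root"]), 0)  # no parents: -log2(4/4)
})

test_that("constructed ontologies reject cycles and unknown parents", {
  expect_error(ontology(c("a", "b"), list(a = "b", b = "a")), "cycle")
  expect_error(ontology("a", list(a = "zz")), "absent")
})
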
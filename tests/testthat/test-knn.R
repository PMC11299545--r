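toy_index <- function(metric = "euclidean") {
  emb <- rbind(A = c(0, 0), B = c(2, 0), C = c(0, 4))
  labels <- annotation_set(list(A = "g1", B = c("g1", "g2"), C = "g2"),
                           propagated = TRUE)
  build_index(emb, labels, term_vocabulary(c("g1", "g2")), metric = metric)
}

test_that("index construction enforces its preconditions", {
  idx <- toy_index()
  expect_equal(nrow(idx$emb), 3)
  labels <- annotation_set(list(A = "g1", Z = "g2"), propagated = TRUE)
  expect_error(
    build_index(rbind(A = c(0, 0)), labels, term_vocabulary(c("g1", "g2"))),
    "Z")
  expect_error(toy_index("manhattan"))
})

test_that("single-neighbour prediction is the neighbour's label indicator", {
  idx <- toy_index()
  p <- knn_predict(idx, rbind(Q = c(0.1, 0)), k = 1)
  expect_equal(p["Q", ], c(g1 = 1, g2 = 0))
})

test_that("inverse-distance weights give the hand-computed fraction", {
  # neighbours at distances 1 and 3; only the nearer carries g1
  emb <- rbind(A = c(1, 0), B = c(3, 0))
  labels <- annotation_set(list(A = "g1", B = "g2"), propagated = TRUE)
  idx <- build_index(emb, labels, term_vocabulary(c("g1", "g2")))
  p <- knn_predict(idx, rbind(Q = c(0, 0)), k = 2)
  expect_equal(p["Q", "g1"], (1 / 1) / (1 / 1 + 1 / 3))  # 0.75
  expect_equal(p["Q", "g2"], (1 / 3) / (1 / 1 + 1 / 3))
})

test_that("unanimous neighbourhoods give 0/1 indicators under any weighting", {
  set.seed(3)
  emb <- matrix(rnorm(10 * 4), 10, dimnames = list(sprintf("T%02d", 1:10), NULL))
  labels <- annotation_set(stats::setNames(
    rep(list(c("g1", "g3")), 10), rownames(emb)), propagated = TRUE)
  idx <- build_index(emb, labels, term_vocabulary(c("g1", "g2", "g3")))
  for (w in c("inverse_distance", "uniform")) {
    p <- knn_predict(idx, rbind(Q = rnorm(4)), k = 5, weighting = w)
    expect_equal(p["Q", ], c(g1 = 1, g2 = 0, g3 = 1))
  }
})

test_that("exact duplicates dominate via the uniform-over-duplicates rule", {
  emb <- rbind(A = c(0, 0), B = c(0, 0), C = c(5, 5))
  labels <- annotation_set(list(A = "g1", B = "g2", C = "g2"),
                           propagated = TRUE)
  idx <- build_index(emb, labels, term_vocabulary(c("g1", "g2")))
  p <- knn_predict(idx, rbind(Q = c(0, 0)), k = 3)
  expect_equal(p["Q", ], c(g1 = 0.5, g2 = 0.5))
})

test_that("knn_predict matches the brute-force oracle exactly", {
  fx <- default_dataset(seed = 13, separation = 2)  # overlapping clouds
  sp <- half_split(fx$ds$families)
  train_ann <- subset_annotations(fx$ds$annotations, sp$train)
  queries <- fx$ds$embeddings[sp$test[1:20], , drop = FALSE]
  label_sets <- restrict_annotations(train_ann, fx$vocab)$sets
  for (metric in c("euclidean", "cosine")) {
    idx <- build_index(fx$ds$embeddings[sp$train, ], train_ann, fx$vocab,
                       metric = metric)
    for (w in c("inverse_distance", "uniform")) {
      for (k in c(1, 3, 5)) {
        got <- knn_predict(idx, queries, k = k, weighting = w)
        want <- knn_oracle(fx$ds$embeddings[sp$train, ], label_sets,
                           fx$vocab$terms, queries, k, metric, w)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("scores are bounded and uniform scores are k-denominators", {
  fx <- default_dataset(seed = 5)
  sp <- half_split(fx$ds$families)
  idx <- build_index(fx$ds$embeddings[sp$train, ],
                     subset_annotations(fx$ds$annotations, sp$train),
                     fx$vocab)
  p <- knn_predict(idx, fx$ds$embeddings[sp$test, ], k = 5,
                   weighting = "uniform")
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(abs(p * 5 - round(p * 5)) < 1e-9))
})

test_that("predictions are invariant to permuting the training rows", {
  fx <- default_dataset(seed = 21)
  sp <- half_split(fx$ds$families)
  train <- fx$ds$embeddings[sp$train, ]
  ann <- subset_annotations(fx$ds$annotations, sp$train)
  q <- fx$ds$embeddings[sp$test[1:10], ]
  p1 <- knn_predict(build_index(train, ann, fx$vocab), q, k = 5)
  set.seed(8)
  perm <- train[sample(nrow(train)), ]
  p2 <- knn_predict(build_index(perm, ann, fx$vocab), q, k = 5)
  expect_equal(p1, p2)
})

test_that("propagated reference labels make scores hierarchy-consistent", {
  fx <- default_dataset(seed = 17, noise = 0.1)
  sp <- half_split(fx$ds$families)
  idx <- build_index(fx$ds$embeddings[sp$train, ],
                     subset_annotations(fx$ds$annotations, sp$train),
                     fx$vocab)
  p <- knn_predict(idx, fx$ds$embeddings[sp$test, ], k = 5)
  for (t in fx$vocab$terms) {
    for (par in intersect(fx$g$parents[[t]], fx$vocab$terms)) {
      expect_true(all(p[, par] >= p[, t] - 1e-12))
    }
  }
})

test_that("k out of range and dimension mismatch are rejected", {
  idx <- toy_index()
  q <- rbind(Q = c(0, 0))
  expect_error(knn_predict(idx, q, k = 4), "out of range")
  expect_error(knn_predict(idx, rbind(Q = c(0, 0, 0)), k = 1), "dimension")
})
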
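two_protein_case <- function() {
  vocab <- term_vocabulary(c("a", "b"))
  pred <- prediction_matrix(
    rbind(P1 = c(0.9, 0.4), P2 = c(0.3, 0.8)), vocab)
  truth <- annotation_set(list(P1 = c("a", "b"), P2 = "a"), propagated = TRUE)
  list(pred = pred, truth = truth)
}

test_that("a perfect 0/1 predictor attains F-max 1 and S-min 0", {
  fx <- default_dataset(seed = 2)
  truth <- restrict_annotations(fx$ds$annotations, fx$vocab)
  pred <- annotation_matrix(truth, fx$vocab)
  expect_equal(pr_curve(pred, truth)$summary, 1)
  ic <- information_content(fx$ds$annotations, fx$vocab)
  expect_equal(smin_curve(pred, truth, ic)$summary, 0)
})

test_that("all-zero predictions give F-max 0 and a truth-IC S-min", {
  fx <- default_dataset(seed = 2)
  truth <- restrict_annotations(fx$ds$annotations, fx$vocab)
  pred <- annotation_matrix(truth, fx$vocab) * 0
  expect_equal(pr_curve(pred, truth)$summary, 0)
  ic <- information_content(fx$ds$annotations, fx$vocab)
  # hand sum: ru is constant at the mean total IC of each truth set, mi = 0
  ru <- mean(vapply(truth$sets, function(s) sum(ic[s]), numeric(1)))
  expect_equal(smin_curve(pred, truth, ic)$summary, ru)
  expect_equal(f_estimate_curve(pred, truth)$summary, 0)
})

test_that("the two-protein curve matches exhaustive confusion counting", {
  case <- two_protein_case()
  taus <- seq(0.2, 0.9, by = 0.1)
  got <- pr_curve(case$pred, case$truth, thresholds = taus)
  for (i in seq_along(taus)) {
    want <- pr_oracle_at(case$pred, case$truth$sets, taus[i])
    expect_equal(got$curve$precision[i], unname(want["precision"]))
    expect_equal(got$curve$recall[i], unname(want["recall"]))
    expect_equal(got$curve$f[i], unname(want["f"]))
  }
  # frozen oracle values: tau = 0.2 gives precision (1 + 1/2)/2, recall 1
  expect_equal(got$curve$f[1], 6 / 7)
  full <- pr_curve(case$pred, case$truth)
  expect_equal(full$summary, 6 / 7)
})

test_that("doubling information content doubles S-min", {
  fx <- default_dataset(seed = 6, noise = 0.15)
  sp <- half_split(fx$ds$families)
  idx <- build_index(fx$ds$embeddings[sp$train, ],
                     subset_annotations(fx$ds$annotations, sp$train), fx$vocab)
  pred <- knn_predict(idx, fx$ds$embeddings[sp$test, ], k = 5)
  truth <- subset_annotations(restrict_annotations(fx$ds$annotations, fx$vocab),
                              sp$test)
  ic <- information_content(fx$ds$annotations, fx$vocab)
  s1 <- smin_curve(pred, truth, ic)$summary
  s2 <- smin_curve(pred, truth, ic * 2)$summary
  expect_equal(s2, 2 * s1)
  expect_gt(s1, 0)
})

test_that("S-min requires IC coverage of the predicted terms", {
  case <- two_protein_case()
  expect_error(smin_curve(case$pred, case$truth, c(a = 1)), "missing")
})

test_that("F-estimate has the closed form v/t for a perfect predictor", {
  # 6 proteins, 10-term vocabulary, exactly 2 true terms each
  terms <- sprintf("g%02d", 1:10)
  sets <- lapply(1:6, function(i) terms[c(i, i + 1)])
  names(sets) <- sprintf("P%d", 1:6)
  truth <- annotation_set(sets, propagated = TRUE)
  vocab <- term_vocabulary(terms)
  pred <- annotation_matrix(truth, vocab)
  fe <- f_estimate_curve(pred, truth)
  expect_equal(fe$summary, 10 / 2)  # recall 1, q = t/v
})

test_that("F-max and S-min are invariant to monotone score transforms", {
  fx <- default_dataset(seed = 8, noise = 0.1)
  sp <- half_split(fx$ds$families)
  idx <- build_index(fx$ds$embeddings[sp$train, ],
                     subset_annotations(fx$ds$annotations, sp$train), fx$vocab)
  pred <- knn_predict(idx, fx$ds$embeddings[sp$test, ], k = 5)
  truth <- subset_annotations(restrict_annotations(fx$ds$annotations, fx$vocab),
                              sp$test)
  # strictly positive probabilities -> logit-like transform keeps order
  pred_pos <- pred * 0.98 + 0.01
  logits <- log(pred_pos / (1 - pred_pos))
  expect_equal(pr_curve(logits, truth)$summary,
               pr_curve(pred_pos, truth)$summary, tolerance = 1e-10)
  ic <- information_content(fx$ds$annotations, fx$vocab)
  expect_equal(smin_curve(logits, truth, ic)$summary,
               smin_curve(pred_pos, truth, ic)$summary, tolerance = 1e-10)
})

test_that("protein set mismatches are reported with the difference", {
  case <- two_protein_case()
  truth_bad <- annotation_set(list(P1 = "a", P9 = "a"), propagated = TRUE)
  expect_error(pr_curve(case$pred, truth_bad), "P9")
})

test_that("per-class F1 follows binary confusion arithmetic at 0.5", {
  vocab <- term_vocabulary(c("a", "b", "c"))
  pred <- prediction_matrix(rbind(P1 = c(0.9, 0.6, 0.1),
                                  P2 = c(0.8, 0.2, 0.2),
                                  P3 = c(0.1, 0.7, 0.3)), vocab)
  truth <- annotation_set(list(P1 = c("a", "b"), P2 = "a", P3 = "c"),
                          propagated = TRUE)
  f1 <- per_class_f1(pred, truth)
  expect_equal(unname(f1["a"]), 1)        # perfect
  expect_equal(unname(f1["b"]), 2 / 3)    # TP=1 FP=1 FN=0
  expect_equal(unname(f1["c"]), 0)        # never predicted, one truth
  expect_error(per_class_f1(pred, truth, threshold = 0), "threshold")
})

test_that("max-upward score propagation enforces parent >= child", {
  g <- chain_ontology()
  vocab <- term_vocabulary(c("root", "b", "c", "d"))
  pred <- prediction_matrix(rbind(P1 = c(0.1, 0.2, 0.9, 0.5)), vocab)
  # columns are sorted: b, c, d, root
  out <- propagate_scores(pred, g)
  expect_equal(out["P1", "root"], max(pred["P1", ]))
  expect_gte(out["P1", "b"], out["P1", "c"])
  expect_gte(out["P1", "c"], out["P1", "d"])
  # already-consistent predictions are unchanged
  fx <- default_dataset(seed = 12)
  sp <- half_split(fx$ds$families)
  idx <- build_index(fx$ds$embeddings[sp$train, ],
                     subset_annotations(fx$ds$annotations, sp$train), fx$vocab)
  p <- knn_predict(idx, fx$ds$embeddings[sp$test, ], k = 5)
  expect_equal(propagate_scores(p, fx$g), p)
})

test_that("F-estimate ranks predictors like F-max on complete labels", {
  fx <- default_dataset(seed = 40, separation = 3, noise = 0.05)
  sp <- half_split(fx$ds$families)
  train_ann <- subset_annotations(fx$ds$annotations, sp$train)
  truth <- subset_annotations(restrict_annotations(fx$ds$annotations, fx$vocab),
                              sp$test)
  idx <- build_index(fx$ds$embeddings[sp$train, ], train_ann, fx$vocab)
  hits <- gen_hits(fx$ds$embeddings, fx$ds$families, fx$cfg,
                   queries = sp$test, subjects = sp$train)
  knn5 <- knn_predict(idx, fx$ds$embeddings[sp$test, ], k = 5)
  set.seed(99)
  corrupted <- 0.6 * knn5 + 0.4 * matrix(runif(length(knn5)), nrow(knn5),
                                         dimnames = dimnames(knn5))
  preds <- list(
    knn1 = knn_predict(idx, fx$ds$embeddings[sp$test, ], k = 1),
    knn5 = knn5,
    knn15u = knn_predict(idx, fx$ds$embeddings[sp$test, ], k = 15,
                         weighting = "uniform"),
    blast = blast_predict(hits, train_ann, fx$vocab, queries = sp$test),
    naive = naive_predict(train_ann, fx$vocab, sp$test),
    corrupted = corrupted)
  fmax <- vapply(preds, function(p) pr_curve(p, truth)$summary, numeric(1))
  femax <- vapply(preds, function(p) f_estimate_curve(p, truth)$summary,
                  numeric(1))
  expect_gte(cor(fmax, femax, method = "spearman"), 0.9)
})
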
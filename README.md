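# funtra — interpretable protein function annotation by similarity

Most proteins will never see a wet-lab functional assay; their Gene
Ontology (GO) annotations must be inferred. The most interpretable
inferences are transfers from similar, already-annotated proteins.
`funtra` is an R toolkit for doing and judging such transfers:

* **Multilabel KNN in embedding space.** Training proteins (embedded by
  any model — a protein language model's pooled token embeddings, a
  convolutional encoder, anything tabular) form a reference database. A
  query's score for term *g* is the weighted fraction of its *k* nearest
  neighbours annotated with *g*:
  `score(g) = Σ wᵢ·1[g ∈ Tᵢ] / Σ wᵢ`, with `wᵢ = 1/max(dᵢ, ε)`.
  Defaults: k = 5, Euclidean distance, inverse-distance weights, exact
  search, deterministic tie-breaks.
* **Bitscore-weighted transfer** from BLAST/DIAMOND tabular hits:
  `s(q, g) = Σ_B bits(q,B)·1[g ∈ T_B] / Σ_B bits(q,B)` over labelled hit
  subjects — a strong, classical baseline.
* **Naive prior baseline**: every query scores each term at its training
  frequency.
* **A CAFA-style evaluation suite**: protein-centric F-max; S-min over
  information-content-weighted false negatives/positives
  (`S = sqrt(ru² + mi²)`); a positive-unlabelled F-estimate
  (`FE = recall²/q`) for incomplete truth sets; term-centric F1; and a
  clustering protocol (mini-batch k-means + v-measure) that judges an
  embedding space without any classifier.
* **Ontology handling** (OBO parsing, ancestor closures, annotation
  propagation, frequency-filtered term vocabularies), **split regimes**
  (family-aware protein splits, GO-term holdout, the novel-protein subset
  with no significant hit against training data), a seeded
  **convolutional sequence encoder**, and a fully deterministic
  **synthetic data generator** used by the test suite.

## Worked example

Generate a family-structured synthetic dataset, transfer annotations to a
held-out half by KNN, and evaluate:

```r
library(funtra)

cfg <- synth_config(n_families = 5, proteins_per_family = 20, seed = 42)
g   <- gen_ontology(cfg)
ds  <- gen_dataset(cfg, g)
vocab <- build_vocabulary(ds$annotations, min_count = 1)
print(vocab)
#> term_vocabulary: 18 terms (min_count = 1)

test  <- names(ds$families)[seq(1, 100, by = 2)]
train <- setdiff(names(ds$families), test)
idx  <- build_index(ds$embeddings[train, ],
                    subset_annotations(ds$annotations, train), vocab)
pred <- knn_predict(idx, ds$embeddings[test, ], k = 5)
truth <- subset_annotations(restrict_annotations(ds$annotations, vocab), test)

pr_curve(pred, truth)
#> metric_curve: 22 thresholds; fmax = 1.0000 at tau = 0.6028
ic <- information_content(ds$annotations, vocab)
smin_curve(pred, truth, ic)
#> metric_curve: 22 thresholds; smin = 0.0000 at tau = 0.6028
naive <- naive_predict(subset_annotations(ds$annotations, train), vocab, test)
pr_curve(naive, truth)
#> metric_curve: 100 thresholds; fmax = 0.6061 at tau = 0.21
clustering_eval(ds$embeddings, ds$families, n_clusters = 5, seed = 1)
#> cluster_eval: v = 1.0000 (h = 1.0000, c = 1.0000), k = 5, batch = 32
```

Read: with clearly separated families and noise-free labels, five-neighbour
transfer recovers held-out annotations perfectly (F-max 1, S-min 0 — at the
optimal threshold there are no false positives or negatives), while the
frequency prior tops out at F-max 0.61; the embedding space itself clusters
exactly into the five families (v-measure 1). Dial `separation` and `noise`
down in `synth_config()` to watch all of these degrade.

The same steps are scriptable from a shell via the bundled CLI
(`exec/funtra`): `simulate`, `split`, `train-encoder`, `embed`,
`annotate-knn`, `annotate-blast`, `annotate-naive`, `evaluate`,
`cluster-eval`; every run writes a `.meta.json` with version, seed and
resolved options.

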
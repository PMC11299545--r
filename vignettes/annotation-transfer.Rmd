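---
title: "Annotation transfer by similarity: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation transfer by similarity: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funtra)
```

## The problem

Most proteins have no experimentally determined function. Function is
recorded as sets of Gene Ontology (GO) terms — a controlled vocabulary
organized as a directed acyclic graph in which annotating a term implies
all of its ancestors — and the practical question is how well functions can
be *transferred* from annotated proteins to unannotated ones by similarity.
`funtra` implements two interpretable transfer schemes, a trainable
convolutional classifier, and the evaluation machinery needed to compare
them fairly: protein-centric F-max, information-weighted S-min, a
positive-unlabelled F-estimate for incomplete truth sets, term-centric F1,
and an entropy-based clustering protocol for judging embedding spaces
directly.

Everything operates on five simple containers: an ontology DAG, an
annotation set (protein → term set, with a propagation flag), a term
vocabulary fixing column order, dense embedding matrices, and tabular
similarity hit tables in the 12-column BLAST/DIAMOND dialect.

## Annotation transfer models

**Multilabel KNN in embedding space.** Training proteins are embedded and
treated as a reference database; each carries its propagated,
vocabulary-restricted term set. For a query $q$ the $k$ nearest training
embeddings are found by exact search and each term $g$ is scored by the
weighted fraction of neighbours that carry it:

$$\hat p(g \mid q) \;=\; \frac{\sum_{i \in N_k(q)} w_i \, \mathbb{1}[g \in T_i]}
                              {\sum_{i \in N_k(q)} w_i},
\qquad w_i = \frac{1}{\max(d_i, \varepsilon)} .$$

Defaults are $k = 5$, Euclidean distance and inverse-distance weights,
which this family of methods finds near-optimal and robust. Scores lie in
$[0,1]$, and because every neighbour contributing a child term also
contributes its ancestors, predictions from propagated reference labels
are hierarchy-consistent by construction.

Numerical choices: ties at the $k$-th distance are broken by ascending
protein id, so predictions are invariant to the storage order of the
reference; $\varepsilon = 10^{-12}$ floors the inverse-distance weight, and
when one or more neighbours sit below $\varepsilon$ (exact duplicates of
the query) the score becomes the uniform average over those duplicates
alone — duplicates dominate, but never divide by zero.

**Bitscore-weighted transfer.** Given a similarity hit table, the score of
term $g$ for query $q$ is the bitscore-weighted average of the indicator
that each hit subject carries $g$:

$$s(q, g) \;=\; \frac{\sum_{B} \mathrm{bits}(q,B)\,\mathbb{1}[g \in T_B]}
                     {\sum_{B} \mathrm{bits}(q,B)} .$$

The sums run over hit subjects present in the labelled training set;
subjects without labels are excluded from numerator *and* denominator (and
counted in a report), so the score stays a proper weighted average on the
evidence that exists. Duplicate HSPs for a (query, subject) pair collapse
to the maximum bitscore. The score is invariant to rescaling a query's
bitscores by any positive constant, and a single hit reduces to that
subject's label indicator.

**Naive prior.** Every query receives each term's training frequency. This
is the floor any informative predictor must clear.

## Evaluation suite

A (protein, term) pair is *predicted* at threshold $\tau$ when its score is
at least $\tau$ and strictly positive; on the probability scale a score of
exactly zero means "no prediction" at any threshold, which gives the
all-zero matrix F-max 0 rather than a spurious full-recall point. The
default grid is the percent grid $\{0.01, \dots, 1.00\}$ united with all
achieved positive scores; for matrices whose values leave $[0,1]$ (logits)
the grid is the achieved values alone. Taking the grid over achieved
values makes F-max and S-min invariant to strictly monotone transforms of
the scores, so probability and logit outputs of the same ranker summarize
identically.

* **F-max** (protein-centric CAFA protocol): at each $\tau$, precision is
  averaged over proteins with at least one prediction, recall over all
  proteins; $F(\tau) = 2pr/(p+r)$ and F-max is the maximum over the grid.
* **S-min**: with information content $IC(t) = -\log_2(\mathrm{count}(t)/N)$
  computed from propagated training annotations, remaining uncertainty
  $ru(\tau)$ is the mean total IC of false negatives and misinformation
  $mi(\tau)$ of false positives; $S = \sqrt{ru^2 + mi^2}$, minimized over
  the grid. Rare, high-IC terms dominate, which is the point. A
  conditional-IC mode ($-\log_2$ of the frequency among proteins carrying
  all parents) is available behind a flag.
* **F-estimate**: annotation databases under-report true functions. Under
  missing-at-random negatives a quantity proportional to true F1 is
  estimable from positives alone: $FE(\tau) = r(\tau)^2 / q(\tau)$, where
  $q$ is the fraction of (protein, term) pairs predicted positive. The
  source literature defines this estimator only as "proportional to the
  true F1"; instantiating it as the positive-unlabelled $r^2/q$ form is an
  interpretive choice of this package, recorded here deliberately. FE
  values compare predictors on one dataset; they are not comparable across
  datasets.
* **Term-centric F1** at a fixed threshold (default 0.5) for per-class
  analysis.
* **Clustering protocol**: mini-batch k-means (batch size 32, k = known
  number of families, k-means++ initialization, 10 restarts keeping best
  inertia, fully seeded) on the embeddings, scored by the v-measure — the
  harmonic mean of homogeneity $1 - H(\mathrm{class}\mid\mathrm{cluster})/H(\mathrm{class})$
  and completeness $1 - H(\mathrm{cluster}\mid\mathrm{class})/H(\mathrm{cluster})$,
  with the usual conventions (a zero-entropy denominator scores 1;
  $v = 0$ when both components vanish).

Truth sets are always propagated before evaluation. Prediction matrices
can additionally be made hierarchy-consistent by `propagate_scores()`, a
max-upward pass; the `evaluate` CLI subcommand applies it by default
(`--no-propagate-scores` disables it). The metric functions themselves
evaluate the matrix they are given, so worked micro-examples stay exact.

## Split regimes

`family_split()` assigns whole families to one side (greedy fill of a
seeded shuffle until the test fraction is reached; overshoot is bounded by
the largest family), preventing evaluation on close homologs of training
proteins. `term_split()` holds out a random half of the vocabulary for
testing generalization to unseen GO classes. `novel_subset()` restricts a
test set to proteins with no similarity hit below e-value 0.001 against
training data — the regime where alignment transfer is uninformative by
construction and embedding methods must stand alone. Family definitions
are an input; when only a hit table is available,
`families_from_hits()` derives them as connected components of the
significant-hit graph.

## The convolutional encoder

The trainable baseline is a convolutional classifier in the DeepGOPlus
lineage: one-hot residues → parallel 1-D convolution banks of strictly
increasing kernel sizes → ReLU → global max-pool per filter →
concatenation → dense projection to the embedding dimension → linear head
with sigmoid outputs, trained to minimize mean per-term binary
cross-entropy with Adam under a slanted triangular learning-rate schedule
(10% linear warmup, linear decay to 1/32 of the peak, the ULMFiT
convention — the source method names the schedule without parameters).
Implementation is plain R matrix algebra with hand-written
backpropagation: convolution is a sliding-window matrix product (windows
of the row-major one-hot flattening are contiguous slices, so building
them is a single indexing operation), and max-pool gradients route to the
argmax position. Everything is seeded; identical configurations produce
bit-identical logs and weights. Residues outside the 20-letter alphabet
map to an unknown token and are counted in a report.

Defaults in `encoder_config()` follow the lineage's conventions (kernel
ladder up to 128, 512 filters); the test fixtures use a smaller
configuration (kernels {4, 8, 12}, 64 filters, embedding 32, learning rate
0.02, batch size 8, 5 epochs) chosen so that the head converges on a
100-protein training set within a small epoch budget on one CPU. The
hyperparameter search the source method runs (80 Bayesian-optimization
trials) is out of scope; `encoder_config()` is the hook a search would
drive. `pool()` is the only contract facing pretrained protein language
models: mean of residue embeddings plus the CLS-role vector, applied to
raw exported token embeddings. Running or fine-tuning such models is out
of scope; their exported tables enter through `read_embeddings()`.

## The synthetic generator

`synth_config()` fixes fully self-contained study conditions with the
statistical structure the toolkit assumes, and nothing more:

* a rooted random DAG (terms spread over `depth` levels, one parent on the
  level above, a seeded fraction of cross-edges to shallower levels —
  acyclic by construction);
* families whose label template is a random term subset plus ancestors,
  applied to members with independent flip noise and re-closed, so truth
  sets stay hierarchy-consistent at any noise rate;
* embedding clouds: family centers on a sphere with pairwise distances at
  least `separation` × the within-family standard deviation (directions
  resampled, with bounded radius escalation, else an error suggesting a
  higher dimension), members isotropic Gaussian around them;
* sequences: uniform-random amino acids with a family motif implanted at a
  random position;
* hit tables: within-family hits at e-value $10^{-30}$ with bitscore
  $\max(\mathrm{round}(200 e^{-d/\sigma}), 1)$ — an arbitrary but monotone
  map from embedding distance, which is all downstream code assumes — and
  a seeded fraction of insignificant cross-family hits (e-value > 0.001).

Defaults — 5 families × 20 proteins, dimension 16, separation 5, 30 terms,
depth 3, 3 base terms per family, length-120 sequences with length-10
motifs, zero label noise — are sized so a family is learnable from ~10
training examples yet the clouds are not trivially far apart, and so the
whole suite runs in seconds on one CPU. Every artifact is a deterministic
function of the configuration.

What the generator does *not* emulate: realistic sequence evolution,
power-law term frequencies, annotation biases that are correlated rather
than missing-at-random, and embedding geometry of real language models
(anisotropy, hubness). Tests passing on these fixtures therefore establish
the correctness of the algorithms and the internal consistency of the
evaluation protocol — not performance claims about real proteomes.

## Known limitations

* Exact neighbour search only; at reference sizes beyond ~10^5 an
  approximate index would be needed and is deliberately not provided.
* The F-estimate form $r^2/q$ is one defensible instantiation of a
  "proportional to F1" estimator; rankings, not absolute values, are the
  supported use.
* Marginal IC is the default; conditional IC is available but computed
  naively (per-term scan), which is fine at vocabulary sizes used here.
* The encoder is CPU-scale by design: correct, seeded, and small, not a
  performance reimplementation of GPU training.
* Whether propagation should cross `part_of` as well as `is_a` is
  convention-dependent; both relations are followed by default and the set
  is configurable in `load_obo()`.
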
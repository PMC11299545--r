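Package: funtra
Title: Interpretable Protein Function Annotation by Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for multilabel Gene Ontology annotation of proteins by
    similarity: exact K-nearest-neighbour annotation transfer in embedding
    space, bitscore-weighted transfer from BLAST/DIAMOND tabular hits, and a
    naive prior baseline, together with a CAFA-style evaluation suite (F-max,
    S-min, F-estimate, per-class F1, mini-batch k-means v-measure), ontology
    parsing and annotation propagation, family- and term-aware train/test
    split regimes, a small convolutional sequence encoder, and a synthetic
    data generator that emulates family-structured protein datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
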
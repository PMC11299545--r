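#' CAFA-style evaluation curves
#'
#' The protein-centric evaluation sweeps a score threshold tau over a
#' prediction matrix. A (protein, term) pair is predicted positive at tau
#' when its score is at least tau and strictly positive: on the probability
#' scale a score of exactly zero means "no prediction" at any threshold, so
#' an all-zero matrix never predicts anything. For matrices whose scores
#' leave `[0, 1]` (logits) the grid is taken over the achieved score values,
#' which makes F-max and S-min invariant to strictly monotone transforms of
#' the scores.
#'
#' @name metric_curves
NULL

# threshold grid: percent grid union achieved positive scores for
# probability-valued matrices; achieved values only for unbounded scores
make_thresholds <- function(pred) {
  v <- as.numeric(pred)
  if (all(v >= 0 & v <= 1)) {
    sort(unique(c(seq(0.01, 1, by = 0.01), v[v > 0])))
  } else {
    sort(unique(v))
  }
}

predicted_at <- function(pred, tau, bounded) {
  if (bounded) pred >= tau & pred > 0 else pred >= tau
}

# align a truth annotation_set with the rows of a prediction matrix
truth_matrix_for <- function(pred, truth, vocab = NULL) {
  stopifnot(inherits(truth, "annotation_set"))
  prots <- rownames(pred)
  extra_pred <- setdiff(prots, names(truth$sets))
  extra_truth <- setdiff(names(truth$sets), prots)
  if (length(extra_pred) > 0 || length(extra_truth) > 0) {
    stopf(paste0("prediction/truth protein mismatch; only predicted: {%s}; ",
                 "only in truth: {%s}"),
          paste(utils::head(extra_pred, 5), collapse = ", "),
          paste(utils::head(extra_truth, 5), collapse = ", "))
  }
  vocab <- vocab %||% term_vocabulary(colnames(pred))
  tm <- matrix(0, length(prots), ncol(pred),
               dimnames = list(prots, colnames(pred)))
  for (p in prots) {
    hit <- intersect(truth$sets[[p]], colnames(pred))
    tm[p, hit] <- 1
  }
  tm
}

new_metric_curve <- function(df, summary_name, summary_value, tau_opt) {
  structure(list(curve = df, summary = summary_value, tau = tau_opt),
            class = "metric_curve", summary_name = summary_name)
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("metric_curve: %d thresholds; %s = %.4f at tau = %.4g\n",
              nrow(x$curve), attr(x, "summary_name"), x$summary, x$tau))
  invisible(x)
}

#' Precision-recall curve and F-max
#'
#' Protein-centric CAFA protocol: at each threshold, precision is averaged
#' over the proteins that have at least one predicted term, recall is
#' averaged over all proteins, and `F(tau) = 2 p r / (p + r)`. F-max is the
#' maximum over the grid; if no threshold yields any prediction, F-max is 0.
#'
#' @param pred a prediction matrix (see [prediction_matrix()]).
#' @param truth a propagated, vocabulary-restricted [annotation_set()]
#'   covering exactly the predicted proteins.
#' @param thresholds optional explicit threshold grid; defaults to the
#'   percent grid united with achieved scores.
#' @return a `metric_curve` with columns `tau`, `precision`, `recall`, `f`
#'   and summary `fmax`.
#' @export
pr_curve <- function(pred, truth, thresholds = NULL) {
  tm <- truth_matrix_for(pred, truth)
  bounded <- all(pred >= 0 & pred <= 1)
  taus <- thresholds %||% make_thresholds(pred)
  npos <- rowSums(tm)
  res <- vapply(taus, function(tau) {
    P <- predicted_at(pred, tau, bounded)
    tp <- rowSums(P & tm == 1)
    npred <- rowSums(P)
    has_pred <- npred > 0
    pr <- if (any(has_pred)) mean(tp[has_pred] / npred[has_pred]) else NA_real_
    rc <- mean(ifelse(npos > 0, tp / npos, 0))
    f <- if (is.na(pr) || pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    c(pr = ifelse(is.na(pr), 0, pr), rc = rc, f = f)
  }, c(pr = 0, rc = 0, f = 0))
  df <- data.frame(tau = taus, precision = res["pr", ],
                   recall = res["rc", ], f = res["f", ])
  i <- which.max(df$f)
  new_metric_curve(df, "fmax", df$f[i], df$tau[i])
}

#' Remaining-uncertainty / misinformation curve and S-min
#'
#' At each threshold, remaining uncertainty `ru` is the mean (over proteins)
#' total information content of false-negative terms and misinformation
#' `mi` the mean total information content of false positives;
#' `S(tau) = sqrt(ru^2 + mi^2)`. S-min, the minimum over the grid, puts
#' higher emphasis on rare (high-IC) classes.
#'
#' @inheritParams pr_curve
#' @param ic named information-content vector (see [information_content()])
#'   covering every predicted term.
#' @return a `metric_curve` with columns `tau`, `ru`, `mi`, `s` and summary
#'   `smin`.
#' @export
smin_curve <- function(pred, truth, ic, thresholds = NULL) {
  tm <- truth_matrix_for(pred, truth)
  miss <- setdiff(colnames(pred), names(ic))
  if (length(miss) > 0) {
    stopf("information content missing for term(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  icv <- ic[colnames(pred)]
  bounded <- all(pred >= 0 & pred <= 1)
  taus <- thresholds %||% make_thresholds(pred)
  res <- vapply(taus, function(tau) {
    P <- predicted_at(pred, tau, bounded)
    fn <- (!P) & tm == 1
    fp <- P & tm == 0
    ru <- mean(as.numeric(fn %*% icv))
    mi <- mean(as.numeric(fp %*% icv))
    c(ru = ru, mi = mi, s = sqrt(ru^2 + mi^2))
  }, c(ru = 0, mi = 0, s = 0))
  df <- data.frame(tau = taus, ru = res["ru", ], mi = res["mi", ],
                   s = res["s", ])
  i <- which.min(df$s)
  new_metric_curve(df, "smin", df$s[i], df$tau[i])
}

#' F-estimate curve for incomplete truth sets
#'
#' Annotation databases under-report true functions, biasing precision
#' downward. Under missing-at-random false negatives, a quantity
#' proportional to the true F1 can still be estimated from positives alone:
#' `FE(tau) = recall(tau)^2 / q(tau)`, the positive-unlabelled estimator,
#' where `q(tau)` is the fraction of all (protein, term) pairs predicted
#' positive. The summary is the maximum over the grid. Because the estimate
#' is only proportional to F1, FE values are comparable between predictors
#' on the same dataset, not across datasets.
#'
#' @inheritParams pr_curve
#' @return a `metric_curve` with columns `tau`, `recall`, `q`, `fe` and
#'   summary `femax`.
#' @export
f_estimate_curve <- function(pred, truth, thresholds = NULL) {
  tm <- truth_matrix_for(pred, truth)
  bounded <- all(pred >= 0 & pred <= 1)
  taus <- thresholds %||% make_thresholds(pred)
  npos <- rowSums(tm)
  npairs <- length(pred)
  res <- vapply(taus, function(tau) {
    P <- predicted_at(pred, tau, bounded)
    tp <- rowSums(P & tm == 1)
    rc <- mean(ifelse(npos > 0, tp / npos, 0))
    q <- sum(P) / npairs
    c(rc = rc, q = q, fe = if (q == 0) 0 else rc^2 / q)
  }, c(rc = 0, q = 0, fe = 0))
  df <- data.frame(tau = taus, recall = res["rc", ], q = res["q", ],
                   fe = res["fe", ])
  i <- which.max(df$fe)
  new_metric_curve(df, "femax", df$fe[i], df$tau[i])
}

#' Term-centric F1 at a fixed threshold
#'
#' Binary F1 per term over all proteins, with scores discretized at the
#' given threshold (default 0.5). A term with no true positives and no
#' predictions scores 0.
#'
#' @inheritParams pr_curve
#' @param terms term ids to evaluate (default: all predicted columns).
#' @param threshold discretization threshold in (0, 1).
#' @return named numeric vector of per-term F1 values.
#' @export
per_class_f1 <- function(pred, truth, terms = colnames(pred),
                         threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  tm <- truth_matrix_for(pred, truth)
  miss <- setdiff(terms, colnames(pred))
  if (length(miss) > 0) {
    stopf("term(s) not in prediction matrix: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  P <- predicted_at(pred, threshold, bounded = TRUE)
  vapply(terms, function(t) {
    tp <- sum(P[, t] & tm[, t] == 1)
    fp <- sum(P[, t] & tm[, t] == 0)
    fn <- sum(!P[, t] & tm[, t] == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' Make prediction scores hierarchy-consistent
#'
#' Max-upward pass: each term's score becomes the maximum over the scores
#' of its vocabulary descendants (including itself), so that parent scores
#' never fall below child scores. Annotators that transfer propagated
#' reference labels already satisfy this and are unchanged.
#'
#' @param pred a prediction matrix whose columns are ontology terms.
#' @param g a [ontology()] containing those terms.
#' @return a prediction matrix of the same shape.
#' @export
propagate_scores <- function(pred, g) {
  stopifnot(inherits(g, "go_ontology"))
  cols <- colnames(pred)
  miss <- setdiff(cols, g$terms)
  if (length(miss) > 0) {
    stopf("term(s) not in ontology: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  anc <- ancestor_closure(g)
  out <- pred
  for (t in cols) {
    # descendants of t among predicted columns (terms whose closure holds t)
    desc <- cols[vapply(cols, function(u) t %in% anc[[u]], logical(1))]
    if (length(desc) > 1) {
      out[, t] <- apply(pred[, desc, drop = FALSE], 1, max)
    }
  }
  out
}

#' Write a metric curve as TSV
#'
#' @param curve a `metric_curve`.
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "metric_curve"))
  utils::write.table(format(curve$curve, digits = 8), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
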
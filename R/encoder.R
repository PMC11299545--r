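#' Convolutional encoder configuration
#'
#' Configuration for the convolutional sequence classifier, a DeepGOPlus
#' lineage architecture: one-hot encoded residues pass through parallel 1-D
#' convolution banks of increasing kernel size, each globally max-pooled,
#' the pooled features are concatenated and projected by a dense layer to
#' the embedding dimension, and a linear head with sigmoid outputs yields
#' per-term probabilities. Defaults follow that lineage (kernel sizes 8 to
#' 128 in steps of 8 are conventional; a smaller geometric ladder is the
#' default here to keep CPU fixtures tractable, and all values are tunable).
#'
#' @param kernel_sizes strictly increasing integer vector of 1-D kernel
#'   widths.
#' @param filters number of filters per kernel size.
#' @param embedding_dim dimension of the protein embedding (>= 1).
#' @param lr peak learning rate of the slanted triangular schedule.
#' @param max_length sequences are truncated to this many residues.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param warmup fraction of steps spent in linear warmup; after the peak
#'   the rate decays linearly to `lr / lr_ratio` (ULMFiT convention).
#' @param lr_ratio ratio of peak to floor learning rate.
#' @param seed integer seed (mandatory; training is stochastic).
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(kernel_sizes = c(8L, 16L, 32L, 64L, 128L),
                           filters = 512L, embedding_dim = 128L,
                           lr = 1e-3, max_length = 1000L, epochs = 20L,
                           batch_size = 32L, warmup = 0.1, lr_ratio = 32,
                           seed = 1L) {
  kernel_sizes <- as.integer(kernel_sizes)
  if (any(diff(kernel_sizes) <= 0)) {
    stopf("kernel sizes must be strictly increasing")
  }
  if (embedding_dim < 1) stopf("embedding_dim must be >= 1")
  structure(list(kernel_sizes = kernel_sizes, filters = as.integer(filters),
                 embedding_dim = as.integer(embedding_dim), lr = lr,
                 max_length = as.integer(max_length),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), warmup = warmup,
                 lr_ratio = lr_ratio, seed = as.integer(seed),
                 alphabet = c(AA_ALPHABET, "X")),
            class = "encoder_config")
}

# one-hot matrix (L x |alphabet|); residues outside the alphabet map to the
# unknown token X. Returns NULL attribute-free matrix.
encode_onehot <- function(seq, cfg) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) > cfg$max_length) chars <- chars[seq_len(cfg$max_length)]
  idx <- match(chars, cfg$alphabet)
  n_unknown <- sum(is.na(idx))
  idx[is.na(idx)] <- length(cfg$alphabet)
  m <- matrix(0, length(chars), length(cfg$alphabet))
  m[cbind(seq_along(idx), idx)] <- 1
  attr(m, "n_unknown") <- n_unknown
  m
}

# sliding windows of the flattened one-hot as rows: (L - w + 1) x (w * A).
# Rows of the one-hot are contiguous in its row-major flattening, so each
# window is a contiguous slice with stride A.
conv_windows <- function(onehot, w) {
  L <- nrow(onehot); A <- ncol(onehot)
  if (L < w) return(matrix(0, 1L, w * A))
  xflat <- as.vector(t(onehot))
  P <- L - w + 1L
  idx <- outer((seq_len(P) - 1L) * A, seq_len(w * A), `+`)
  matrix(xflat[idx], P, w * A)
}

init_encoder_params <- function(cfg, n_terms) {
  A <- length(cfg$alphabet)
  glorot <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  }
  conv <- lapply(cfg$kernel_sizes, function(w) {
    list(W = glorot(w * A, cfg$filters), b = rep(0, cfg$filters))
  })
  ftot <- length(cfg$kernel_sizes) * cfg$filters
  list(conv = conv,
       We = glorot(ftot, cfg$embedding_dim), be = rep(0, cfg$embedding_dim),
       Wc = glorot(cfg$embedding_dim, n_terms), bc = rep(0, n_terms))
}

# forward pass for one precomputed window list; returns activations needed
# for backprop
encoder_forward <- function(windows, params, cfg) {
  pooled <- list(); argmax <- list(); relu <- list()
  for (j in seq_along(cfg$kernel_sizes)) {
    H <- sweep(windows[[j]] %*% params$conv[[j]]$W, 2, params$conv[[j]]$b, `+`)
    R <- pmax(H, 0)
    am <- max.col(t(R), ties.method = "first")
    pl <- R[cbind(am, seq_len(ncol(R)))]
    pooled[[j]] <- pl; argmax[[j]] <- am; relu[[j]] <- pl > 0
  }
  z <- unlist(pooled, use.names = FALSE)
  e <- as.numeric(z %*% params$We) + params$be
  logits <- as.numeric(e %*% params$Wc) + params$bc
  list(z = z, e = e, logits = logits, argmax = argmax, relu = relu)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable mean binary cross-entropy from logits
bce_from_logits <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

# slanted triangular learning rate at step t of total T
stl_rate <- function(t, total, cfg) {
  cut <- max(floor(cfg$warmup * total), 1L)
  p <- if (t <= cut) t / cut else max(1 - (t - cut) / max(total - cut, 1L), 0)
  cfg$lr * (1 + p * (cfg$lr_ratio - 1)) / cfg$lr_ratio
}

#' Train the convolutional encoder
#'
#' Minimizes mean per-term binary cross-entropy of sigmoid outputs from a
#' linear head on the embedding, with Adam and a slanted triangular
#' learning-rate schedule (linear warmup, then linear decay). Fully seeded:
#' identical configurations produce bit-identical logs and weights.
#'
#' @param sequences named character vector (or `AAStringSet`) of amino-acid
#'   sequences.
#' @param labels binary target matrix, proteins x vocabulary terms, with
#'   protein row names and term column names; every labelled protein must
#'   be present in `sequences`.
#' @param cfg an [encoder_config()].
#' @return an object of class `conv_encoder_fit`: trained parameters, the
#'   configuration, the term order, and a per-epoch training `log`
#'   (data.frame of epoch, mean loss, final learning rate).
#' @export
train_encoder <- function(sequences, labels, cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  sequences <- as_named_sequences(sequences)
  labels <- as.matrix(labels)
  if (ncol(labels) == 0) stopf("empty vocabulary: no target terms")
  miss <- setdiff(rownames(labels), names(sequences))
  if (length(miss) > 0) {
    stopf("labelled protein(s) without a sequence: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  prot <- rownames(labels)
  nterms <- ncol(labels)
  windows <- lapply(prot, function(p) {
    oh <- encode_onehot(sequences[[p]], cfg)
    lapply(cfg$kernel_sizes, function(w) conv_windows(oh, w))
  })
  names(windows) <- prot
  with_seed(cfg$seed, {
    params <- init_encoder_params(cfg, nterms)
    opt <- adam_state(params)
    nb <- ceiling(length(prot) / cfg$batch_size)
    total_steps <- cfg$epochs * nb
    step <- 0L
    log <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(prot)
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        batch <- ord[((bi - 1L) * cfg$batch_size + 1L):
                       min(bi * cfg$batch_size, length(prot))]
        grads <- zero_grads(params)
        bloss <- 0
        for (p in batch) {
          fwd <- encoder_forward(windows[[p]], params, cfg)
          y <- labels[p, ]
          bloss <- bloss + bce_from_logits(fwd$logits, y)
          grads <- accumulate_grads(grads, params, cfg, windows[[p]], fwd, y,
                                    nterms)
        }
        if (!is.finite(bloss)) {
          stopf("non-finite loss at epoch %d batch %d; lower the learning rate",
                ep, bi)
        }
        step <- step + 1L
        lr_t <- stl_rate(step, total_steps, cfg)
        upd <- adam_update(params, grads, opt, lr_t, length(batch), step)
        params <- upd$params; opt <- upd$opt
        ep_loss <- ep_loss + bloss
      }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / length(prot),
                                   lr = stl_rate(step, total_steps, cfg)))
    }
    structure(list(params = params, cfg = cfg, terms = colnames(labels),
                   log = log),
              class = "conv_encoder_fit")
  })
}

zero_grads <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

# backprop for one sequence; gradient of the mean-BCE loss
accumulate_grads <- function(grads, params, cfg, wins, fwd, y, nterms) {
  dlogit <- (sigmoid(fwd$logits) - y) / nterms
  grads$Wc <- grads$Wc + outer(fwd$e, dlogit)
  grads$bc <- grads$bc + dlogit
  de <- as.numeric(params$Wc %*% dlogit)
  grads$We <- grads$We + outer(fwd$z, de)
  grads$be <- grads$be + de
  dz <- as.numeric(params$We %*% de)
  off <- 0L
  for (j in seq_along(cfg$kernel_sizes)) {
    dp <- dz[(off + 1L):(off + cfg$filters)]
    dp[!fwd$relu[[j]]] <- 0
    G <- matrix(0, nrow(wins[[j]]), cfg$filters)
    G[cbind(fwd$argmax[[j]], seq_len(cfg$filters))] <- dp
    grads$conv[[j]]$W <- grads$conv[[j]]$W + crossprod(wins[[j]], G)
    grads$conv[[j]]$b <- grads$conv[[j]]$b + dp
    off <- off + cfg$filters
  }
  grads
}

adam_state <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"))
}

# flat walk over the nested parameter list
adam_update <- function(params, grads, opt, lr, batch_n, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    g <- g / batch_n
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^step)
    vhat <- v / (1 - beta2^step)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  res <- walk(params, grads, opt$m, opt$v)
  list(params = res$p, opt = list(m = res$m, v = res$v))
}

#' Embed sequences with a trained convolutional encoder
#'
#' Deterministic given the trained weights: one-hot encoding (truncation to
#' the configured maximum length), convolution banks, global max-pooling,
#' concatenation, dense projection to the embedding dimension. Residues
#' outside the amino-acid alphabet are mapped to the unknown token and
#' counted in the attached report.
#'
#' @param sequences named character vector (or `AAStringSet`).
#' @param fit a [train_encoder()] result.
#' @return embedding matrix, one row per sequence, `embedding_dim` columns,
#'   with attribute `"report"` (unknown-residue count).
#' @export
conv_encode <- function(sequences, fit) {
  stopifnot(inherits(fit, "conv_encoder_fit"))
  sequences <- as_named_sequences(sequences)
  cfg <- fit$cfg
  out <- matrix(0, length(sequences), cfg$embedding_dim,
                dimnames = list(names(sequences), NULL))
  n_unknown <- 0L
  for (i in seq_along(sequences)) {
    oh <- encode_onehot(sequences[[i]], cfg)
    n_unknown <- n_unknown + attr(oh, "n_unknown")
    wins <- lapply(cfg$kernel_sizes, function(w) conv_windows(oh, w))
    out[i, ] <- encoder_forward(wins, fit$params, cfg)$e
  }
  attr(out, "report") <- list(unknown_residues = n_unknown)
  out
}

#' Per-term probabilities from the classifier head
#'
#' @param fit a [train_encoder()] result.
#' @param sequences named character vector (or `AAStringSet`).
#' @return prediction matrix of sigmoid probabilities, sequences x terms.
#' @export
conv_predict <- function(fit, sequences) {
  emb <- conv_encode(sequences, fit)
  logits <- sweep(emb %*% fit$params$Wc, 2, fit$params$bc, `+`)
  p <- sigmoid(logits)
  dimnames(p) <- list(rownames(emb), fit$terms)
  p
}

#' @export
print.conv_encoder_fit <- function(x, ...) {
  cat(sprintf(
    "conv_encoder_fit: kernels {%s} x %d filters -> d = %d; %d terms; %d epochs (final loss %.4f)\n",
    paste(x$cfg$kernel_sizes, collapse = ","), x$cfg$filters,
    x$cfg$embedding_dim, length(x$terms), nrow(x$log),
    utils::tail(x$log$loss, 1)))
  invisible(x)
}

# coerce AAStringSet or character to a named character vector
as_named_sequences <- function(sequences) {
  nm <- names(sequences)
  sequences <- as.character(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stopf("sequences must be named")
  stats::setNames(sequences, sub("\\s.*$", "", nm))
}
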
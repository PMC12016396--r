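# Base-level skip-gram embeddings. The vocabulary is the four RNA bases, so
# the exact full-softmax objective is cheap: the corpus enters only through
# the 4x4 (center, context) count matrix, and full-batch gradient ascent on
# that sufficient statistic is identical to iterating over every pair.

seq_to_codes <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], RNA_BASES)
  if (anyNA(codes)) stopf("sequence contains characters outside A/C/G/U")
  codes
}

#' Enumerate skip-gram (center, context) pairs of a sequence
#'
#' For every position t and offset j with `-k <= j <= k`, `j != 0`, and
#' `t + j` inside the sequence, emits the pair (base_t, base_{t+j}), in scan
#' order (t ascending, j ascending).
#'
#' @param seq base string over A/C/G/U.
#' @param k window half-width (>= 1).
#' @return `data.frame` with character columns `center`, `context`; zero
#'   rows when the sequence has no valid context positions.
#' @export
extract_skipgram_pairs <- function(seq, k) {
  stopifnot(k >= 1)
  codes <- seq_to_codes(seq)
  T_len <- length(codes)
  offs <- setdiff(seq(-k, k), 0L)
  t_idx <- rep(seq_len(T_len), each = length(offs))
  j_idx <- rep(offs, times = T_len)
  keep <- t_idx + j_idx >= 1L & t_idx + j_idx <= T_len
  data.frame(center = RNA_BASES[codes[t_idx[keep]]],
             context = RNA_BASES[codes[t_idx[keep] + j_idx[keep]]],
             stringsAsFactors = FALSE)
}

# 4x4 count matrix N[center, context] over a corpus; each sequence is one
# sentence (windows never cross sequences).
context_count_matrix <- function(seqs, k) {
  N <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  for (s in seqs) {
    codes <- seq_to_codes(s)
    L <- length(codes)
    for (j in seq_len(min(k, L - 1L))) {
      a <- codes[seq_len(L - j)]
      b <- codes[seq_len(L - j) + j]
      tab <- table(factor(a, levels = 1:4), factor(b, levels = 1:4))
      N <- N + tab + t(tab)   # center->context both directions
    }
  }
  N
}

#' Skip-gram configuration
#'
#' @param dim embedding width d0 (default 64).
#' @param window context half-width k (default 2).
#' @param epochs full-batch gradient-ascent steps (default 50).
#' @param lr learning rate (default 0.025).
#' @param seed integer seed for the embedding initialization.
#' @return list of class `skipgram_config`.
#' @export
skipgram_config <- function(dim = 64L, window = 2L, epochs = 50L,
                            lr = 0.025, seed = 1L) {
  stopifnot(dim >= 1, window >= 1, epochs >= 1, lr > 0)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "skipgram_config")
}

row_softmax <- function(S) {
  Z <- exp(S - apply(S, 1, max))
  Z / rowSums(Z)
}

#' Train base embeddings with a full-softmax skip-gram model
#'
#' Maximizes the average corpus log-probability of context bases given
#' center bases, `mean log P(context | center)`, where
#' `P(w | c) = softmax_w(u_w . v_c)` over the 4-base vocabulary. Because the
#' vocabulary has only four words the exact softmax is used (no negative
#' sampling) and the optimizer is full-batch gradient ascent on the corpus
#' count matrix, so the average log-likelihood is monitored per epoch.
#'
#' @param corpus a `cmi_sequences` table (circRNA and miRNA sequences are
#'   usually pooled into one corpus), or any data.frame with a `seq` column.
#' @param cfg a [skipgram_config()].
#' @return object of class `cmi_base_embeddings`: list with `vocab`,
#'   `vectors` (4 x d0 center embeddings, the lookup table), `context`
#'   (4 x d0 context embeddings), `loglik` (per-epoch trace), `config`.
#' @export
train_base_embeddings <- function(corpus, cfg = skipgram_config()) {
  if (NROW(corpus) == 0) stopf("corpus is empty")
  N <- context_count_matrix(corpus$seq, cfg$window)
  total <- sum(N)
  if (total == 0) stopf("corpus yields no skip-gram pairs (all sequences of length 1?)")
  d0 <- cfg$dim
  V <- with_seed(cfg$seed, matrix(stats::runif(4 * d0, -0.5, 0.5) / d0, 4, d0))
  U <- with_seed(cfg$seed + 1L, matrix(stats::runif(4 * d0, -0.5, 0.5) / d0, 4, d0))
  loglik <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    S <- V %*% t(U)                       # S[c, w] = v_c . u_w
    P <- row_softmax(S)
    logP <- log(P)
    loglik[ep] <- sum(N * logP) / total
    dS <- (N - rowSums(N) * P) / total    # gradient of mean log-likelihood
    dV <- dS %*% U
    dU <- t(dS) %*% V
    V <- V + cfg$lr * dV
    U <- U + cfg$lr * dU
  }
  rownames(V) <- rownames(U) <- RNA_BASES
  structure(list(vocab = RNA_BASES, vectors = V, context = U,
                 loglik = loglik, counts = N, config = cfg),
            class = "cmi_base_embeddings")
}

#' Conditional context distribution of a trained embedding table
#'
#' @param table a `cmi_base_embeddings` object.
#' @return 4x4 matrix `P[center, context]`, rows summing to one.
#' @export
context_distribution <- function(table) {
  row_softmax(table$vectors %*% t(table$context))
}

#' Map a sequence to its matrix of base vectors
#'
#' @param seq base string over A/C/G/U (non-empty).
#' @param table a `cmi_base_embeddings` object.
#' @return L x d0 matrix; row t is the embedding of base t.
#' @export
embed_sequence <- function(seq, table) {
  if (!nzchar(seq)) stopf("cannot embed an empty sequence")
  table$vectors[seq_to_codes(seq), , drop = FALSE]
}

#' Serialize a base-embedding table as TSV
#' @param table a `cmi_base_embeddings` object.
#' @param path output path (columns: base, then d0 values).
#' @export
write_base_embeddings <- function(table, path) {
  df <- data.frame(base = table$vocab, table$vectors, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
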
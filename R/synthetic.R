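# Synthetic desk-scale datasets with planted low-rank structure.
#
# The generative model mirrors the assumption the predictor scores under
# (interaction propensity = inner product of latent factors): each node
# gets a Gaussian factor row z, an edge (c, m) appears independently with
# probability sigmoid(alpha + beta * z_c . z_m), and alpha is calibrated so
# the expected edge density hits the configured value. Sequences carry a
# deliberately partial signature of the factors — base composition tilted
# by the first latent coordinate only — so the sequence pathway alone
# cannot recover the full planted structure and the graph-collaboration
# pathway is genuinely needed.

#' Synthetic dataset configuration
#'
#' Defaults give a desk-scale analogue of the public CMI corpora
#' (thousands of pairs over hundreds of nodes, here 200 x 80 nodes at
#' density 0.12, about 1.9k positive pairs): rank-4 factors, strong planted
#' signal, circRNA lengths an order of magnitude above miRNA lengths.
#'
#' @param n_circ,n_mir node counts (defaults 200, 80).
#' @param rank latent factor rank r (default 4).
#' @param edge_density expected fraction of present edges (default 0.12).
#' @param seq_len_circ,seq_len_mir inclusive length ranges (defaults
#'   c(60, 120) and c(18, 25) nt).
#' @param signal_strength beta >= 0 scaling both the edge logits and the
#'   sequence composition tilt (default 5; 0 gives the no-signal null).
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_circ = 200L, n_mir = 80L, rank = 4L,
                         edge_density = 0.12,
                         seq_len_circ = c(60L, 120L),
                         seq_len_mir = c(18L, 25L),
                         signal_strength = 5, seed = 1L) {
  stopifnot(rank >= 1, edge_density > 0, edge_density < 1,
            signal_strength >= 0, n_circ >= 1, n_mir >= 1)
  structure(list(n_circ = as.integer(n_circ), n_mir = as.integer(n_mir),
                 rank = as.integer(rank), edge_density = edge_density,
                 seq_len_circ = as.integer(seq_len_circ),
                 seq_len_mir = as.integer(seq_len_mir),
                 signal_strength = signal_strength,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Draw latent factor matrices
#'
#' Rows i.i.d. standard Gaussian.
#'
#' @param cfg a [synth_config()].
#' @return list with `Z_circ` (n_circ x r) and `Z_mir` (n_mir x r).
#' @export
generate_latent_factors <- function(cfg) {
  with_seed(cfg$seed, {
    list(Z_circ = matrix(stats::rnorm(cfg$n_circ * cfg$rank),
                         cfg$n_circ, cfg$rank),
         Z_mir = matrix(stats::rnorm(cfg$n_mir * cfg$rank),
                        cfg$n_mir, cfg$rank))
  })
}

synth_ids <- function(cfg) {
  list(circ = sprintf("circ%04d", seq_len(cfg$n_circ)),
       mir = sprintf("mir%04d", seq_len(cfg$n_mir)))
}

#' Sample the planted interaction table
#'
#' Edge (c, m) is present independently with probability
#' `sigmoid(alpha + beta * z_c . z_m)`; the intercept alpha is calibrated
#' by bisection so the expected density matches `cfg$edge_density` to
#' within 1% (relative). The true probabilities are returned for oracle
#' tests.
#'
#' @param Z_circ,Z_mir factor matrices from [generate_latent_factors()].
#' @param cfg a [synth_config()].
#' @return list: `table` (`cmi_interactions`, the sampled positives),
#'   `prob` (n_circ x n_mir true edge probabilities), `alpha`.
#' @export
generate_interactions <- function(Z_circ, Z_mir, cfg) {
  G <- cfg$signal_strength * tcrossprod(Z_circ, Z_mir)   # n_circ x n_mir
  lo <- -60; hi <- 60
  dens <- function(a) mean(sigmoid(a + G))
  if (dens(lo) > cfg$edge_density || dens(hi) < cfg$edge_density) {
    stopf("edge density %.3g is not attainable under the factor model",
          cfg$edge_density)
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (dens(mid) < cfg$edge_density) lo <- mid else hi <- mid
    if (abs(dens(mid) - cfg$edge_density) < 0.01 * cfg$edge_density) break
  }
  alpha <- (lo + hi) / 2
  P <- sigmoid(alpha + G)
  ids <- synth_ids(cfg)
  edges <- with_seed(cfg$seed + 1L,
                     matrix(stats::runif(length(P)) < P, nrow(P), ncol(P)))
  idx <- which(edges, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("no edges sampled; raise edge_density")
  dimnames(P) <- list(ids$circ, ids$mir)
  list(table = interaction_table(ids$circ[idx[, 1]], ids$mir[idx[, 2]]),
       prob = P, alpha = alpha)
}

#' Generate sequences whose composition reflects the first factor
#'
#' Bases are drawn i.i.d. per node from a composition in which the odds of
#' G and C are multiplied by `exp(beta * z1)` (z1 = the node's first
#' latent coordinate); lengths are uniform over the configured range.
#'
#' @param Z factor matrix for the nodes of this kind.
#' @param cfg a [synth_config()].
#' @param kind `"circRNA"` or `"miRNA"`.
#' @return a `cmi_sequences` table.
#' @export
generate_sequences <- function(Z, cfg, kind = c("circRNA", "miRNA")) {
  kind <- match.arg(kind)
  ids <- synth_ids(cfg)
  id <- if (kind == "circRNA") ids$circ else ids$mir
  rng <- if (kind == "circRNA") cfg$seq_len_circ else cfg$seq_len_mir
  seed <- cfg$seed + if (kind == "circRNA") 2L else 3L
  stopifnot(nrow(Z) == length(id))
  seqs <- with_seed(seed, {
    lens <- sample(rng[1]:rng[2], nrow(Z), replace = TRUE)
    vapply(seq_len(nrow(Z)), function(i) {
      gc_odds <- exp(cfg$signal_strength * Z[i, 1])
      w <- c(A = 1, C = gc_odds, G = gc_odds, U = 1)
      paste(sample(RNA_BASES, lens[i], replace = TRUE, prob = w / sum(w)),
            collapse = "")
    }, character(1))
  })
  structure(data.frame(id = id, seq = seqs, kind = kind,
                       stringsAsFactors = FALSE),
            class = c("cmi_sequences", "data.frame"))
}

#' Write sequences as FASTA
#' @param records a `cmi_sequences` table.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Generate a complete synthetic dataset
#'
#' Composes the factor, interaction and sequence generators. With
#' `out_dir` the dataset is also written in the dialects the readers
#' consume (`circ.fasta`, `mir.fasta`, `interactions.tsv`, `truth.json`),
#' so re-reading round-trips exactly.
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional output directory.
#' @return list: `sequences` (pooled `cmi_sequences`), `interactions`
#'   (`cmi_interactions` positives), `prob` (true edge probabilities),
#'   `factors`, `alpha`, `config`.
#' @export
generate_dataset <- function(cfg = synth_config(), out_dir = NULL) {
  fac <- generate_latent_factors(cfg)
  ints <- generate_interactions(fac$Z_circ, fac$Z_mir, cfg)
  circ_seq <- generate_sequences(fac$Z_circ, cfg, "circRNA")
  mir_seq <- generate_sequences(fac$Z_mir, cfg, "miRNA")
  seqs <- rbind(circ_seq, mir_seq)
  class(seqs) <- c("cmi_sequences", "data.frame")
  out <- list(sequences = seqs, interactions = ints$table,
              prob = ints$prob, factors = fac, alpha = ints$alpha,
              config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(circ_seq, file.path(out_dir, "circ.fasta"))
    write_fasta(mir_seq, file.path(out_dir, "mir.fasta"))
    write_interactions(ints$table, file.path(out_dir, "interactions.tsv"))
    jsonlite::write_json(
      list(alpha = ints$alpha, config = unclass(cfg),
           prob = ints$prob, Z_circ = fac$Z_circ, Z_mir = fac$Z_mir),
      file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  out
}
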
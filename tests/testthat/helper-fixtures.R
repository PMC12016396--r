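# Shared fixtures: everything is generated in code at test time.

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# A tiny planted dataset plus a 1:1-negative labeled table.
tiny_dataset <- function(n_circ = 8, n_mir = 5, seed = 11,
                         beta = 1, density = 0.3) {
  cfg <- synth_config(n_circ = n_circ, n_mir = n_mir, rank = 2,
                      edge_density = density,
                      seq_len_circ = c(8L, 14L), seq_len_mir = c(4L, 7L),
                      signal_strength = beta, seed = seed)
  ds <- generate_dataset(cfg)
  ids <- list(circ = unique(ds$sequences$id[ds$sequences$kind == "circRNA"]),
              mir = unique(ds$sequences$id[ds$sequences$kind == "miRNA"]))
  tab <- sample_negatives(ds$interactions, ids$circ, ids$mir,
                          ratio = 1, seed = seed + 1)
  list(cfg = cfg, ds = ds, ids = ids, tab = tab)
}

# A small random bipartite graph object (no sequences attached).
random_graph <- function(n, m, p = 0.4, seed = 1) {
  R <- cmiCollab:::with_seed(seed, matrix(rbinom(n * m, 1, p), n, m))
  A <- build_adjacency(R)
  structure(list(n = n, m = m, R = R, A = A, L = normalized_laplacian(A),
                 mir_ids = sprintf("m%d", seq_len(n)),
                 circ_ids = sprintf("c%d", seq_len(m)),
                 node_ids = c(sprintf("m%d", seq_len(n)),
                              sprintf("c%d", seq_len(m)))),
            class = "cmi_graph")
}

# Small trained-model fixture shared by model-level tests (kept tiny so the
# suite stays fast).
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fix <- tiny_dataset(seed = 21)
      graph <- build_graph(fix$tab, fix$ids$circ, fix$ids$mir)
      enc <- encoder_config(input_dim = 8, hidden_dim = 6, num_layers = 2,
                            feature_dim = 10, graph_dim = 4, seed = 3)
      cfg <- train_config(lr = 5e-3, batch_size = 1000L, epochs = 3,
                          seed = 5)
      base <- train_base_embeddings(fix$ds$sequences,
                                    skipgram_config(dim = 8, epochs = 10,
                                                    seed = 2))
      model <- train_model(fix$tab, graph, fix$ds$sequences, cfg = cfg,
                           encoder = enc, base = base)
      cache <<- list(fix = fix, graph = graph, enc = enc, cfg = cfg,
                     base = base, model = model)
    }
    cache
  }
})
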
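# Sequence encoder: base-embedding lookup -> stacked LSTM -> fully
# connected compression to the feature width -> affine projection to the
# graph-embedding width. The projection bridges the 128-d sequence features
# to the (narrower) width the propagation layers run at.

#' Encoder configuration
#'
#' @param input_dim width of the base embeddings fed to the first LSTM
#'   layer (default 64).
#' @param hidden_dim LSTM hidden width (default 256).
#' @param num_layers stacked LSTM depth (default 2).
#' @param feature_dim fully connected output width (default 128).
#' @param graph_dim width d of the graph-propagation embeddings
#'   (default 64).
#' @param max_seq_len truncation cap; longer sequences keep their 5'
#'   prefix (default 1000 nt — miRNAs are far shorter, circRNAs are capped
#'   to bound desk-scale compute).
#' @param summary `"final"` (final hidden state of the top layer, the
#'   default) or `"mean"` (mean over valid timesteps).
#' @param init_scale multiplier on the LSTM weight-initialization range
#'   (default 1; see [init_lstm_layer()]).
#' @param seed integer seed for parameter initialization.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(input_dim = 64L, hidden_dim = 256L,
                           num_layers = 2L, feature_dim = 128L,
                           graph_dim = 64L, max_seq_len = 1000L,
                           summary = c("final", "mean"), init_scale = 1,
                           seed = 1L) {
  summary <- match.arg(summary)
  stopifnot(input_dim >= 1, hidden_dim >= 1, num_layers >= 1,
            feature_dim >= 1, graph_dim >= 1, max_seq_len >= 1,
            init_scale > 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 num_layers = as.integer(num_layers),
                 feature_dim = as.integer(feature_dim),
                 graph_dim = as.integer(graph_dim),
                 max_seq_len = as.integer(max_seq_len),
                 summary = summary, init_scale = init_scale,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Initialize encoder parameters
#'
#' LSTM layers use uniform(-1/sqrt(hidden), +1/sqrt(hidden)); the two
#' affine maps use uniform(-1/sqrt(fan_in), +1/sqrt(fan_in)).
#'
#' @param cfg an [encoder_config()].
#' @return list with `layers` (LSTM layer parameter lists), `fc1`
#'   (hidden -> feature_dim), `proj` (feature_dim -> graph_dim).
#' @export
init_encoder_params <- function(cfg) {
  layers <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    in_dim <- if (l == 1L) cfg$input_dim else cfg$hidden_dim
    layers[[l]] <- init_lstm_layer(in_dim, cfg$hidden_dim,
                                   seed = cfg$seed + l,
                                   scale = cfg$init_scale %||% 1)
  }
  affine <- function(fin, fout, seed) {
    s <- 1 / sqrt(fin)
    list(W = with_seed(seed, matrix(stats::runif(fin * fout, -s, s), fin, fout)),
         b = numeric(fout))
  }
  list(layers = layers,
       fc1 = affine(cfg$hidden_dim, cfg$feature_dim, cfg$seed + 101L),
       proj = affine(cfg$feature_dim, cfg$graph_dim, cfg$seed + 102L))
}

# Build the B x d0 x L input array for a batch of coded sequences
# (codes: list of integer row indices into `vectors`; padded timesteps
# stay zero).
batch_inputs <- function(codes, vectors) {
  lens <- lengths(codes)
  B <- length(codes); L <- max(lens); d0 <- ncol(vectors)
  X <- array(0, c(B, d0, L))
  for (b in seq_len(B)) {
    X[b, , seq_len(lens[b])] <- t(vectors[codes[[b]], , drop = FALSE])
  }
  list(X = X, lens = lens)
}

# Forward pass of the full encoder on a prepared batch.
encoder_forward_batch <- function(X, lens, params, cfg) {
  Lmax <- dim(X)[3]
  caches <- vector("list", cfg$num_layers)
  cur <- X
  for (l in seq_len(cfg$num_layers)) {
    caches[[l]] <- lstm_layer_forward_batch(cur, lens, params$layers[[l]])
    # masked hidden outputs h_1..h_L feed the next layer
    cur <- caches[[l]]$H[, , 1L + seq_len(Lmax), drop = FALSE]
  }
  top <- caches[[cfg$num_layers]]
  if (cfg$summary == "final") {
    hbar <- top$H[, , Lmax + 1L]         # frozen at each sequence's end
    if (is.null(dim(hbar))) hbar <- matrix(hbar, nrow = dim(X)[1])
  } else {
    B <- length(lens)
    hbar <- matrix(0, B, cfg$hidden_dim)
    for (t in seq_len(Lmax)) {
      hbar <- hbar + top$H[, , t + 1L] * as.numeric(lens >= t)
    }
    hbar <- hbar / lens
  }
  feat <- sweep(hbar %*% params$fc1$W, 2, params$fc1$b, "+")
  e0 <- sweep(feat %*% params$proj$W, 2, params$proj$b, "+")
  list(feat = feat, e0 = e0,
       cache = list(caches = caches, hbar = hbar, feat = feat,
                    lens = lens, Lmax = Lmax))
}

# Backward pass; dE0 is B x graph_dim. Returns parameter gradients (same
# shape as params) and the gradients w.r.t. the base-embedding inputs.
encoder_backward_batch <- function(dE0, fw, params, cfg) {
  cache <- fw$cache
  dproj <- list(W = crossprod(cache$feat, dE0), b = colSums(dE0))
  dfeat <- tcrossprod(dE0, params$proj$W)
  dfc1 <- list(W = crossprod(cache$hbar, dfeat), b = colSums(dfeat))
  dhbar <- tcrossprod(dfeat, params$fc1$W)
  Lmax <- cache$Lmax
  B <- nrow(dhbar); H <- ncol(dhbar)
  dH_out <- array(0, c(B, H, Lmax))
  if (cfg$summary == "final") {
    dH_out[, , Lmax] <- dhbar
  } else {
    for (t in seq_len(Lmax)) {
      dH_out[, , t] <- dhbar * (as.numeric(cache$lens >= t) / cache$lens)
    }
  }
  dlayers <- vector("list", cfg$num_layers)
  for (l in rev(seq_len(cfg$num_layers))) {
    bk <- lstm_layer_backward_batch(cache$caches[[l]], dH_out)
    dlayers[[l]] <- list(W = bk$dW, b = bk$db)
    dH_out <- bk$dX
  }
  list(layers = dlayers, fc1 = dfc1, proj = dproj, dX = dH_out)
}

#' Encode sequences into feature and graph vectors
#'
#' Runs the full encoder (lookup, stacked LSTM, compression, projection)
#' over a set of records in one masked batch. Sequences longer than
#' `cfg$max_seq_len` are truncated to their 5' prefix. Batched and
#' per-sequence evaluation agree because states freeze at each sequence's
#' end, so padding never influences an output.
#'
#' @param records a `cmi_sequences` table; ids must be unique across kinds.
#' @param table a `cmi_base_embeddings` object.
#' @param cfg an [encoder_config()].
#' @param params encoder parameters (default: fresh [init_encoder_params()]).
#' @return list with `features` (N x feature_dim matrix, rownames = ids)
#'   and `graph` (N x graph_dim matrix).
#' @export
encode_sequences <- function(records, table, cfg = encoder_config(),
                             params = init_encoder_params(cfg)) {
  if (anyDuplicated(records$id)) {
    stopf("duplicate record id(s) across kinds: %s",
          paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  if (any(!nzchar(records$seq))) stopf("empty sequence(s) cannot be encoded")
  codes <- lapply(records$seq, function(s) {
    utils::head(seq_to_codes(s), cfg$max_seq_len)
  })
  bi <- batch_inputs(codes, table$vectors)
  fw <- encoder_forward_batch(bi$X, bi$lens, params, cfg)
  rownames(fw$feat) <- rownames(fw$e0) <- records$id
  list(features = fw$feat, graph = fw$e0)
}
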
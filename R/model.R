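# Joint model: encoder -> graph propagation -> inner-product scoring,
# trained end to end with Adam against binary cross-entropy. Every
# optimization step recomputes the full forward pass (all node embeddings),
# so collaborative gradients reach the encoder parameters.

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size labeled pairs per optimization step (default 128);
#'   values >= the number of pairs give full-batch training.
#' @param adam_betas Adam (beta1, beta2) (default c(0.9, 0.999)).
#' @param adam_eps Adam epsilon (default 1e-8).
#' @param epochs training epochs (default 100).
#' @param seed integer seed controlling shuffling, dropout and (via the
#'   component initializers) parameter draws.
#' @param embed_mode `"concat_layers"` (final node embedding is the
#'   concatenation of E0..EL, the collaborative-filtering lineage
#'   convention) or `"final_layer"`.
#' @param score_link `"sigmoid"` (default; maps the unbounded inner product
#'   into (0,1) before the cross-entropy) or `"raw"`.
#' @param finetune_base when `TRUE` the base-embedding table is trained
#'   jointly; by default it is held fixed after skip-gram pretraining.
#' @param clip_norm global gradient-norm ceiling (default 5); gradients are
#'   rescaled when their overall Euclidean norm exceeds it, which keeps
#'   aggressive learning rates stable. `Inf` disables clipping.
#' @param e0_init `"standardize"` (default) rescales the projection once at
#'   model creation so the initial node embeddings E0 have zero column mean
#'   and column standard deviation `e0_init_sd` across nodes; `"raw"` keeps
#'   the untouched random projection. A freshly initialized recurrent
#'   encoder maps every sequence close to a common attractor, so without
#'   this calibration the between-node spread of E0 — the only thing the
#'   inner-product score can rank by — starts orders of magnitude below its
#'   mean and the collaborative gradients are second-order small.
#' @param e0_init_sd target column sd of the standardized E0 (default 0.3).
#' @param e0_init_gain ceiling on the per-column rescaling factor (default
#'   20): an unbounded gain would equally amplify every subsequent change
#'   of the upstream encoder parameters, destabilizing training, so
#'   columns whose spread is far below target are only amplified this much.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 128L,
                         adam_betas = c(0.9, 0.999), adam_eps = 1e-8,
                         epochs = 100L, seed = 1L,
                         embed_mode = c("concat_layers", "final_layer"),
                         score_link = c("sigmoid", "raw"),
                         finetune_base = FALSE, clip_norm = 5,
                         e0_init = c("standardize", "raw"),
                         e0_init_sd = 0.3, e0_init_gain = 20) {
  embed_mode <- match.arg(embed_mode)
  score_link <- match.arg(score_link)
  e0_init <- match.arg(e0_init)
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, clip_norm > 0,
            e0_init_sd > 0, e0_init_gain >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 adam_betas = adam_betas, adam_eps = adam_eps,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 embed_mode = embed_mode, score_link = score_link,
                 finetune_base = finetune_base, clip_norm = clip_norm,
                 e0_init = e0_init, e0_init_sd = e0_init_sd,
                 e0_init_gain = e0_init_gain),
            class = "train_config")
}

# Data-dependent initialization of the projection layer: rescale each
# output column so E0 starts centered with the target between-node spread.
# Touches only the initial parameter values; the projection trains freely
# afterwards.
standardize_projection <- function(model, graph, batches) {
  cfg <- model$encoder_config
  enc <- model$params$enc
  fw_mir <- encoder_forward_batch(batches$mir$X, batches$mir$lens, enc, cfg)
  fw_circ <- encoder_forward_batch(batches$circ$X, batches$circ$lens, enc,
                                   cfg)
  feat <- rbind(fw_mir$feat, fw_circ$feat)
  W <- enc$proj$W
  e0 <- feat %*% W
  sds <- apply(e0, 2, stats::sd)
  target <- model$train_config$e0_init_sd
  scale <- ifelse(sds > 1e-12, target / sds, 1)
  scale <- pmin(scale, model$train_config$e0_init_gain)
  W <- sweep(W, 2, scale, "*")
  b <- -colMeans(feat %*% W)
  model$params$enc$proj$W <- W
  model$params$enc$proj$b <- b
  model
}

clip_grads <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  sq <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else sq <<- sq + sum(x^2)
    invisible()
  }
  walk(grads)
  nrm <- sqrt(sq)
  if (nrm <= clip_norm) grads
  else tree_map(function(g) g * (clip_norm / nrm), grads)
}

#' Score one pair from its final embeddings
#'
#' The interaction score is the inner product of the two final embeddings;
#' under the sigmoid link it is mapped into (0,1).
#'
#' @param e_m,e_c numeric vectors of equal length.
#' @param link `"sigmoid"` (default) or `"raw"`.
#' @return scalar score.
#' @export
score_pair <- function(e_m, e_c, link = c("sigmoid", "raw")) {
  link <- match.arg(link)
  if (length(e_m) != length(e_c)) stopf("embedding dimensions differ")
  s <- sum(e_m * e_c)
  if (link == "sigmoid") sigmoid(s) else s
}

#' Mean binary cross-entropy
#'
#' `-(1/k) sum[y log p + (1-y) log(1-p)]`, with probabilities clamped to
#' `[1e-7, 1 - 1e-7]` for numerical safety. Always nonnegative.
#'
#' @param y 0/1 labels.
#' @param p predicted probabilities.
#' @return scalar loss.
#' @export
bce_loss <- function(y, p) {
  if (length(y) == 0) stopf("bce_loss needs at least one observation")
  if (length(y) != length(p)) stopf("labels and probabilities differ in length")
  p <- clamp_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- parameter trees -------------------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}
tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x)); names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else f(x, y)
}
tree_zeros <- function(x) tree_map(function(v) v * 0, x)

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# ---- model state -----------------------------------------------------------

# Trainable parameters live under model$params:
#   $enc  (layers/fc1/proj)   $prop ($W1, $W2)   [$base when finetuning]
new_cmi_model <- function(base, enc_cfg, enc_params, prop, cfg) {
  # only numeric leaves live in the trainable tree (layer dims are
  # recovered from the packed weight shapes)
  enc_params$layers <- lapply(enc_params$layers,
                              function(l) list(W = l$W, b = l$b))
  trainable <- list(enc = enc_params, prop = list(W1 = prop$W1, W2 = prop$W2))
  if (cfg$finetune_base) trainable$base <- base$vectors
  structure(list(schema = 1L, base = base, encoder_config = enc_cfg,
                 propagation = prop, train_config = cfg,
                 params = trainable, opt = adam_init(trainable),
                 epoch = 0L, history = numeric(0)),
            class = "cmi_model")
}

model_base_vectors <- function(model) {
  if (!is.null(model$params$base)) model$params$base else model$base$vectors
}

model_prop_params <- function(model) {
  p <- model$propagation
  p$W1 <- model$params$prop$W1
  p$W2 <- model$params$prop$W2
  p
}

# Align sequence records with graph node order and pre-slice the LSTM
# inputs (one batch per kind; miRNAs are short, circRNAs long, so batching
# them separately avoids padding every miRNA to circRNA length).
prepare_node_batches <- function(graph, sequences, model) {
  cfg <- model$encoder_config
  miss <- setdiff(graph$node_ids, sequences$id)
  if (length(miss)) {
    stopf("graph node(s) without a sequence: %s", paste(miss, collapse = ", "))
  }
  vectors <- model_base_vectors(model)
  codes_of <- function(ids) {
    rows <- sequences[match(ids, sequences$id), ]
    lapply(rows$seq, function(s) utils::head(seq_to_codes(s), cfg$max_seq_len))
  }
  mir_codes <- codes_of(graph$mir_ids)
  circ_codes <- codes_of(graph$circ_ids)
  list(mir = batch_inputs(mir_codes, vectors),
       circ = batch_inputs(circ_codes, vectors),
       mir_codes = mir_codes, circ_codes = circ_codes)
}

model_forward <- function(model, graph, batches, mode = "eval") {
  cfg <- model$encoder_config
  enc <- model$params$enc
  fw_mir <- encoder_forward_batch(batches$mir$X, batches$mir$lens, enc, cfg)
  fw_circ <- encoder_forward_batch(batches$circ$X, batches$circ$lens, enc,
                                   cfg)
  E0 <- rbind(fw_mir$e0, fw_circ$e0)
  prop <- model_prop_params(model)
  Es <- vector("list", prop$num_layers + 1L)
  caches <- vector("list", prop$num_layers)
  Es[[1]] <- E0
  for (l in seq_len(prop$num_layers)) {
    st <- propagate_layer_forward(Es[[l]], graph$L, prop, l,
                                  training = (mode == "train"))
    Es[[l + 1L]] <- st$out
    caches[[l]] <- st$cache
  }
  E_final <- if (model$train_config$embed_mode == "concat_layers") {
    do.call(cbind, Es)
  } else {
    Es[[prop$num_layers + 1L]]
  }
  rownames(E_final) <- graph$node_ids
  list(E_final = E_final, Es = Es, caches = caches,
       fw_mir = fw_mir, fw_circ = fw_circ)
}

#' Final embeddings for every graph node
#'
#' Runs the full forward pass (encoder, propagation stack) and assembles
#' the per-node final embedding according to the configured `embed_mode`
#' (`concat_layers` gives width `d * (num_layers + 1)`).
#'
#' @param model a trained (or freshly initialized) `cmi_model`.
#' @param graph a `cmi_graph`.
#' @param sequences a `cmi_sequences` table covering every node.
#' @param mode `"eval"` (deterministic, the default) or `"train"`
#'   (dropout active, drawing from the current RNG stream).
#' @return (n+m) x D matrix, rownames = node ids (miRNAs then circRNAs).
#' @export
forward_all <- function(model, graph, sequences, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  batches <- prepare_node_batches(graph, sequences, model)
  model_forward(model, graph, batches, mode)$E_final
}

# Loss and gradients for one labeled mini-batch of pairs.
# pair_idx: list(mir_node, circ_node, y) with node indices in graph order.
model_loss_grads <- function(model, graph, batches, pair_idx, mode = "train") {
  cfg <- model$encoder_config
  prop <- model_prop_params(model)
  fw <- model_forward(model, graph, batches, mode)
  Ef <- fw$E_final
  mi <- pair_idx$mir_node; ci <- pair_idx$circ_node; y <- pair_idx$y
  s <- rowSums(Ef[mi, , drop = FALSE] * Ef[ci, , drop = FALSE])
  p <- if (model$train_config$score_link == "sigmoid") sigmoid(s) else s
  loss <- bce_loss(y, p)
  k <- length(y)
  dlogit <- (clamp_prob(p) - y) / k        # d loss / d s under the sigmoid link
  dEf <- matrix(0, nrow(Ef), ncol(Ef))
  add_grad <- function(dEf, rows, contrib) {
    agg <- rowsum(contrib, rows)
    at <- as.integer(rownames(agg))
    dEf[at, ] <- dEf[at, , drop = FALSE] + agg
    dEf
  }
  dEf <- add_grad(dEf, mi, dlogit * Ef[ci, , drop = FALSE])
  dEf <- add_grad(dEf, ci, dlogit * Ef[mi, , drop = FALSE])
  nl <- prop$num_layers
  d <- prop$d
  dEs <- vector("list", nl + 1L)
  if (model$train_config$embed_mode == "concat_layers") {
    for (l in seq_len(nl + 1L)) {
      dEs[[l]] <- dEf[, ((l - 1L) * d + 1L):(l * d), drop = FALSE]
    }
  } else {
    for (l in seq_len(nl)) dEs[[l]] <- matrix(0, nrow(Ef), d)
    dEs[[nl + 1L]] <- dEf
  }
  gW1 <- vector("list", nl); gW2 <- vector("list", nl)
  dcur <- dEs[[nl + 1L]]
  for (l in rev(seq_len(nl))) {
    bk <- propagate_layer_backward(dcur, fw$caches[[l]], prop)
    gW1[[l]] <- bk$dW1; gW2[[l]] <- bk$dW2
    dcur <- bk$dE_prev + dEs[[l]]
  }
  dE0 <- dcur
  n <- graph$n
  bk_mir <- encoder_backward_batch(dE0[seq_len(n), , drop = FALSE],
                                   fw$fw_mir, model$params$enc, cfg)
  bk_circ <- encoder_backward_batch(dE0[-seq_len(n), , drop = FALSE],
                                    fw$fw_circ, model$params$enc, cfg)
  genc <- tree_map2(`+`,
                    list(layers = bk_mir$layers, fc1 = bk_mir$fc1,
                         proj = bk_mir$proj),
                    list(layers = bk_circ$layers, fc1 = bk_circ$fc1,
                         proj = bk_circ$proj))
  grads <- list(enc = genc, prop = list(W1 = gW1, W2 = gW2))
  if (!is.null(model$params$base)) {
    dV <- matrix(0, 4, ncol(model$params$base))
    accum <- function(dV, bk, codes) {
      for (t in seq_len(dim(bk$dX)[3])) {
        act <- which(lengths(codes) >= t)
        if (!length(act)) next
        at <- vapply(codes[act], `[`, integer(1), t)
        agg <- rowsum(matrix(bk$dX[act, , t], ncol = ncol(dV)), at)
        rows <- as.integer(rownames(agg))
        dV[rows, ] <- dV[rows, , drop = FALSE] + agg
      }
      dV
    }
    dV <- accum(dV, bk_mir, batches$mir_codes)
    dV <- accum(dV, bk_circ, batches$circ_codes)
    grads$base <- dV
  }
  list(loss = loss, grads = grads, scores = p)
}

assert_no_leakage <- function(graph, table) {
  pos <- table[table$label == 1L, ]
  edge_keys <- paste(rep(graph$mir_ids, times = graph$m)[graph$R == 1],
                     rep(graph$circ_ids, each = graph$n)[graph$R == 1])
  pos_keys <- paste(pos$miRNA, pos$circRNA)
  extra <- setdiff(edge_keys, pos_keys)
  if (length(extra)) {
    stopf("leakage: %d graph edge(s) are not training positives (e.g. %s)",
          length(extra), extra[1])
  }
  invisible(TRUE)
}

#' Train the joint model
#'
#' Jointly optimizes the encoder, the projection, and the propagation
#' weights with Adam against mean binary cross-entropy on the labeled
#' pairs. Each mini-batch step recomputes the full forward pass over all
#' nodes, so the collaborative signal mined by the propagation layers
#' back-propagates into the sequence encoder. The propagation graph must
#' be built from the training positives only; an edge without a matching
#' training positive raises a leakage error.
#'
#' @param data a `cmi_interactions` table with positives and negatives.
#' @param graph a `cmi_graph` built from `data`'s positives.
#' @param sequences a `cmi_sequences` table covering every node.
#' @param cfg a [train_config()].
#' @param encoder an [encoder_config()].
#' @param propagation optional `propagation_params` (default: fresh
#'   initialization at `d = encoder$graph_dim`).
#' @param base optional pretrained `cmi_base_embeddings`; by default a
#'   skip-gram table is trained on the pooled sequences.
#' @param model optionally continue training an existing `cmi_model`.
#' @param verbose print the epoch losses.
#' @return a `cmi_model` with `history` holding the per-epoch mean
#'   training loss.
#' @export
train_model <- function(data, graph, sequences, cfg = train_config(),
                        encoder = encoder_config(), propagation = NULL,
                        base = NULL, model = NULL, verbose = FALSE) {
  if (!any(data$label == 1L) || !any(data$label == 0L)) {
    stopf("training data must contain both positives and negatives")
  }
  assert_no_leakage(graph, data)
  if (is.null(model)) {
    base <- base %||% train_base_embeddings(
      sequences, skipgram_config(dim = encoder$input_dim, seed = cfg$seed))
    if (ncol(base$vectors) != encoder$input_dim) {
      stopf("base embedding width %d does not match encoder input_dim %d",
            ncol(base$vectors), encoder$input_dim)
    }
    propagation <- propagation %||%
      init_propagation_params(d = encoder$graph_dim, seed = cfg$seed + 7L)
    model <- new_cmi_model(base, encoder, init_encoder_params(encoder),
                           propagation, cfg)
    if (cfg$e0_init == "standardize") {
      model <- standardize_projection(model, graph,
                                      prepare_node_batches(graph, sequences,
                                                           model))
    }
  }
  batches <- prepare_node_batches(graph, sequences, model)
  mir_node <- match(data$miRNA, graph$mir_ids)
  circ_node <- graph$n + match(data$circRNA, graph$circ_ids)
  y <- data$label
  n_pairs <- length(y)
  bs <- min(cfg$batch_size, n_pairs)
  with_seed(cfg$seed + model$epoch, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_pairs)
      n_batches <- ceiling(n_pairs / bs)
      ep_loss <- 0
      for (bb in seq_len(n_batches)) {
        take <- ord[((bb - 1L) * bs + 1L):min(bb * bs, n_pairs)]
        res <- model_loss_grads(model, graph, batches,
                                list(mir_node = mir_node[take],
                                     circ_node = circ_node[take],
                                     y = y[take]),
                                mode = "train")
        st <- adam_step(model$params, clip_grads(res$grads, cfg$clip_norm),
                        model$opt, cfg$lr, cfg$adam_betas, cfg$adam_eps)
        model$params <- st$params
        model$opt <- st$state
        if (!is.null(model$params$base)) {
          batches <- prepare_node_batches(graph, sequences, model)
        }
        ep_loss <- ep_loss + res$loss * length(take)
      }
      model$epoch <- model$epoch + 1L
      model$history <- c(model$history, ep_loss / n_pairs)
      if (verbose) {
        message(sprintf("epoch %d: loss %.6f", model$epoch,
                        ep_loss / n_pairs))
      }
    }
  })
  model
}

#' Score labeled or unlabeled pairs with a trained model
#'
#' @param model a `cmi_model`.
#' @param graph a `cmi_graph`.
#' @param sequences a `cmi_sequences` table.
#' @param pairs data.frame with columns `circRNA`, `miRNA`.
#' @return numeric vector of scores (probabilities under the sigmoid link).
#' @export
predict_pairs <- function(model, graph, sequences, pairs) {
  Ef <- forward_all(model, graph, sequences, mode = "eval")
  mi <- match(pairs$miRNA, graph$mir_ids)
  ci <- graph$n + match(pairs$circRNA, graph$circ_ids)
  if (anyNA(mi) || anyNA(ci)) stopf("pair ids outside the graph universe")
  s <- rowSums(Ef[mi, , drop = FALSE] * Ef[ci, , drop = FALSE])
  if (model$train_config$score_link == "sigmoid") sigmoid(s) else s
}

#' Rank unknown candidate pairs
#'
#' Scores every (circRNA, miRNA) pair outside `exclude` (by default the
#' graph's training positives) and returns the top `K` by descending
#' score; ties are broken by (circRNA, miRNA) lexicographic order.
#' Ordering uses the raw inner product — the sigmoid is monotone, so the
#' ranking is identical, but a confidently trained model saturates the
#' sigmoid to 1 in floating point and would otherwise reduce the top of
#' the list to the tie-break.
#'
#' @param model a trained `cmi_model`.
#' @param graph a `cmi_graph`.
#' @param sequences a `cmi_sequences` table.
#' @param K number of candidates to return.
#' @param exclude optional data.frame with columns `circRNA`, `miRNA` of
#'   pairs never to return.
#' @return data.frame with columns `rank`, `circRNA`, `miRNA`, `score`.
#' @export
rank_candidates <- function(model, graph, sequences, K = 20L,
                            exclude = NULL) {
  all_pairs <- expand.grid(miRNA = graph$mir_ids, circRNA = graph$circ_ids,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  known <- graph$R[cbind(match(all_pairs$miRNA, graph$mir_ids),
                         match(all_pairs$circRNA, graph$circ_ids))] == 1
  drop <- known
  if (!is.null(exclude)) {
    drop <- drop | paste(all_pairs$circRNA, all_pairs$miRNA) %in%
      paste(exclude$circRNA, exclude$miRNA)
  }
  cand <- all_pairs[!drop, , drop = FALSE]
  if (K == 0L || nrow(cand) == 0L) {
    return(data.frame(rank = integer(0), circRNA = character(0),
                      miRNA = character(0), score = numeric(0)))
  }
  if (K > nrow(cand)) {
    warning(sprintf("K = %d exceeds the %d candidate pairs; returning all",
                    K, nrow(cand)))
    K <- nrow(cand)
  }
  raw_model <- model
  raw_model$train_config$score_link <- "raw"
  raw <- predict_pairs(raw_model, graph, sequences, cand)
  cand$score <- if (model$train_config$score_link == "sigmoid") {
    sigmoid(raw)
  } else {
    raw
  }
  ord <- order(-raw, cand$circRNA, cand$miRNA)
  top <- cand[ord[seq_len(K)], c("circRNA", "miRNA", "score")]
  rownames(top) <- NULL
  cbind(rank = seq_len(K), top)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is the full model state (parameters, optimizer moments,
#' epoch counter, configurations, schema version); saving and re-loading
#' round-trips exactly.
#'
#' @param model a `cmi_model`.
#' @param path file path.
#' @return `load_model` returns the `cmi_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cmi_model")) stopf("not a cmi_model checkpoint: %s", path)
  model
}
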
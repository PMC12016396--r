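test_that("score_pair follows the sigmoid of the inner product", {
  expect_equal(score_pair(c(1, 0), c(0, 1)), 0.5)
  expect_equal(score_pair(c(log(3), 1), c(1, 0)), 0.75)
  e1 <- rnorm(5); e2 <- rnorm(5)
  expect_equal(score_pair(e1, e2), score_pair(e2, e1))
  expect_equal(score_pair(e1, e2, link = "raw"), sum(e1 * e2))
  expect_error(score_pair(1:3, 1:4), "dimensions")
})

test_that("bce_loss matches closed forms and is monotone", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(1, 0), c(1 - 1e-12, 1e-12)), 1e-5)
  expect_gt(bce_loss(1, 0.25), bce_loss(1, 0.75))
  expect_error(bce_loss(numeric(0), numeric(0)), "at least one")
})

test_that("forward_all assembles final embeddings per embed_mode", {
  tt <- tiny_trained()
  Ef <- forward_all(tt$model, tt$graph, tt$fix$ds$sequences)
  # concat of E0..E3 at graph_dim 4 -> 16 columns
  expect_equal(ncol(Ef), 4 * (3 + 1))
  expect_equal(nrow(Ef), tt$graph$n + tt$graph$m)
  expect_equal(rownames(Ef), tt$graph$node_ids)
  # eval mode is deterministic
  expect_identical(Ef, forward_all(tt$model, tt$graph, tt$fix$ds$sequences))
  # final_layer mode yields graph_dim columns
  m2 <- tt$model; m2$train_config$embed_mode <- "final_layer"
  expect_equal(ncol(forward_all(m2, tt$graph, tt$fix$ds$sequences)), 4)
})

test_that("a missing node sequence is reported by name", {
  tt <- tiny_trained()
  seqs <- tt$fix$ds$sequences
  drop <- seqs$id[3]
  expect_error(forward_all(tt$model, tt$graph, seqs[seqs$id != drop, ]),
               drop)
})

test_that("training reduces the loss on a planted dataset and is deterministic", {
  fix <- tiny_dataset(n_circ = 12, n_mir = 8, seed = 31, beta = 3)
  graph <- build_graph(fix$tab, fix$ids$circ, fix$ids$mir)
  enc <- encoder_config(input_dim = 6, hidden_dim = 5, num_layers = 2,
                        feature_dim = 8, graph_dim = 4, seed = 3)
  cfg <- train_config(lr = 5e-3, batch_size = 1000L, epochs = 8, seed = 9)
  base <- train_base_embeddings(fix$ds$sequences,
                                skipgram_config(dim = 6, epochs = 10,
                                                seed = 2))
  m1 <- train_model(fix$tab, graph, fix$ds$sequences, cfg = cfg,
                    encoder = enc, base = base)
  expect_lt(tail(m1$history, 1), m1$history[1])
  m2 <- train_model(fix$tab, graph, fix$ds$sequences, cfg = cfg,
                    encoder = enc, base = base)
  expect_equal(m1$history, m2$history, tolerance = 1e-6)
  expect_equal(m1$params, m2$params, tolerance = 1e-12)
})

test_that("mini-batching honors batch_size with a partial final batch", {
  fix <- tiny_dataset(n_circ = 10, n_mir = 6, seed = 41)
  graph <- build_graph(fix$tab, fix$ids$circ, fix$ids$mir)
  enc <- encoder_config(input_dim = 6, hidden_dim = 4, num_layers = 1,
                        feature_dim = 6, graph_dim = 3, seed = 3)
  base <- train_base_embeddings(fix$ds$sequences,
                                skipgram_config(dim = 6, epochs = 5,
                                                seed = 2))
  n_pairs <- nrow(fix$tab)
  bs <- 16L
  cfg <- train_config(lr = 1e-3, batch_size = bs, epochs = 1, seed = 9)
  m <- train_model(fix$tab, graph, fix$ds$sequences, cfg = cfg,
                   encoder = enc, base = base)
  # one Adam step per batch, ceiling(n/bs) batches per epoch
  expect_equal(m$opt$t, as.integer(ceiling(n_pairs / bs)))
})

test_that("training refuses graphs containing non-training edges", {
  fix <- tiny_dataset(seed = 51)
  graph <- build_graph(fix$tab, fix$ids$circ, fix$ids$mir)
  pos_idx <- which(fix$tab$label == 1L)
  smaller <- fix$tab[-pos_idx[1], ]
  class(smaller) <- class(fix$tab)
  expect_error(train_model(smaller, graph, fix$ds$sequences,
                           cfg = train_config(epochs = 1L)),
               "leakage")
})

test_that("checkpoints round-trip bit-identically", {
  tt <- tiny_trained()
  path <- tempfile(fileext = ".rds")
  save_model(tt$model, path)
  back <- load_model(path)
  expect_identical(back, tt$model)
  s1 <- predict_pairs(tt$model, tt$graph, tt$fix$ds$sequences,
                      tt$fix$tab[1:5, ])
  s2 <- predict_pairs(back, tt$graph, tt$fix$ds$sequences,
                      tt$fix$tab[1:5, ])
  expect_identical(s1, s2)
})

test_that("rank_candidates: exclusion, shape, ordering, determinism", {
  tt <- tiny_trained()
  top <- rank_candidates(tt$model, tt$graph, tt$fix$ds$sequences, K = 10)
  expect_equal(nrow(top), 10)
  expect_equal(top$rank, 1:10)
  expect_true(all(diff(top$score) <= 1e-12))
  # no returned pair is a training positive (graph edge)
  pos <- tt$fix$tab[tt$fix$tab$label == 1L, ]
  expect_false(any(paste(top$circRNA, top$miRNA) %in%
                     paste(pos$circRNA, pos$miRNA)))
  top2 <- rank_candidates(tt$model, tt$graph, tt$fix$ds$sequences, K = 10)
  expect_identical(top, top2)
  expect_equal(nrow(rank_candidates(tt$model, tt$graph,
                                    tt$fix$ds$sequences, K = 0)), 0)
  expect_warning(
    all_ranked <- rank_candidates(tt$model, tt$graph, tt$fix$ds$sequences,
                                  K = 10000L),
    "exceeds")
  expect_equal(nrow(all_ranked),
               tt$graph$n * tt$graph$m - sum(tt$graph$R == 1))
})

test_that("analytic gradients of the full model match finite differences", {
  fix <- tiny_dataset(n_circ = 5, n_mir = 4, seed = 61)
  graph <- build_graph(fix$tab, fix$ids$circ, fix$ids$mir)
  enc <- encoder_config(input_dim = 4, hidden_dim = 3, num_layers = 2,
                        feature_dim = 5, graph_dim = 3, seed = 4)
  cfg <- train_config(seed = 5, finetune_base = TRUE)
  base <- train_base_embeddings(fix$ds$sequences,
                                skipgram_config(dim = 4, epochs = 5,
                                                seed = 6))
  prop <- init_propagation_params(d = 3, num_layers = 2, node_dropout = 0,
                                  mess_dropout = 0, seed = 8)
  model <- cmiCollab:::new_cmi_model(base, enc, init_encoder_params(enc),
                                     prop, cfg)
  batches <- cmiCollab:::prepare_node_batches(graph, fix$ds$sequences,
                                              model)
  pidx <- list(mir_node = match(fix$tab$miRNA, graph$mir_ids),
               circ_node = graph$n + match(fix$tab$circRNA,
                                           graph$circ_ids),
               y = fix$tab$label)
  res <- cmiCollab:::model_loss_grads(model, graph, batches, pidx,
                                      mode = "eval")
  p0 <- model$params
  loss_at <- function(params) {
    m2 <- model; m2$params <- params
    b2 <- cmiCollab:::prepare_node_batches(graph, fix$ds$sequences, m2)
    cmiCollab:::model_loss_grads(m2, graph, b2, pidx, mode = "eval")$loss
  }
  eps <- 1e-5
  set.seed(123)
  check_leaf <- function(path, x) {
    if (is.list(x)) {
      for (i in seq_along(x)) check_leaf(c(path, i), x[[i]])
      return(invisible())
    }
    for (j in sample(length(x), min(3, length(x)))) {
      pp <- p0
      v <- pp[[path]]; v[j] <- v[j] + eps; pp[[path]] <- v
      up <- loss_at(pp)
      v[j] <- v[j] - 2 * eps; pp[[path]] <- v
      dn <- loss_at(pp)
      gn <- (up - dn) / (2 * eps)
      ga <- res$grads[[path]][j]
      expect_equal(ga, gn, tolerance = 1e-4)
    }
  }
  check_leaf(integer(0), p0)
})
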
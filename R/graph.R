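# Bipartite interaction graph and multi-layer collaborative message
# propagation.
#
# Node order is always miRNAs first, then circRNAs. With R the n x m
# binary interaction matrix (n miRNAs, m circRNAs), the adjacency is the
# bipartite block matrix A = [[0, R], [R^T, 0]] and the propagation
# operator is the self-loop-renormalized
#   Lhat = D^(-1/2) (A + I) D^(-1/2),
# where D is the degree matrix of (A + I). Including the self-loop in D
# keeps isolated nodes well-defined and bounds Lhat's spectrum by 1.
#
# One propagation layer (matrix form, the canonical path):
#   E^(l) = LeakyReLU( Lhat E^(l-1) W1 + (E^(l-1) o Lhat E^(l-1)) W2 )
# Row c of Lhat E^(l-1) is sum_j Lhat_cj e_j, so each incoming edge
# contributes 1/sqrt((|N_c|+1)(|N_j|+1)) * (e_j W1 + (e_j o e_c) W2) and the
# self term carries the same normalization with coefficient 1/(|N_c|+1).
# The per-node form below reproduces exactly this and serves as the
# brute-force oracle for the matrix path.

#' Build the bipartite adjacency matrix
#'
#' @param R n x m binary interaction matrix (miRNAs x circRNAs).
#' @return sparse symmetric (n+m) x (n+m) adjacency with zero diagonal
#'   blocks, nodes ordered miRNAs then circRNAs.
#' @export
build_adjacency <- function(R) {
  R <- unname(as.matrix(R))
  if (!all(R %in% c(0, 1))) stopf("interaction matrix must be binary")
  n <- nrow(R); m <- ncol(R)
  A <- rbind(cbind(matrix(0, n, n), R),
             cbind(t(R), matrix(0, m, m)))
  methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Self-loop-renormalized propagation operator
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` with `D` the degree matrix of
#' `A + I`. All eigenvalues of the result lie in `[-1, 1]`.
#'
#' @param A symmetric nonnegative adjacency (dense or sparse).
#' @return sparse symmetric operator of the same dimension.
#' @export
normalized_laplacian <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  if (!Matrix::isSymmetric(A)) stopf("adjacency must be symmetric")
  Ahat <- A + Matrix::Diagonal(nrow(A))
  dinv <- 1 / sqrt(Matrix::rowSums(Ahat))
  L <- Matrix::Diagonal(x = dinv) %*% Ahat %*% Matrix::Diagonal(x = dinv)
  methods::as(methods::as(L, "generalMatrix"), "CsparseMatrix")
}

#' Build the bipartite CMI graph from an interaction table
#'
#' Uses only the positive pairs of `table` as edges (negatives and held-out
#' pairs must never enter the propagation operator).
#'
#' @param table a `cmi_interactions` table.
#' @param circ_ids,mir_ids node universes (order fixes node indexing).
#' @return object of class `cmi_graph`: list with `n` (miRNAs), `m`
#'   (circRNAs), `mir_ids`, `circ_ids`, `R`, `A`, `L`, `node_ids`
#'   (miRNAs then circRNAs).
#' @export
build_graph <- function(table, circ_ids, mir_ids) {
  pos <- table[table$label == 1L, , drop = FALSE]
  ci <- match(pos$circRNA, circ_ids)
  mi <- match(pos$miRNA, mir_ids)
  if (anyNA(ci) || anyNA(mi)) stopf("interaction table contains ids outside the graph universe")
  n <- length(mir_ids); m <- length(circ_ids)
  R <- matrix(0, n, m, dimnames = list(mir_ids, circ_ids))
  R[cbind(mi, ci)] <- 1
  A <- build_adjacency(R)
  structure(list(n = n, m = m, mir_ids = mir_ids, circ_ids = circ_ids,
                 R = R, A = A, L = normalized_laplacian(A),
                 node_ids = c(mir_ids, circ_ids)),
            class = "cmi_graph")
}

#' Propagation parameters
#'
#' Per layer, two d x d weight matrices: `W1` transforms the propagated
#' embedding, `W2` the elementwise interaction term. Xavier-uniform
#' initialization, seeded.
#'
#' @param d embedding width per layer (default 64).
#' @param num_layers number of message-passing layers (default 3).
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @param node_dropout probability of dropping a nonzero of the propagation
#'   operator during training (default 0.1).
#' @param mess_dropout probability of dropping an output activation during
#'   training (default 0.1).
#' @param seed integer seed.
#' @return list of class `propagation_params` with `W1`, `W2` (lists of
#'   matrices) and the scalar settings.
#' @export
init_propagation_params <- function(d = 64L, num_layers = 3L,
                                    leaky_slope = 0.2,
                                    node_dropout = 0.1, mess_dropout = 0.1,
                                    seed = 1L) {
  stopifnot(num_layers >= 1, d >= 1,
            node_dropout >= 0, node_dropout < 1,
            mess_dropout >= 0, mess_dropout < 1)
  s <- sqrt(6 / (d + d))
  mats <- with_seed(seed, lapply(seq_len(2L * num_layers), function(i) {
    matrix(stats::runif(d * d, -s, s), d, d)
  }))
  structure(list(W1 = mats[seq_len(num_layers)],
                 W2 = mats[num_layers + seq_len(num_layers)],
                 d = as.integer(d), num_layers = as.integer(num_layers),
                 leaky_slope = leaky_slope,
                 node_dropout = node_dropout, mess_dropout = mess_dropout),
            class = "propagation_params")
}

#' Single edge message
#'
#' The message passed from node m to node c:
#' `(1/sqrt(deg_c * deg_m)) * (e_m W1 + (e_m o e_c) W2)`. Weights act on
#' the right, matching the matrix-form convention. Callers supply the
#' degrees that define the normalization (the propagation operator uses
#' self-loop-augmented degrees).
#'
#' @param e_m,e_c embedding vectors (length d).
#' @param W1,W2 d x d weight matrices.
#' @param deg_c,deg_m positive degrees.
#' @return message vector of length d.
#' @export
compute_message <- function(e_m, e_c, W1, W2, deg_c, deg_m) {
  if (deg_c < 1 || deg_m < 1) stopf("message requires both degrees >= 1")
  as.vector((e_m %*% W1 + (e_m * e_c) %*% W2) / sqrt(deg_c * deg_m))
}

#' Per-node propagation (brute-force oracle)
#'
#' Computes one node's layer-(l) embedding by explicit summation over its
#' self term and incoming edge messages, with every term normalized by the
#' self-loop-augmented degrees — exactly the corresponding row of the
#' matrix form. Quadratic and only used for verification.
#'
#' @param node node index in `1..(n+m)` (miRNAs first).
#' @param E_prev (n+m) x d embedding matrix of the previous layer.
#' @param graph a `cmi_graph`.
#' @param params `propagation_params`.
#' @param layer layer index.
#' @return d-vector.
#' @export
propagate_node <- function(node, E_prev, graph, params, layer = 1L) {
  W1 <- params$W1[[layer]]; W2 <- params$W2[[layer]]
  A <- as.matrix(graph$A)
  deg <- rowSums(A) + 1                  # self-loop-augmented
  e_c <- E_prev[node, ]
  acc <- compute_message(e_c, e_c, W1, W2, deg[node], deg[node])
  for (j in which(A[node, ] > 0)) {
    acc <- acc + compute_message(E_prev[j, ], e_c, W1, W2, deg[node], deg[j])
  }
  leaky_relu(acc, params$leaky_slope)
}

# Shared forward core; returns the output and the cache backward needs.
# Dropout masks are drawn from the current RNG stream when training.
propagate_layer_forward <- function(E_prev, Lmat, params, layer,
                                    training = FALSE) {
  W1 <- params$W1[[layer]]; W2 <- params$W2[[layer]]
  Luse <- Lmat
  if (training && params$node_dropout > 0) {
    nz <- length(Luse@x)
    keep <- stats::runif(nz) >= params$node_dropout
    Luse@x <- Luse@x * keep / (1 - params$node_dropout)
  }
  M <- as.matrix(Luse %*% E_prev)
  Z <- M %*% W1 + (E_prev * M) %*% W2
  out <- leaky_relu(Z, params$leaky_slope)
  mess_mask <- NULL
  if (training && params$mess_dropout > 0) {
    mess_mask <- matrix(stats::runif(length(out)) >= params$mess_dropout,
                        nrow(out), ncol(out))
    out <- out * mess_mask / (1 - params$mess_dropout)
  }
  list(out = out, cache = list(E_prev = E_prev, L = Luse, M = M, Z = Z,
                               mess_mask = mess_mask, layer = layer))
}

propagate_layer_backward <- function(dOut, cache, params) {
  W1 <- params$W1[[cache$layer]]; W2 <- params$W2[[cache$layer]]
  if (!is.null(cache$mess_mask)) {
    dOut <- dOut * cache$mess_mask / (1 - params$mess_dropout)
  }
  dZ <- dOut * leaky_relu_grad(cache$Z, params$leaky_slope)
  dW1 <- crossprod(cache$M, dZ)
  dW2 <- crossprod(cache$E_prev * cache$M, dZ)
  dZW2 <- tcrossprod(dZ, W2)
  dM <- tcrossprod(dZ, W1) + cache$E_prev * dZW2
  dE_prev <- as.matrix(Matrix::crossprod(cache$L, dM)) + cache$M * dZW2
  list(dW1 = dW1, dW2 = dW2, dE_prev = dE_prev)
}

#' One matrix-form propagation layer
#'
#' @param E_prev (n+m) x d embedding matrix.
#' @param L propagation operator (from [normalized_laplacian()]).
#' @param params `propagation_params`.
#' @param layer layer index.
#' @param training when `TRUE`, node dropout (on the operator's nonzeros)
#'   and message dropout (inverted dropout on the output) are applied using
#'   the current RNG stream; when `FALSE` the layer is deterministic.
#' @return (n+m) x d matrix `E^(layer)`.
#' @export
propagate_matrix <- function(E_prev, L, params, layer = 1L,
                             training = FALSE) {
  propagate_layer_forward(E_prev, L, params, layer, training)$out
}

#' Stack all propagation layers
#'
#' @param E0 initial embedding matrix ((n+m) x d).
#' @param graph a `cmi_graph`.
#' @param params `propagation_params`.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @return list of `num_layers + 1` matrices: `E0, E1, ..., EL`.
#' @export
stack_layers <- function(E0, graph, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (params$num_layers < 1) stopf("at least one propagation layer is required")
  Es <- vector("list", params$num_layers + 1L)
  Es[[1]] <- E0
  for (l in seq_len(params$num_layers)) {
    Es[[l + 1L]] <- propagate_matrix(Es[[l]], graph$L, params, l,
                                     training = (mode == "train"))
  }
  Es
}
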
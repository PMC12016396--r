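test_that("adjacency has the bipartite block structure", {
  A <- as.matrix(build_adjacency(matrix(1, 1, 1)))
  expect_equal(A, matrix(c(0, 1, 1, 0), 2, 2))
  A0 <- as.matrix(build_adjacency(matrix(0, 2, 3)))
  expect_equal(A0, matrix(0, 5, 5))
  set.seed(3)
  R <- matrix(0, 4, 6); R[sample(24, 7)] <- 1
  A7 <- build_adjacency(R)
  expect_equal(sum(A7), 14)
  expect_true(Matrix::isSymmetric(A7))
  expect_error(build_adjacency(matrix(2, 1, 1)), "binary")
})

test_that("normalized operator matches hand linear algebra and edge cases", {
  # single interaction: A+I is the all-ones 2x2, D = diag(2,2)
  L1 <- as.matrix(normalized_laplacian(build_adjacency(matrix(1, 1, 1))))
  expect_equal(L1, matrix(0.5, 2, 2))
  # edgeless graph reduces to the identity
  L0 <- as.matrix(normalized_laplacian(build_adjacency(matrix(0, 2, 2))))
  expect_equal(L0, diag(4))
})

test_that("spectral bound holds on random graphs (dense eigensolver oracle)", {
  set.seed(12)
  for (rep in 1:100) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    R <- matrix(rbinom(n * m, 1, runif(1, 0.1, 0.9)), n, m)
    L <- as.matrix(normalized_laplacian(build_adjacency(R)))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-9)
  }
})

test_that("single messages follow the normalized two-term form", {
  v <- c(1, -1); I2 <- diag(2); Z2 <- matrix(0, 2, 2)
  expect_equal(compute_message(v, c(5, 5), I2, Z2, 1, 1), v)
  expect_equal(compute_message(v, c(5, 5), I2, Z2, 4, 1), v / 2)
  expect_equal(compute_message(v, v, Z2, I2, 1, 1), c(1, 1))
  expect_error(compute_message(v, v, I2, Z2, 0, 1), "degree")
})

test_that("isolated node reduces to the unit-normalized self path", {
  g <- random_graph(1, 1, p = 0)            # two isolated nodes
  pp <- init_propagation_params(d = 2, num_layers = 1, node_dropout = 0,
                                mess_dropout = 0, seed = 1)
  pp$W1[[1]] <- diag(2); pp$W2[[1]] <- matrix(0, 2, 2)
  E0 <- rbind(c(1, -2), c(3, 4))
  out <- propagate_node(1, E0, g, pp, 1)
  expect_equal(out, c(1, -0.4))
})

test_that("matrix form equals the per-node oracle on random graphs", {
  set.seed(31)
  worst <- 0
  for (rep in 1:50) {
    n <- sample(2:12, 1); m <- sample(2:18, 1)   # n+m <= 30
    d <- sample(2:8, 1)
    g <- random_graph(n, m, p = runif(1, 0.1, 0.6), seed = rep)
    pp <- init_propagation_params(d = d, num_layers = 3, node_dropout = 0,
                                  mess_dropout = 0, seed = rep)
    E0 <- matrix(rnorm((n + m) * d), n + m, d)
    Es <- stack_layers(E0, g, pp, mode = "eval")
    for (l in 1:3) {
      for (node in seq_len(n + m)) {
        ref <- propagate_node(node, Es[[l]], g, pp, l)
        worst <- max(worst, max(abs(ref - Es[[l + 1]][node, ])))
      }
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("edgeless graph propagation is an elementwise LeakyReLU", {
  g <- random_graph(3, 4, p = 0)
  pp <- init_propagation_params(d = 3, num_layers = 1, node_dropout = 0,
                                mess_dropout = 0, seed = 2)
  pp$W1[[1]] <- diag(3); pp$W2[[1]] <- matrix(0, 3, 3)
  E0 <- matrix(rnorm(21), 7, 3)
  out <- propagate_matrix(E0, g$L, pp, 1)
  expect_equal(out, ifelse(E0 >= 0, E0, 0.2 * E0), tolerance = 1e-12)
})

test_that("node-order permutation equivariance", {
  set.seed(8)
  g <- random_graph(4, 5, p = 0.4, seed = 3)
  pp <- init_propagation_params(d = 3, num_layers = 2, node_dropout = 0,
                                mess_dropout = 0, seed = 4)
  E0 <- matrix(rnorm(27), 9, 3)
  out <- stack_layers(E0, g, pp, "eval")[[3]]
  perm <- sample(9)
  g2 <- g
  g2$A <- g$A[perm, perm]
  g2$L <- normalized_laplacian(g2$A)
  out2 <- stack_layers(E0[perm, ], g2, pp, "eval")[[3]]
  expect_equal(out2, out[perm, ], tolerance = 1e-10)
})

test_that("stacking returns all layers, is deterministic without dropout", {
  g <- random_graph(3, 3, p = 0.5, seed = 5)
  pp <- init_propagation_params(d = 4, num_layers = 3, node_dropout = 0,
                                mess_dropout = 0, seed = 6)
  E0 <- matrix(rnorm(24), 6, 4)
  Es <- stack_layers(E0, g, pp, "eval")
  expect_length(Es, 4)
  expect_identical(Es[[1]], E0)
  Es2 <- stack_layers(E0, g, pp, "eval")
  expect_identical(Es, Es2)
  # all-zero input stays zero through every layer
  Z <- stack_layers(matrix(0, 6, 4), g, pp, "eval")
  expect_true(all(vapply(Z, function(M) all(M == 0), logical(1))))
  pp0 <- pp; pp0$num_layers <- 0L
  expect_error(stack_layers(E0, g, pp0, "eval"), "at least one")
})

test_that("dropout is active only in training mode and respects the RNG", {
  g <- random_graph(5, 6, p = 0.5, seed = 7)
  pp <- init_propagation_params(d = 4, num_layers = 1, node_dropout = 0.3,
                                mess_dropout = 0.3, seed = 8)
  E0 <- matrix(rnorm(44), 11, 4)
  e1 <- propagate_matrix(E0, g$L, pp, 1, training = FALSE)
  e2 <- propagate_matrix(E0, g$L, pp, 1, training = FALSE)
  expect_identical(e1, e2)
  set.seed(1); t1 <- propagate_matrix(E0, g$L, pp, 1, training = TRUE)
  set.seed(1); t2 <- propagate_matrix(E0, g$L, pp, 1, training = TRUE)
  set.seed(2); t3 <- propagate_matrix(E0, g$L, pp, 1, training = TRUE)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})
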
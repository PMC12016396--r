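# Stacked LSTM sequence encoder.
#
# The cell follows the standard gated form: with z_t = [h_{t-1}, x_t],
#   f_t = sigmoid(W_f z_t + b_f)        (forget gate)
#   i_t = sigmoid(W_i z_t + b_i)        (input gate)
#   g_t = tanh(W_C z_t + b_C)           (candidate cell state)
#   C_t = f_t * C_{t-1} + i_t * g_t
#   o_t = sigmoid(W_o z_t + b_o)        (output gate)
#   h_t = o_t * tanh(C_t)
#
# Two implementations coexist deliberately: a per-timestep, per-sequence
# reference (lstm_cell_step / run_lstm) and a batched version that
# processes all sequences of a batch simultaneously with length masking
# (hidden and cell states freeze once a sequence ends, so padding can never
# influence an output). The batched path is the one trained; the reference
# is its oracle in the tests.
#
# Gate parameters are stored packed: W is (hidden+input) x 4*hidden with
# column blocks [f | i | g | o], b is length 4*hidden.

gate_cols <- function(H) {
  list(f = 1:H, i = (H + 1):(2 * H), g = (2 * H + 1):(3 * H),
       o = (3 * H + 1):(4 * H))
}

# Dimensions are recoverable from the packed weight shape, so parameter
# lists holding only W and b (the trainable leaves) are accepted
# everywhere.
layer_dims <- function(params) {
  H <- as.integer(ncol(params$W) / 4L)
  list(H = H, In = as.integer(nrow(params$W) - H))
}

#' Initialize parameters for one LSTM layer
#'
#' Entries drawn uniform in `(-scale/sqrt(hidden), +scale/sqrt(hidden))`.
#' `scale = 1` is the conservative default; larger scales put the
#' untrained recurrent network in a richer (reservoir-like) regime whose
#' hidden states separate input sequences more strongly, which speeds up
#' the early phase of joint training.
#'
#' @param input_dim,hidden_dim layer dimensions.
#' @param seed integer seed.
#' @param scale multiplier on the 1/sqrt(hidden) range (default 1).
#' @return list with `W` ((hidden+input) x 4*hidden), `b` (4*hidden),
#'   `input_dim`, `hidden_dim`.
#' @export
init_lstm_layer <- function(input_dim, hidden_dim, seed = 1L, scale = 1) {
  s <- scale / sqrt(hidden_dim)
  n <- (hidden_dim + input_dim) * 4L * hidden_dim
  W <- with_seed(seed, matrix(stats::runif(n, -s, s),
                              hidden_dim + input_dim, 4L * hidden_dim))
  list(W = W, b = numeric(4L * hidden_dim),
       input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim))
}

#' One LSTM cell update (reference form)
#'
#' Direct evaluation of the gate equations on a single timestep; used as
#' the independent oracle for the batched encoder.
#'
#' @param x_t input vector (length `input_dim`).
#' @param prev list with `C` and `h` vectors (length `hidden_dim`).
#' @param params a layer parameter list from [init_lstm_layer()].
#' @return list with updated `C` and `h`.
#' @export
lstm_cell_step <- function(x_t, prev, params) {
  dims <- layer_dims(params)
  H <- dims$H
  if (length(x_t) != dims$In) {
    stopf("input has length %d, expected %d", length(x_t), dims$In)
  }
  if (length(prev$h) != H || length(prev$C) != H) {
    stopf("state vectors must have length %d", H)
  }
  z <- c(prev$h, x_t)
  a <- drop(z %*% params$W) + params$b
  gc <- gate_cols(H)
  f <- sigmoid(a[gc$f]); i <- sigmoid(a[gc$i])
  g <- tanh(a[gc$g]);    o <- sigmoid(a[gc$o])
  C <- f * prev$C + i * g
  list(C = C, h = o * tanh(C))
}

#' Run an LSTM layer over one sequence (reference form)
#'
#' @param X L x input_dim matrix.
#' @param params layer parameters.
#' @param init optional initial state (defaults to zeros).
#' @return list with `H` (L x hidden matrix of hidden states), `C`
#'   (L x hidden), and `final` state list.
#' @export
run_lstm <- function(X, params, init = NULL) {
  if (NROW(X) == 0) stopf("run_lstm needs at least one timestep")
  H_dim <- layer_dims(params)$H
  st <- init %||% list(C = numeric(H_dim), h = numeric(H_dim))
  L <- nrow(X)
  Hs <- matrix(0, L, H_dim); Cs <- matrix(0, L, H_dim)
  for (t in seq_len(L)) {
    st <- lstm_cell_step(X[t, ], st, params)
    Hs[t, ] <- st$h; Cs[t, ] <- st$C
  }
  list(H = Hs, C = Cs, final = st)
}

# ---- batched layer with length masking ------------------------------------
#
# X is a B x In x L array (batch, input, time). The heavy lifting is done
# by compiled kernels; the per-timestep R functions above define the
# semantics and serve as the oracle in the tests.

lstm_layer_forward_batch <- function(X, lens, params) {
  out <- .lstm_forward_cpp(X, as.integer(lens), params$W, params$b)
  list(H = out$H, C = out$C, f = out$f, i = out$i, g = out$g, o = out$o,
       X = X, lens = lens, params = params)
}

# dHout: B x H x L array of gradients w.r.t. the masked hidden output at
# each timestep. Returns gradients for W, b and the layer input.
lstm_layer_backward_batch <- function(cache, dHout) {
  out <- .lstm_backward_cpp(cache$X, as.integer(cache$lens),
                            cache$params$W, cache$H, cache$C,
                            cache$f, cache$i, cache$g, cache$o, dHout)
  list(dW = out$dW, db = as.numeric(out$db), dX = out$dX)
}
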
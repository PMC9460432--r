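# Gated recurrent cells.
#
# A GRU step computes, from the previous state h_prev and input x,
#   r = sigmoid(W_r [h_prev, x] + b_r)         (reset gate)
#   z = sigmoid(W_z [h_prev, x] + b_z)         (update gate)
#   hc = tanh(W_h [h_prev * r, x] + b_h)       (candidate state)
#   h  = (1 - z) * h_prev + z * hc
# The bidirectional encoder runs one cell forward and one backward over
# the sequence and concatenates the states per position.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Create a GRU cell
#'
#' Weight matrices act on the concatenation `[h_prev, x]` (so they have
#' `hidden_size + input_size` rows); biases are zero-initialized.
#'
#' @param input_size input dimension per timestep (the fused rows feed
#'   scalar features, so 1 in the pipeline).
#' @param hidden_size state dimension (the published configuration uses
#'   128).
#' @return object of class `gru_cell`.
#' @export
gru_cell <- function(input_size, hidden_size) {
  d <- input_size + hidden_size
  structure(list(
    W_r = glorot(d, hidden_size), b_r = numeric(hidden_size),
    W_z = glorot(d, hidden_size), b_z = numeric(hidden_size),
    W_h = glorot(d, hidden_size), b_h = numeric(hidden_size),
    input_size = input_size, hidden_size = hidden_size
  ), class = "gru_cell")
}

as_state_matrix <- function(h, hidden_size) {
  if (is.matrix(h)) h else matrix(h, nrow = 1)
}

#' One GRU step
#'
#' Applies the gating equations once. Accepts a single state vector with a
#' scalar/vector input, or a batch (rows) of states with a matching batch
#' of inputs. Gate activations lie in (0,1) and the candidate in (-1,1),
#' so the new state is a convex combination of `h_prev` and the candidate.
#'
#' @param cell a [gru_cell()].
#' @param h_prev previous state: length-`hidden_size` vector or
#'   `B x hidden_size` matrix.
#' @param x input: length-`input_size` vector or `B x input_size` matrix.
#' @param detail if TRUE, also return the gate activations.
#' @return new state, same shape as `h_prev` (or a list when `detail`).
#' @export
gru_step <- function(cell, h_prev, x, detail = FALSE) {
  single <- !is.matrix(h_prev)
  H <- as_state_matrix(h_prev, cell$hidden_size)
  X <- if (is.matrix(x)) x else matrix(x, nrow = nrow(H))
  if (ncol(H) != cell$hidden_size || ncol(X) != cell$input_size ||
      nrow(H) != nrow(X))
    stop("dimension mismatch in gru_step")
  A <- cbind(H, X)
  r <- sigmoid(sweep(A %*% cell$W_r, 2, cell$b_r, "+"))
  z <- sigmoid(sweep(A %*% cell$W_z, 2, cell$b_z, "+"))
  A2 <- cbind(H * r, X)
  hc <- tanh(sweep(A2 %*% cell$W_h, 2, cell$b_h, "+"))
  h <- (1 - z) * H + z * hc
  if (detail) return(list(h = h, r = r, z = z, hc = hc))
  if (single) drop(h) else h
}

#' Create an LSTM cell
#'
#' Standard LSTM with forget/input/output gates and a tanh candidate; the
#' forget-gate bias starts at 1 (common practice, eases gradient flow).
#'
#' @inheritParams gru_cell
#' @export
lstm_cell <- function(input_size, hidden_size) {
  d <- input_size + hidden_size
  structure(list(
    W_f = glorot(d, hidden_size), b_f = rep(1, hidden_size),
    W_i = glorot(d, hidden_size), b_i = numeric(hidden_size),
    W_o = glorot(d, hidden_size), b_o = numeric(hidden_size),
    W_g = glorot(d, hidden_size), b_g = numeric(hidden_size),
    input_size = input_size, hidden_size = hidden_size
  ), class = "lstm_cell")
}

lstm_step <- function(cell, h_prev, c_prev, x, detail = FALSE) {
  H <- as_state_matrix(h_prev, cell$hidden_size)
  C <- as_state_matrix(c_prev, cell$hidden_size)
  X <- if (is.matrix(x)) x else matrix(x, nrow = nrow(H))
  A <- cbind(H, X)
  f <- sigmoid(sweep(A %*% cell$W_f, 2, cell$b_f, "+"))
  i <- sigmoid(sweep(A %*% cell$W_i, 2, cell$b_i, "+"))
  o <- sigmoid(sweep(A %*% cell$W_o, 2, cell$b_o, "+"))
  g <- tanh(sweep(A %*% cell$W_g, 2, cell$b_g, "+"))
  cn <- f * C + i * g
  h <- o * tanh(cn)
  if (detail) list(h = h, c = cn, f = f, i = i, o = o, g = g)
  else list(h = h, c = cn)
}

run_cell_sequence <- function(cell, X) {
  # X: B x T (scalar inputs per step). Returns list of per-step states.
  B <- nrow(X); Tn <- ncol(X); hs <- cell$hidden_size
  h <- matrix(0, B, hs)
  states <- vector("list", Tn)
  if (inherits(cell, "lstm_cell")) {
    cc <- matrix(0, B, hs)
    for (t in seq_len(Tn)) {
      st <- lstm_step(cell, h, cc, matrix(X[, t], ncol = 1))
      h <- st$h; cc <- st$c
      states[[t]] <- h
    }
  } else {
    for (t in seq_len(Tn)) {
      h <- gru_step(cell, h, matrix(X[, t], ncol = 1))
      states[[t]] <- h
    }
  }
  states
}

#' Encode a sequence with a bidirectional GRU
#'
#' Runs the forward cell over the sequence and the backward cell over the
#' reversed sequence, and concatenates the two states at each position:
#' `H[t, ] = [h_t_fwd ; h_t_bwd]`, width `2 * hidden_size`.
#'
#' @param forward_cell,backward_cell [gru_cell()] objects with equal sizes.
#' @param sequence numeric vector (one scalar input per position) or
#'   `T x input_size` matrix.
#' @return `T x (2 * hidden_size)` matrix `H`.
#' @export
encode_bigru <- function(forward_cell, backward_cell, sequence) {
  X <- if (is.matrix(sequence)) sequence else matrix(sequence, ncol = 1)
  Tn <- nrow(X)
  if (Tn < 1) stop("empty sequence")
  hf <- numeric(forward_cell$hidden_size)
  hb <- numeric(backward_cell$hidden_size)
  Hf <- matrix(NA_real_, Tn, forward_cell$hidden_size)
  Hb <- matrix(NA_real_, Tn, backward_cell$hidden_size)
  for (t in seq_len(Tn)) {
    hf <- gru_step(forward_cell, hf, X[t, ])
    Hf[t, ] <- hf
  }
  for (t in rev(seq_len(Tn))) {
    hb <- gru_step(backward_cell, hb, X[t, ])
    Hb[t, ] <- hb
  }
  cbind(Hf, Hb)
}
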
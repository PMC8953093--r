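# Plain-R reference forward pass: a direct, loop-based evaluation of the
# convolution equation (centred kernel-3, zero borders, ReLU), the
# standard LSTM cell run in both directions from zero initial state, and
# the per-timestep softmax head.  Independent of the compiled path.
ref_nn_forward <- function(params, x) {
  A <- matrix(x, nrow = 1)
  for (l in seq_along(params$conv_W)) {
    W <- params$conv_W[[l]]
    b <- params$conv_b[[l]][, 1L]
    Cin <- ncol(W) / 3L
    Tn <- ncol(A)
    Ap <- cbind(matrix(0, Cin, 1L), A, matrix(0, Cin, 1L))
    Z <- matrix(0, nrow(W), Tn)
    for (t in seq_len(Tn))
      Z[, t] <- W %*% c(Ap[, t], Ap[, t + 1L], Ap[, t + 2L]) + b
    A <- pmax(Z, 0)
  }
  H <- ncol(params$Wh_f)
  sig <- function(v) 1 / (1 + exp(-v))
  run_dir <- function(Wx, Wh, b, A, reverse) {
    Tn <- ncol(A)
    out <- matrix(0, H, Tn)
    h <- numeric(H)
    cs <- numeric(H)
    for (s in seq_len(Tn)) {
      t <- if (reverse) Tn - s + 1L else s
      G <- Wx %*% A[, t] + Wh %*% h + b[, 1L]
      i <- sig(G[seq_len(H)])
      f <- sig(G[H + seq_len(H)])
      g <- tanh(G[2L * H + seq_len(H)])
      o <- sig(G[3L * H + seq_len(H)])
      cs <- f * cs + i * g
      h <- o * tanh(cs)
      out[, t] <- h
    }
    out
  }
  Hf <- run_dir(params$Wx_f, params$Wh_f, params$b_f, A, FALSE)
  Hb <- run_dir(params$Wx_b, params$Wh_b, params$b_b, A, TRUE)
  Z <- params$Wd %*% rbind(Hf, Hb) + params$bd[, 1L]
  P <- apply(Z, 2L, function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  })
  P  # K x T
}
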
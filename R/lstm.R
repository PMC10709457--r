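# LSTM over token vectors, with exact backpropagation through time.
#
# Gates follow the standard formulation: input, forget and output gates are
# sigmoids of a linear map of [x_t, h_{t-1}]; the candidate state is a tanh
# of the same form; c_t = f_t * c_{t-1} + i_t * candidate; h_t = o_t *
# tanh(c_t); h_0 and c_0 are zero. The four gate blocks are fused into one
# weight matrix W of shape (d_in + h) x 4h, column blocks [i | f | o | g],
# with bias b of length 4h.

lstm_forward <- function(X, W, b, reverse = FALSE) {
  L <- nrow(X)
  hsz <- length(b) %/% 4L
  d_in <- nrow(W) - hsz
  stopifnot(ncol(X) == d_in)
  idx_i <- 1:hsz; idx_f <- hsz + idx_i; idx_o <- 2L * hsz + idx_i
  idx_g <- 3L * hsz + idx_i
  ord <- if (reverse) L:1 else 1:L
  H <- matrix(0, L, hsz)
  h_prev <- numeric(hsz); c_prev <- numeric(hsz)
  steps <- vector("list", L)
  for (k in seq_len(L)) {
    t <- ord[k]
    zin <- c(X[t, ], h_prev)
    pre <- drop(zin %*% W) + b
    i <- sigmoid(pre[idx_i]); f <- sigmoid(pre[idx_f])
    o <- sigmoid(pre[idx_o]); g <- tanh(pre[idx_g])
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    ht <- o * tc
    H[t, ] <- ht
    steps[[k]] <- list(zin = zin, i = i, f = f, o = o, g = g,
                       c_prev = c_prev, tc = tc)
    h_prev <- ht; c_prev <- cc
  }
  list(H = H, cache = list(steps = steps, ord = ord, hsz = hsz,
                           d_in = d_in))
}

lstm_backward <- function(dH, cache, W) {
  hsz <- cache$hsz; d_in <- cache$d_in
  ord <- cache$ord; steps <- cache$steps
  L <- nrow(dH)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(4L * hsz)
  dX <- matrix(0, L, d_in)
  dh_next <- numeric(hsz); dc_next <- numeric(hsz)
  for (k in rev(seq_len(L))) {
    t <- ord[k]
    st <- steps[[k]]
    dh <- dH[t, ] + dh_next
    do <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dz <- c(di * st$i * (1 - st$i),
            df * st$f * (1 - st$f),
            do * st$o * (1 - st$o),
            dg * (1 - st$g^2))
    dW <- dW + outer(st$zin, dz)
    db <- db + dz
    dzin <- drop(W %*% dz)
    dX[t, ] <- dzin[1:d_in]
    dh_next <- dzin[(d_in + 1L):(d_in + hsz)]
    dc_next <- dc * st$f
  }
  list(dX = dX, dW = dW, db = db)
}

# Bidirectional wrapper: forward and backward LSTMs over the same input,
# hidden states concatenated per token (d_h = 2 * hidden size).

bilstm_forward <- function(X, p) {
  fw <- lstm_forward(X, p$W_lstm_f, p$b_lstm_f, reverse = FALSE)
  bw <- lstm_forward(X, p$W_lstm_b, p$b_lstm_b, reverse = TRUE)
  list(H = cbind(fw$H, bw$H), fw = fw, bw = bw)
}

bilstm_backward <- function(dH, cache, p) {
  hsz <- cache$fw$cache$hsz
  gf <- lstm_backward(dH[, 1:hsz, drop = FALSE], cache$fw$cache, p$W_lstm_f)
  gb <- lstm_backward(dH[, (hsz + 1L):(2L * hsz), drop = FALSE],
                      cache$bw$cache, p$W_lstm_b)
  list(dX = gf$dX + gb$dX,
       grads = list(W_lstm_f = gf$dW, b_lstm_f = gf$db,
                    W_lstm_b = gb$dW, b_lstm_b = gb$db))
}
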
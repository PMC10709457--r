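# Bidirectional graph convolution over the matching graph.
#
# One layer computes, from the current token states H_t (L x d_h) and the
# row-normalized forward/backward adjacencies:
#
#   Q_out = Relu(norm(A_out) H_t W_out)
#   Q_in  = Relu(norm(A_in)  H_t W_in)
#   H_{t+1} = Norm(H_t + Relu([Q_out, Q_in] W_O))
#
# where Norm is layer normalization and the addition of H_t is the residual
# connection. W_out, W_in are d_h x d_h, W_O is 2 d_h x d_h so the residual
# sum type-checks. Ablations: `single_gcn` drops the backward branch (W_O
# becomes d_h x d_h); `no_residual` drops the H_t term; `late_fusion` runs
# the two branches as separate residual streams and fuses them once, after
# the last layer.

bigcn_layer_forward <- function(H, An_out, An_in, W_out, W_in, W_O,
                                gamma, beta, single_gcn = FALSE,
                                residual = TRUE) {
  P_out <- An_out %*% H
  S_out <- P_out %*% W_out
  Q_out <- relu(S_out)
  if (!single_gcn) {
    P_in <- An_in %*% H
    S_in <- P_in %*% W_in
    Q_in <- relu(S_in)
    Cat <- cbind(Q_out, Q_in)
  } else {
    P_in <- S_in <- NULL
    Cat <- Q_out
  }
  Fm <- Cat %*% W_O
  R <- relu(Fm)
  Z <- if (residual) H + R else R
  ln <- layer_norm_forward(Z, gamma, beta)
  list(H_next = ln$y,
       cache = list(P_out = P_out, S_out = S_out, P_in = P_in, S_in = S_in,
                    Cat = Cat, Fm = Fm, ln = ln$cache, An_out = An_out,
                    An_in = An_in, W_out = W_out, W_in = W_in, W_O = W_O,
                    single_gcn = single_gcn, residual = residual))
}

bigcn_layer_backward <- function(dH_next, cache) {
  d <- ncol(cache$S_out)
  lb <- layer_norm_backward(dH_next, cache$ln)
  dZ <- lb$dx
  dR <- dZ * (cache$Fm > 0)
  dW_O <- crossprod(cache$Cat, dR)
  dCat <- dR %*% t(cache$W_O)
  dQ_out <- dCat[, 1:d, drop = FALSE]
  dS_out <- dQ_out * (cache$S_out > 0)
  dW_out <- crossprod(cache$P_out, dS_out)
  dH <- crossprod(cache$An_out, dS_out %*% t(cache$W_out))
  if (!cache$single_gcn) {
    dQ_in <- dCat[, (d + 1L):(2L * d), drop = FALSE]
    dS_in <- dQ_in * (cache$S_in > 0)
    dW_in <- crossprod(cache$P_in, dS_in)
    dH <- dH + crossprod(cache$An_in, dS_in %*% t(cache$W_in))
  } else {
    dW_in <- NULL
  }
  if (cache$residual) dH <- dH + dZ
  list(dH = dH, dW_out = dW_out, dW_in = dW_in, dW_O = dW_O,
       dgamma = lb$dgamma, dbeta = lb$dbeta)
}

# ---- late-fusion variant ---------------------------------------------------
# Per layer, each direction updates its own residual stream:
#   H^dir_{t+1} = Norm(H^dir_t + Relu(norm(A_dir) H^dir_t W_dir))
# and only after layer T are the streams combined:
#   H_final = Norm(H_0 + Relu([H^out_T, H^in_T] W_O))

gcn_branch_forward <- function(H, An, W, gamma, beta, residual = TRUE) {
  P <- An %*% H
  S <- P %*% W
  Q <- relu(S)
  Z <- if (residual) H + Q else Q
  ln <- layer_norm_forward(Z, gamma, beta)
  list(H_next = ln$y,
       cache = list(P = P, S = S, An = An, W = W, ln = ln$cache,
                    residual = residual))
}

gcn_branch_backward <- function(dH_next, cache) {
  lb <- layer_norm_backward(dH_next, cache$ln)
  dZ <- lb$dx
  dS <- dZ * (cache$S > 0)
  dW <- crossprod(cache$P, dS)
  dH <- crossprod(cache$An, dS %*% t(cache$W))
  if (cache$residual) dH <- dH + dZ
  list(dH = dH, dW = dW, dgamma = lb$dgamma, dbeta = lb$dbeta)
}
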
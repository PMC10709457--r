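# Small dense-network primitives used by the encoder and the BiGCN.
# Everything is plain double matrices; rows index tokens.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-normalize an adjacency matrix
#'
#' The degree normalization of the graph convolution: every nonzero row is
#' divided by its row sum so a node averages (rather than sums) its
#' neighbors' states. All-zero rows -- tokens taking part in no match --
#' stay all-zero; there is no division by zero.
#'
#' @param a numeric L x L matrix with entries in \{0, 1\}.
#' @return L x L matrix whose nonzero rows sum to one.
#' @export
row_normalize <- function(a) {
  rs <- rowSums(a)
  rs[rs == 0] <- 1
  a / rs
}

#' Row-wise softmax
#'
#' @param x numeric matrix of logits.
#' @return Matrix of the same shape; every row is a probability vector.
#' @export
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# ---- layer normalization ---------------------------------------------------
# Normalizes each token's hidden vector to zero mean / unit variance over
# the hidden dimension, then applies a learnable gain and bias.

layer_norm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- xc * inv_std
  y <- t(t(xhat) * gamma + beta)
  list(y = y, cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma))
}

layer_norm_backward <- function(dy, cache) {
  xhat <- cache$xhat
  inv_std <- cache$inv_std
  d <- ncol(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- t(t(dy) * cache$gamma)
  dx <- (inv_std / d) *
    (d * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- parameter initialization ----------------------------------------------

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}
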
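# Linear-chain CRF head (optional, off by default).
#
# Scores a tag sequence as the sum of per-token emission scores, start and
# end scores, and first-order transition scores. The loss is the negative
# conditional log-likelihood logZ - score(gold); gradients are exact
# marginals from the forward-backward recursions, all in log space.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

crf_loss_grad <- function(em, gold, trans, start, end_vec) {
  L <- nrow(em); C <- ncol(em)
  gold <- as.integer(gold)
  if (any(gold < 1L | gold > C))
    stop("gold tag index outside the tagset (C = ", C, ")")
  # forward
  alpha <- matrix(0, L, C)
  alpha[1L, ] <- start + em[1L, ]
  if (L > 1L) for (i in 2:L)
    alpha[i, ] <- em[i, ] +
      apply(alpha[i - 1L, ] + trans, 2L, logsumexp)
  logZ <- logsumexp(alpha[L, ] + end_vec)
  # backward
  beta <- matrix(0, L, C)
  beta[L, ] <- end_vec
  if (L > 1L) for (i in (L - 1L):1L)
    beta[i, ] <- apply(t(trans) + em[i + 1L, ] + beta[i + 1L, ], 2L,
                       logsumexp)
  # gold score
  score <- sum(em[cbind(1:L, gold)]) + start[gold[1L]] + end_vec[gold[L]]
  if (L > 1L) score <- score + sum(trans[cbind(gold[-L], gold[-1L])])
  # marginals
  m_unary <- exp(alpha + beta - logZ)
  d_em <- m_unary
  d_em[cbind(1:L, gold)] <- d_em[cbind(1:L, gold)] - 1
  d_trans <- matrix(0, C, C)
  if (L > 1L) for (i in 2:L) {
    pair <- exp(outer(alpha[i - 1L, ], em[i, ] + beta[i, ], "+") +
                  trans - logZ)
    d_trans <- d_trans + pair
    d_trans[gold[i - 1L], gold[i]] <- d_trans[gold[i - 1L], gold[i]] - 1
  }
  d_start <- m_unary[1L, ]; d_start[gold[1L]] <- d_start[gold[1L]] - 1
  d_end <- m_unary[L, ]; d_end[gold[L]] <- d_end[gold[L]] - 1
  list(loss = logZ - score, d_em = d_em, d_trans = d_trans,
       d_start = d_start, d_end = d_end)
}

crf_viterbi <- function(em, trans, start, end_vec) {
  L <- nrow(em); C <- ncol(em)
  delta <- start + em[1L, ]
  back <- matrix(0L, L, C)
  if (L > 1L) for (i in 2:L) {
    sc <- delta + trans            # C x C: previous tag x current tag
    back[i, ] <- apply(sc, 2L, which.max)
    delta <- sc[cbind(back[i, ], 1:C)] + em[i, ]
  }
  delta <- delta + end_vec
  path <- integer(L)
  path[L] <- which.max(delta)
  if (L > 1L) for (i in L:2) path[i - 1L] <- back[i, path[i]]
  path
}
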
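#' Training and architecture settings
#'
#' Defaults follow the reference configuration of the tagger: BiLSTM hidden
#' size 256 per direction, 100-dimensional word embeddings, batch size 50,
#' dropout 0.1 on embeddings only, L2 penalty 1e-4 on the softmax
#' projection only, Adam with model learning rate 1e-3 (1e-5 for a
#' contextual-encoder adapter, when one is attached), per-epoch learning
#' rate decay 0.98, at most 50 epochs, and a 2-layer BiGCN. Tests and small
#' synthetic studies shrink the sizes; the defaults are the full-scale
#' configuration.
#'
#' @param lstm_hidden LSTM hidden units per direction.
#' @param emb_dim word-embedding dimension.
#' @param batch_size sentences per parameter update.
#' @param dropout dropout rate applied to embeddings in training.
#' @param l2_softmax L2 coefficient on the classifier projection `W_p`.
#' @param lr_model Adam learning rate for all model parameters.
#' @param lr_encoder_adapter learning rate reserved for a fine-tunable
#'   contextual encoder (the bundled embedding-table encoder ignores it).
#' @param lr_decay multiplicative per-epoch learning-rate decay.
#' @param max_epochs maximum training epochs.
#' @param layers number of BiGCN layers T; 0 disables the graph module.
#' @param seed master seed controlling initialization, shuffling, dropout.
#' @param single_gcn,no_residual,late_fusion,no_bilstm ablation switches:
#'   forward-branch-only GCN; drop the residual; fuse the two branches only
#'   after the last layer; replace the BiLSTM by a linear projection.
#' @param share_gcn_weights tie BiGCN weights across layers.
#' @param self_loops give single-token matches a diagonal edge.
#' @param use_mask_feature embed the greedy masked-manner sequence and
#'   concatenate it to the encoder input (the classic baseline feature).
#' @param mask_emb_dim size of the mask-feature embedding.
#' @param use_crf linear-chain CRF head instead of token softmax.
#' @param early_stop_f1 stop when the monitored (dev, else train) F1
#'   reaches this value; `NULL` trains for `max_epochs`.
#' @param eval_every compute P/R/F1 every this many epochs.
#' @param verbose print one line per epoch.
#' @return A list of class `mgner_control`.
#' @export
mgner_control <- function(lstm_hidden = 256L, emb_dim = 100L,
                          batch_size = 50L, dropout = 0.1,
                          l2_softmax = 1e-4, lr_model = 1e-3,
                          lr_encoder_adapter = 1e-5, lr_decay = 0.98,
                          max_epochs = 50L, layers = 2L, seed = 1L,
                          single_gcn = FALSE, no_residual = FALSE,
                          late_fusion = FALSE, no_bilstm = FALSE,
                          share_gcn_weights = FALSE, self_loops = TRUE,
                          use_mask_feature = FALSE, mask_emb_dim = 16L,
                          use_crf = FALSE, early_stop_f1 = NULL,
                          eval_every = 1L, verbose = FALSE) {
  ctl <- list(lstm_hidden = as.integer(lstm_hidden),
              emb_dim = as.integer(emb_dim),
              batch_size = as.integer(batch_size), dropout = dropout,
              l2_softmax = l2_softmax, lr_model = lr_model,
              lr_encoder_adapter = lr_encoder_adapter, lr_decay = lr_decay,
              max_epochs = as.integer(max_epochs),
              layers = as.integer(layers), seed = as.integer(seed),
              single_gcn = isTRUE(single_gcn),
              no_residual = isTRUE(no_residual),
              late_fusion = isTRUE(late_fusion),
              no_bilstm = isTRUE(no_bilstm),
              share_gcn_weights = isTRUE(share_gcn_weights),
              self_loops = isTRUE(self_loops),
              use_mask_feature = isTRUE(use_mask_feature),
              mask_emb_dim = as.integer(mask_emb_dim),
              use_crf = isTRUE(use_crf), early_stop_f1 = early_stop_f1,
              eval_every = as.integer(eval_every),
              verbose = isTRUE(verbose))
  stopifnot(ctl$lstm_hidden > 0L, ctl$emb_dim > 0L, ctl$batch_size > 0L,
            ctl$dropout >= 0, ctl$dropout < 1, ctl$layers >= 0L,
            ctl$max_epochs >= 1L, ctl$lr_decay > 0, ctl$lr_decay <= 1)
  class(ctl) <- "mgner_control"
  ctl
}

# hidden width of the token states entering the BiGCN
hidden_width <- function(ctl) 2L * ctl$lstm_hidden

layer_suffix <- function(ctl, l) if (ctl$share_gcn_weights) "s" else l

# ---- parameter initialization ----------------------------------------------
# One flat named list of matrices/vectors; gradient lists mirror it.

init_params <- function(ctl, vocab_size, n_tags, n_mask_symbols = 0L) {
  d_in <- ctl$emb_dim +
    if (ctl$use_mask_feature) ctl$mask_emb_dim else 0L
  d <- hidden_width(ctl)
  p <- list()
  p$E <- matrix(stats::rnorm((vocab_size + 1L) * ctl$emb_dim, sd = 0.1),
                vocab_size + 1L, ctl$emb_dim)
  if (ctl$use_mask_feature)
    p$M <- matrix(stats::rnorm(n_mask_symbols * ctl$mask_emb_dim, sd = 0.1),
                  n_mask_symbols, ctl$mask_emb_dim)
  if (ctl$no_bilstm) {
    p$W_proj <- glorot(d_in, d)
  } else {
    h <- ctl$lstm_hidden
    forget_bias <- rep(c(0, 1, 0, 0), each = h)
    p$W_lstm_f <- glorot(d_in + h, 4L * h)
    p$b_lstm_f <- forget_bias
    p$W_lstm_b <- glorot(d_in + h, 4L * h)
    p$b_lstm_b <- forget_bias
  }
  nlay <- if (ctl$share_gcn_weights && ctl$layers > 0L) 1L else ctl$layers
  for (l in seq_len(nlay)) {
    sfx <- layer_suffix(ctl, l)
    p[[paste0("W_out_", sfx)]] <- glorot(d, d)
    if (!ctl$single_gcn) p[[paste0("W_in_", sfx)]] <- glorot(d, d)
    if (ctl$late_fusion) {
      p[[paste0("g_out_", sfx)]] <- rep(1, d)
      p[[paste0("b_out_", sfx)]] <- rep(0, d)
      if (!ctl$single_gcn) {
        p[[paste0("g_in_", sfx)]] <- rep(1, d)
        p[[paste0("b_in_", sfx)]] <- rep(0, d)
      }
    } else {
      p[[paste0("W_O_", sfx)]] <-
        glorot(if (ctl$single_gcn) d else 2L * d, d)
      p[[paste0("g_", sfx)]] <- rep(1, d)
      p[[paste0("b_", sfx)]] <- rep(0, d)
    }
  }
  if (ctl$late_fusion && ctl$layers > 0L) {
    p$W_O_fuse <- glorot(if (ctl$single_gcn) d else 2L * d, d)
    p$g_fuse <- rep(1, d)
    p$b_fuse <- rep(0, d)
  }
  p$W_p <- glorot(d, n_tags)
  if (ctl$use_crf) {
    p$crf_trans <- matrix(0, n_tags, n_tags)
    p$crf_start <- rep(0, n_tags)
    p$crf_end <- rep(0, n_tags)
  }
  p
}

zero_like <- function(p) lapply(p, function(x) x * 0)

# ---- forward / backward over one sentence ----------------------------------
# A prepared sentence carries: ids (1-based embedding rows, unknowns mapped
# to the reserved last row), mask_ids (optional), An_out/An_in
# (row-normalized adjacency), gold (1-based tag indices, may be NULL).

model_forward <- function(p, prep, ctl, train = FALSE) {
  X <- if (!is.null(prep$X_fixed)) prep$X_fixed
       else p$E[prep$ids, , drop = FALSE]
  if (ctl$use_mask_feature)
    X <- cbind(X, p$M[prep$mask_ids, , drop = FALSE])
  drop_mask <- NULL
  if (train && ctl$dropout > 0) {
    drop_mask <- matrix(
      (stats::runif(length(X)) >= ctl$dropout) / (1 - ctl$dropout),
      nrow(X), ncol(X))
    X <- X * drop_mask
  }
  if (ctl$no_bilstm) {
    enc <- NULL
    H <- X %*% p$W_proj
  } else {
    enc <- bilstm_forward(X, p)
    H <- enc$H
  }
  H0 <- H
  layer_caches <- vector("list", ctl$layers)
  late <- NULL
  if (ctl$layers > 0L && !ctl$late_fusion) {
    for (l in seq_len(ctl$layers)) {
      sfx <- layer_suffix(ctl, l)
      st <- bigcn_layer_forward(
        H, prep$An_out, prep$An_in,
        p[[paste0("W_out_", sfx)]],
        if (!ctl$single_gcn) p[[paste0("W_in_", sfx)]] else NULL,
        p[[paste0("W_O_", sfx)]],
        p[[paste0("g_", sfx)]], p[[paste0("b_", sfx)]],
        single_gcn = ctl$single_gcn, residual = !ctl$no_residual)
      layer_caches[[l]] <- st$cache
      H <- st$H_next
    }
  } else if (ctl$layers > 0L) {
    Ho <- H0; Hi <- H0
    for (l in seq_len(ctl$layers)) {
      sfx <- layer_suffix(ctl, l)
      so <- gcn_branch_forward(Ho, prep$An_out, p[[paste0("W_out_", sfx)]],
                               p[[paste0("g_out_", sfx)]],
                               p[[paste0("b_out_", sfx)]],
                               residual = !ctl$no_residual)
      Ho <- so$H_next
      if (!ctl$single_gcn) {
        si <- gcn_branch_forward(Hi, prep$An_in, p[[paste0("W_in_", sfx)]],
                                 p[[paste0("g_in_", sfx)]],
                                 p[[paste0("b_in_", sfx)]],
                                 residual = !ctl$no_residual)
        Hi <- si$H_next
      } else si <- NULL
      layer_caches[[l]] <- list(out = so$cache, inn = si$cache)
    }
    Cat <- if (ctl$single_gcn) Ho else cbind(Ho, Hi)
    Fm <- Cat %*% p$W_O_fuse
    R <- relu(Fm)
    Z <- if (ctl$no_residual) R else H0 + R
    ln <- layer_norm_forward(Z, p$g_fuse, p$b_fuse)
    late <- list(Cat = Cat, Fm = Fm, ln = ln$cache)
    H <- ln$y
  }
  logits <- H %*% p$W_p
  list(logits = logits, H_top = H, H0 = H0, X = X, enc = enc,
       layer_caches = layer_caches, late = late, drop_mask = drop_mask)
}

#' Token-wise classification loss
#'
#' Sum over tokens of the negative log-probability assigned to the gold
#' tag: zero exactly when the model puts probability one on every gold
#' tag, and `L * log(C)` for uniform predictions over `C` classes.
#'
#' @param probs L x C matrix of per-token tag probabilities (rows sum to 1).
#' @param gold integer vector of 1-based gold tag indices, length L.
#' @return Non-negative scalar.
#' @export
nll_loss <- function(probs, gold) {
  gold <- as.integer(gold)
  if (any(gold < 1L | gold > ncol(probs)))
    stop("gold tag index outside the tagset (C = ", ncol(probs), ")")
  -sum(log(probs[cbind(seq_along(gold), gold)]))
}

# loss + full gradient for one sentence; grads accumulated into `acc`
# (an environment holding a list `g` shaped like the parameters)
sentence_loss_grad <- function(p, prep, ctl, acc, train = TRUE) {
  fw <- model_forward(p, prep, ctl, train = train)
  L <- length(prep$ids)
  gold <- prep$gold
  if (ctl$use_crf) {
    cr <- crf_loss_grad(fw$logits, gold, p$crf_trans, p$crf_start,
                        p$crf_end)
    loss <- cr$loss
    dlogits <- cr$d_em
    acc$g$crf_trans <- acc$g$crf_trans + cr$d_trans
    acc$g$crf_start <- acc$g$crf_start + cr$d_start
    acc$g$crf_end <- acc$g$crf_end + cr$d_end
  } else {
    probs <- softmax_rows(fw$logits)
    loss <- nll_loss(probs, gold)
    dlogits <- probs
    dlogits[cbind(seq_len(L), gold)] <- dlogits[cbind(seq_len(L), gold)] - 1
  }
  acc$g$W_p <- acc$g$W_p + crossprod(fw$H_top, dlogits)
  dH <- dlogits %*% t(p$W_p)
  if (ctl$layers > 0L && !ctl$late_fusion) {
    for (l in rev(seq_len(ctl$layers))) {
      sfx <- layer_suffix(ctl, l)
      bk <- bigcn_layer_backward(dH, fw$layer_caches[[l]])
      acc$g[[paste0("W_out_", sfx)]] <-
        acc$g[[paste0("W_out_", sfx)]] + bk$dW_out
      if (!ctl$single_gcn)
        acc$g[[paste0("W_in_", sfx)]] <-
          acc$g[[paste0("W_in_", sfx)]] + bk$dW_in
      acc$g[[paste0("W_O_", sfx)]] <-
        acc$g[[paste0("W_O_", sfx)]] + bk$dW_O
      acc$g[[paste0("g_", sfx)]] <- acc$g[[paste0("g_", sfx)]] + bk$dgamma
      acc$g[[paste0("b_", sfx)]] <- acc$g[[paste0("b_", sfx)]] + bk$dbeta
      dH <- bk$dH
    }
  } else if (ctl$layers > 0L) {
    lb <- layer_norm_backward(dH, fw$late$ln)
    dZ <- lb$dx
    acc$g$g_fuse <- acc$g$g_fuse + lb$dgamma
    acc$g$b_fuse <- acc$g$b_fuse + lb$dbeta
    dR <- dZ * (fw$late$Fm > 0)
    acc$g$W_O_fuse <- acc$g$W_O_fuse + crossprod(fw$late$Cat, dR)
    dCat <- dR %*% t(p$W_O_fuse)
    d <- hidden_width(ctl)
    dHo <- dCat[, 1:d, drop = FALSE]
    dHi <- if (!ctl$single_gcn) dCat[, (d + 1L):(2L * d), drop = FALSE]
           else NULL
    dH0 <- if (ctl$no_residual) matrix(0, L, d) else dZ
    for (l in rev(seq_len(ctl$layers))) {
      sfx <- layer_suffix(ctl, l)
      bo <- gcn_branch_backward(dHo, fw$layer_caches[[l]]$out)
      acc$g[[paste0("W_out_", sfx)]] <-
        acc$g[[paste0("W_out_", sfx)]] + bo$dW
      acc$g[[paste0("g_out_", sfx)]] <-
        acc$g[[paste0("g_out_", sfx)]] + bo$dgamma
      acc$g[[paste0("b_out_", sfx)]] <-
        acc$g[[paste0("b_out_", sfx)]] + bo$dbeta
      dHo <- bo$dH
      if (!ctl$single_gcn) {
        bi <- gcn_branch_backward(dHi, fw$layer_caches[[l]]$inn)
        acc$g[[paste0("W_in_", sfx)]] <-
          acc$g[[paste0("W_in_", sfx)]] + bi$dW
        acc$g[[paste0("g_in_", sfx)]] <-
          acc$g[[paste0("g_in_", sfx)]] + bi$dgamma
        acc$g[[paste0("b_in_", sfx)]] <-
          acc$g[[paste0("b_in_", sfx)]] + bi$dbeta
        dHi <- bi$dH
      }
    }
    dH <- dHo + dH0 + if (ctl$single_gcn) 0 else dHi
  }
  if (ctl$no_bilstm) {
    acc$g$W_proj <- acc$g$W_proj + crossprod(fw$X, dH)
    dX <- dH %*% t(p$W_proj)
  } else {
    bl <- bilstm_backward(dH, fw$enc, p)
    for (nm in names(bl$grads)) acc$g[[nm]] <- acc$g[[nm]] + bl$grads[[nm]]
    dX <- bl$dX
  }
  if (!is.null(fw$drop_mask)) dX <- dX * fw$drop_mask
  de <- ctl$emb_dim
  fixed <- !is.null(prep$X_fixed)
  for (r in seq_len(L)) {
    if (!fixed) {
      id <- prep$ids[r]
      acc$g$E[id, ] <- acc$g$E[id, ] + dX[r, 1:de]
    }
    if (ctl$use_mask_feature) {
      mid <- prep$mask_ids[r]
      acc$g$M[mid, ] <- acc$g$M[mid, ] + dX[r, (de + 1L):ncol(dX)]
    }
  }
  loss
}
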
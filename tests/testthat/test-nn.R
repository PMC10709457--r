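test_that("row normalization averages neighbors and skips empty rows", {
  a <- rbind(c(1, 1, 0), c(0, 0, 0), c(1, 1, 1))
  n <- row_normalize(a)
  expect_equal(n[1, ], c(0.5, 0.5, 0))
  expect_equal(n[2, ], c(0, 0, 0))
  expect_true(all(row_normalize(matrix(0, 3, 3)) == 0))
  set.seed(1)
  for (rep in 1:30) {
    a <- matrix(rbinom(36, 1, 0.4), 6, 6)
    n <- row_normalize(a)
    rs <- rowSums(n)
    expect_true(all(abs(rs[rowSums(a) > 0] - 1) < 1e-9))
    expect_true(all(rs[rowSums(a) == 0] == 0))
  }
})

test_that("softmax rows are probability vectors and uniform on equal logits", {
  set.seed(2)
  x <- matrix(rnorm(40), 8, 5)
  p <- softmax_rows(x)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_equal(softmax_rows(matrix(0, 1, 2))[1, ], c(0.5, 0.5))
})

test_that("layer norm backward matches numerical gradients", {
  set.seed(3)
  x <- matrix(rnorm(12), 3, 4)
  gamma <- runif(4, 0.5, 1.5); beta <- rnorm(4)
  f <- function(x, gamma, beta)
    sum(sin(layer_norm_forward(x, gamma, beta)$y))
  fw <- layer_norm_forward(x, gamma, beta)
  dy <- cos(fw$y)
  bk <- layer_norm_backward(dy, fw$cache)
  eps <- 1e-6
  for (k in 1:length(x)) {
    x1 <- x; x1[k] <- x1[k] + eps
    x2 <- x; x2[k] <- x2[k] - eps
    num <- (f(x1, gamma, beta) - f(x2, gamma, beta)) / (2 * eps)
    expect_equal(bk$dx[k], num, tolerance = 1e-5)
  }
  for (k in 1:4) {
    g1 <- gamma; g1[k] <- g1[k] + eps
    g2 <- gamma; g2[k] <- g2[k] - eps
    num <- (f(x, g1, beta) - f(x, g2, beta)) / (2 * eps)
    expect_equal(bk$dgamma[k], num, tolerance = 1e-5)
  }
})

test_that("LSTM gates stay in (0,1) and states are finite", {
  set.seed(4)
  X <- matrix(rnorm(5 * 3), 5, 3)
  W <- mgner:::glorot(3 + 2, 8); b <- rnorm(8)
  fw <- mgner:::lstm_forward(X, W, b)
  for (st in fw$cache$steps) {
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$o > 0 & st$o < 1))
  }
  expect_true(all(is.finite(fw$H)))
  expect_equal(dim(fw$H), c(5, 2))
})

test_that("a length-1 sentence encodes to a single finite hidden row", {
  s <- tiny_setup()
  ctl <- s$ctl
  prep <- tiny_prep(s)
  prep$ids <- prep$ids[1]; prep$An_out <- matrix(0, 1, 1)
  prep$An_in <- matrix(0, 1, 1); prep$gold <- prep$gold[1]
  set.seed(1)
  p <- mgner:::init_params(ctl, length(s$vocab), length(s$tagset), 0L)
  fw <- mgner:::model_forward(p, prep, ctl)
  expect_equal(nrow(fw$H_top), 1)
  expect_true(all(is.finite(fw$H_top)))
})

test_that("eval-mode forward is bit-identical across runs", {
  s <- tiny_setup()
  prep <- tiny_prep(s)
  set.seed(1)
  p <- mgner:::init_params(s$ctl, length(s$vocab), length(s$tagset), 0L)
  f1 <- mgner:::model_forward(p, prep, s$ctl, train = FALSE)
  f2 <- mgner:::model_forward(p, prep, s$ctl, train = FALSE)
  expect_identical(f1$logits, f2$logits)
})

test_that("zero-adjacency BiGCN layer reduces to Norm of its input", {
  set.seed(6)
  L <- 4; d <- 6
  H <- matrix(rnorm(L * d), L, d)
  Z <- matrix(0, L, L)
  gamma <- runif(d, 0.5, 1.5); beta <- rnorm(d)
  st <- mgner:::bigcn_layer_forward(H, Z, Z, mgner:::glorot(d, d),
                                    mgner:::glorot(d, d),
                                    mgner:::glorot(2 * d, d),
                                    gamma, beta)
  expect_equal(st$H_next, layer_norm_forward(H, gamma, beta)$y)
})

test_that("the scalar hand-trace of one layer matches exactly", {
  # L = 1, d_h = 1, self-loop graph, every weight 1, h = 2:
  # Q_out = Q_in = Relu(1 * 2 * 1) = 2
  # pre-norm residual input = 2 + Relu([2, 2] %*% [1, 1]^T) = 6
  H <- matrix(2, 1, 1)
  A <- matrix(1, 1, 1)
  W1 <- matrix(1, 1, 1); WO <- matrix(1, 2, 1)
  P <- A %*% H
  Q_out <- mgner:::relu(P %*% W1)
  Q_in <- mgner:::relu(P %*% W1)
  expect_equal(Q_out[1, 1], 2)
  pre_norm <- H + mgner:::relu(cbind(Q_out, Q_in) %*% WO)
  expect_equal(pre_norm[1, 1], 6, tolerance = 1e-6)
  # and the packaged layer computes Norm of exactly that quantity
  st <- mgner:::bigcn_layer_forward(H, A, A, W1, W1, WO, gamma = 1,
                                    beta = 0)
  expect_equal(st$H_next,
               layer_norm_forward(pre_norm, 1, 0)$y)
})

test_that("stacking layers on a zero graph equals repeated Norm plus classifier", {
  s <- tiny_setup()
  prep <- tiny_prep(s)
  L <- length(prep$ids)
  d <- mgner:::hidden_width(s$ctl)
  prep$An_out <- matrix(0, L, L)
  prep$An_in <- matrix(0, L, L)
  set.seed(1)
  p <- mgner:::init_params(s$ctl, length(s$vocab), length(s$tagset), 0L)
  fw_T <- mgner:::model_forward(p, prep, s$ctl)
  ctl0 <- s$ctl; ctl0$layers <- 0L
  fw_0 <- mgner:::model_forward(p, prep, ctl0)
  H <- fw_0$H_top
  for (l in 1:s$ctl$layers)
    H <- layer_norm_forward(H, p[[paste0("g_", l)]],
                            p[[paste0("b_", l)]])$y
  expect_equal(fw_T$H_top, H, tolerance = 1e-12)
  expect_equal(fw_T$logits, H %*% p$W_p, tolerance = 1e-12)
})

test_that("token loss has its closed forms", {
  # probabilities one-hot on gold -> exactly zero
  probs <- diag(3)
  expect_equal(nll_loss(probs, 1:3), 0)
  # uniform -> L * log(C)
  L <- 7; C <- 5
  u <- matrix(1 / C, L, C)
  expect_equal(nll_loss(u, sample(C, L, TRUE)), L * log(C),
               tolerance = 1e-9)
  # random probabilities vs a naive per-token loop
  set.seed(8)
  for (rep in 1:20) {
    P <- softmax_rows(matrix(rnorm(4 * 6), 4, 6))
    gold <- sample(6, 4, TRUE)
    naive <- 0
    for (i in 1:4) naive <- naive - log(P[i, gold[i]])
    expect_equal(nll_loss(P, gold), naive, tolerance = 1e-9)
  }
  expect_error(nll_loss(u, c(1, 99)), "outside the tagset")
})

test_that("analytic gradients match numerical ones in every variant", {
  s <- tiny_setup(ctl_args = list(use_mask_feature = TRUE,
                                  mask_emb_dim = 2L))
  variants <- list(
    default = list(),
    single = list(single_gcn = TRUE),
    no_res = list(no_residual = TRUE),
    late = list(late_fusion = TRUE),
    late_single = list(late_fusion = TRUE, single_gcn = TRUE),
    no_bilstm = list(no_bilstm = TRUE),
    shared = list(share_gcn_weights = TRUE),
    crf = list(use_crf = TRUE),
    t0 = list(layers = 0L))
  for (nm in names(variants)) {
    ctl <- do.call(mgner_control,
                   c(list(lstm_hidden = 3L, emb_dim = 4L, dropout = 0,
                          seed = 5L, use_mask_feature = TRUE,
                          mask_emb_dim = 2L), variants[[nm]]))
    prep <- mgner:::prepare_sentence(
      s$sents[[2]]$tokens, s$sents[[2]]$tags, s$vocab, s$tagset,
      s$syn$dictionary, ctl, s$mask_symbols)
    set.seed(7)
    p <- mgner:::init_params(ctl, length(s$vocab), length(s$tagset),
                             length(s$mask_symbols))
    if (ctl$use_crf) {
      p$crf_trans[] <- rnorm(length(p$crf_trans), sd = 0.1)
      p$crf_start[] <- rnorm(length(p$crf_start), sd = 0.1)
      p$crf_end[] <- rnorm(length(p$crf_end), sd = 0.1)
    }
    err <- worst_grad_error(p, prep, ctl)
    expect_lt(err, 1e-4)
  }
})
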
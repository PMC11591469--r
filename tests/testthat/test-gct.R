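test_that("graph convolution stack matches direct evaluation", {
  f <- matrix(c(1, -1, 2, 0), 2, 2)
  expect_equal(graph_conv_stack(f, diag(2), list(diag(2))), pmax(f, 0))
  expect_equal(graph_conv_stack(matrix(0, 3, 2), matrix(1 / 3, 3, 3),
                                list(diag(2), diag(2))), matrix(0, 3, 2))
  withr::local_seed(31)
  inst <- random_tiny_instance(31, n_nodes = 4)
  ws <- list(matrix(rnorm(16), 4, 4), matrix(rnorm(16), 4, 4))
  got <- graph_conv_stack(inst$features, inst$norm_adj, ws)
  want <- inst$features
  for (w in ws) want <- pmax(inst$norm_adj %*% want %*% w, 0)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("Gaussian bias has the prescribed values and sign", {
  expect_equal(gaussian_bias(matrix(2), 1, 0), matrix(-4))
  expect_equal(gaussian_bias(matrix(0), 1, 0), matrix(0))
  # negative b penalises self-attention at distance zero
  expect_equal(gaussian_bias(matrix(0), 1, -3), matrix(-3))
  # omega = 0: constant distance-blind penalty
  hop <- matrix(sample(0:5, 25, TRUE), 5)
  expect_true(all(gaussian_bias(hop, 0, -2) == -2))
  withr::local_seed(8)
  b <- gaussian_bias(hop, rnorm(1), rnorm(1))
  expect_true(all(b <= 0))
})

test_that("biased attention heads are row-stochastic and distance-monotone", {
  # single node attends to itself with weight one
  x <- matrix(c(1, 2), 1, 2)
  out <- biased_attention_head(x, diag(2), diag(2), diag(2), matrix(0), 2)
  expect_equal(out, x)
  # identical rows, zero bias: uniform attention
  x2 <- rbind(c(1, 0), c(1, 0))
  o2 <- biased_attention_head(x2, diag(2), diag(2), diag(2),
                              matrix(0, 2, 2), 2)
  expect_equal(o2, x2)
  expect_error(biased_attention_head(x2, diag(2), diag(2), diag(2),
                                     matrix(0, 2, 2), 0), "positive")

  # large omega with positive off-diagonal distance concentrates on self
  withr::local_seed(41)
  x3 <- matrix(rnorm(8), 4, 2)
  hop <- hop_distances(rbind(c(0, 1, 0, 0), c(1, 0, 1, 0),
                             c(0, 1, 0, 1), c(0, 0, 1, 0)), 10)
  strong <- biased_attention_head(x3, diag(2), diag(2), diag(2),
                                  gaussian_bias(hop, 1e6, 0), 2)
  expect_equal(strong, x3, tolerance = 1e-6)

  # monotonicity: with omega > 0, b = 0, larger hop distance never gets a
  # larger attention weight when the content logits are flat
  for (rep in 1:20) {
    n <- 5
    hp <- matrix(sample(0:4, n * n, TRUE), n)
    hp <- pmax(hp, t(hp)); diag(hp) <- 0
    om <- runif(1, 0.1, 2)
    logits <- gaussian_bias(hp, om, 0)
    a <- t(apply(logits, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    for (i in seq_len(n)) {
      ord <- order(hp[i, ])
      expect_true(all(diff(a[i, ord]) <= 1e-12))
    }
  }
})

test_that("head concatenation and transformer block satisfy their algebra", {
  h <- matrix(rnorm(8), 4, 2)
  expect_equal(concat_heads(list(h), diag(2)), h)
  # two identical heads with an averaging projection reproduce the head
  w_avg <- rbind(diag(2), diag(2)) / 2
  expect_equal(concat_heads(list(h, h), w_avg), h)
  expect_error(concat_heads(list(h, h[1:2, ]), diag(4)), "row counts")

  # layer-norm rows have mean 0 and variance 1 before the affine terms
  x <- matrix(rnorm(40), 5, 8)
  ln <- mdfuse:::layer_norm_rows(x, rep(1, 8), rep(0, 8))
  expect_equal(rowMeans(ln), rep(0, 5), tolerance = 1e-10)
  expect_equal(apply(ln, 1, function(r) mean(r^2)), rep(1, 5),
               tolerance = 1e-4)
  # a constant row maps to zeros (epsilon guards the zero variance)
  lc <- mdfuse:::layer_norm_rows(matrix(3, 1, 8), rep(1, 8), rep(0, 8))
  expect_equal(lc, matrix(0, 1, 8))

  # zero FFN weights: block reduces to LayerNorm(A~)
  ffn0 <- list(W1 = matrix(0, 8, 16), b1 = rep(0, 16),
               W2 = matrix(0, 16, 8), b2 = rep(0, 8))
  attn <- matrix(rnorm(40), 5, 8)
  a_tilde <- mdfuse:::layer_norm_rows(attn + x, rep(1, 8), rep(0, 8))
  expect_equal(transformer_block(x, attn, ffn0),
               mdfuse:::layer_norm_rows(a_tilde, rep(1, 8), rep(0, 8)))
})

test_that("transformer encoder matches the dense loop oracle on small graphs", {
  for (seed in 1:20) {
    inst <- random_tiny_instance(2000 + seed)
    cfg <- gct_config(dim = 8, heads = 2, conv_layers = 2,
                      use_gaussian_bias = seed %% 2 == 0)
    withr::local_seed(seed)
    state <- mdfuse:::init_gct_state(cfg, ncol(inst$features))
    # exercise learned-looking scalars rather than the neutral init
    state$omega$value[] <- runif(1, 0.2, 2)
    state$b$value[] <- rnorm(1)
    graph <- list(features = inst$features, norm_adjacency = inst$norm_adj,
                  hop_distance = inst$hop)
    got <- encode_gct(graph, cfg, state)
    want <- oracle_gct(inst$features, inst$norm_adj, inst$hop, cfg, state)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("ablation variants of the transformer encoder stay shape-valid", {
  inst <- random_tiny_instance(321, n_nodes = 5)
  graph <- list(features = inst$features, norm_adjacency = inst$norm_adj,
                hop_distance = inst$hop)
  withr::local_seed(2)
  # conv-only variant (self-attention removed)
  cfg_a <- gct_config(dim = 8, heads = 2, use_attention = FALSE)
  st_a <- mdfuse:::init_gct_state(cfg_a, 5)
  expect_identical(dim(encode_gct(graph, cfg_a, st_a)), c(5L, 8L))
  # conventional transformer (no graph convolutions, no Gaussian bias)
  cfg_d <- gct_config(dim = 8, heads = 2, use_conv = FALSE,
                      use_gaussian_bias = FALSE)
  st_d <- mdfuse:::init_gct_state(cfg_d, 5)
  expect_identical(dim(encode_gct(graph, cfg_d, st_d)), c(5L, 8L))
})

test_that("zero Gaussian parameters reduce to an unbiased transformer", {
  inst <- random_tiny_instance(654, n_nodes = 5)
  graph <- list(features = inst$features, norm_adjacency = inst$norm_adj,
                hop_distance = inst$hop)
  withr::local_seed(3)
  cfg <- gct_config(dim = 8, heads = 2)
  state <- mdfuse:::init_gct_state(cfg, 5)
  state$omega$value[] <- 0
  state$b$value[] <- 0
  cfg_off <- cfg; cfg_off$use_gaussian_bias <- FALSE
  expect_equal(encode_gct(graph, cfg, state),
               encode_gct(graph, cfg_off, state), tolerance = 1e-12)
})
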
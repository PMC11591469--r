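# Graph convolutional transformer encoder: a stack of GCN layers on the
# normalised heterogeneous adjacency feeds a multi-head self-attention block
# whose logits carry a negative Gaussian bias in squared hop distance,
# followed by residual + layer-norm + feed-forward.

#' Configuration for the graph convolutional transformer encoder
#'
#' @param dim Embedding width D (divisible by `heads`).
#' @param heads Number of self-attention heads.
#' @param conv_layers Number of graph-convolution layers E.
#' @param ffn_hidden Hidden width of the feed-forward sub-layer
#'   (default `2 * dim`).
#' @param distance_cap Hop-distance sentinel used when building the bias.
#' @param ln_eps Layer-norm variance epsilon.
#' @param use_attention `FALSE` drops the self-attention block and returns
#'   the convolution stack output (ablation variant).
#' @param use_conv `FALSE` replaces the graph-convolution stack by a plain
#'   linear input projection, i.e. a conventional transformer on raw
#'   features (ablation variant).
#' @param use_gaussian_bias `FALSE` zeroes the distance bias (used together
#'   with `use_conv = FALSE` for the conventional-transformer variant).
#' @return A `gct_config` list.
#' @export
gct_config <- function(dim = 512L, heads = 4L, conv_layers = 2L,
                       ffn_hidden = 2L * dim, distance_cap = 10L,
                       ln_eps = 1e-5, use_attention = TRUE, use_conv = TRUE,
                       use_gaussian_bias = TRUE) {
  stopifnot(dim >= 1L, heads >= 1L, dim %% heads == 0L, conv_layers >= 1L,
            ffn_hidden >= 1L, distance_cap >= 1L)
  structure(list(dim = as.integer(dim), heads = as.integer(heads),
                 conv_layers = as.integer(conv_layers),
                 ffn_hidden = as.integer(ffn_hidden),
                 distance_cap = as.integer(distance_cap), ln_eps = ln_eps,
                 use_attention = isTRUE(use_attention),
                 use_conv = isTRUE(use_conv),
                 use_gaussian_bias = isTRUE(use_gaussian_bias)),
            class = "gct_config")
}

init_gct_state <- function(config, in_dim) {
  dh <- config$dim %/% config$heads
  conv_w <- list()
  d_in <- in_dim
  if (config$use_conv) {
    for (e in seq_len(config$conv_layers)) {
      conv_w[[e]] <- ad_param(xavier_mat(d_in, config$dim))
      d_in <- config$dim
    }
  } else {
    conv_w[[1L]] <- ad_param(xavier_mat(d_in, config$dim))
    d_in <- config$dim
  }
  heads <- lapply(seq_len(config$heads), function(q) {
    list(W_Q = ad_param(xavier_mat(config$dim, dh)),
         W_K = ad_param(xavier_mat(config$dim, dh)),
         W_V = ad_param(xavier_mat(config$dim, dh)))
  })
  structure(list(
    conv_w = conv_w,
    heads = heads,
    W_O = ad_param(xavier_mat(config$dim, config$dim)),
    omega = ad_param(matrix(1, 1L, 1L), decay = FALSE),
    b = ad_param(matrix(0, 1L, 1L), decay = FALSE),
    ln1_gain = ad_param(matrix(1, 1L, config$dim), decay = FALSE),
    ln1_offset = ad_param(matrix(0, 1L, config$dim), decay = FALSE),
    ln2_gain = ad_param(matrix(1, 1L, config$dim), decay = FALSE),
    ln2_offset = ad_param(matrix(0, 1L, config$dim), decay = FALSE),
    ffn_W1 = ad_param(xavier_mat(config$dim, config$ffn_hidden)),
    ffn_b1 = ad_param(matrix(0, 1L, config$ffn_hidden), decay = FALSE),
    ffn_W2 = ad_param(xavier_mat(config$ffn_hidden, config$dim)),
    ffn_b2 = ad_param(matrix(0, 1L, config$dim), decay = FALSE)
  ), class = "gct_state")
}

gct_params <- function(state, config) {
  ps <- c(state$conv_w,
          unlist(lapply(state$heads, function(h) list(h$W_Q, h$W_K, h$W_V)),
                 recursive = FALSE),
          list(state$W_O, state$ln1_gain, state$ln1_offset, state$ln2_gain,
               state$ln2_offset, state$ffn_W1, state$ffn_b1, state$ffn_W2,
               state$ffn_b2))
  if (config$use_gaussian_bias) ps <- c(ps, list(state$omega, state$b))
  ps
}

# Autodiff forward pass; `k2` is the constant matrix of squared hop counts.
forward_gct <- function(tape, f_node, norm_adj, k2, config, state) {
  x <- f_node
  if (config$use_conv) {
    anode <- ad_const(tape, norm_adj)
    for (w in state$conv_w) {
      x <- ad_relu(tape, ad_matmul(tape, anode, ad_matmul(tape, x, ad_leaf(tape, w))))
    }
  } else {
    x <- ad_matmul(tape, x, ad_leaf(tape, state$conv_w[[1L]]))
  }
  if (!config$use_attention) return(x)
  dh <- config$dim %/% config$heads
  bias_node <- NULL
  if (config$use_gaussian_bias) {
    wk <- ad_smul_const(tape, ad_leaf(tape, state$omega), k2)
    bias_node <- ad_negabs(tape, ad_sadd(tape, wk, ad_leaf(tape, state$b)))
  }
  head_outs <- vector("list", config$heads)
  for (q in seq_len(config$heads)) {
    hp <- state$heads[[q]]
    qn <- ad_matmul(tape, x, ad_leaf(tape, hp$W_Q))
    kn <- ad_matmul(tape, x, ad_leaf(tape, hp$W_K))
    vn <- ad_matmul(tape, x, ad_leaf(tape, hp$W_V))
    logits <- ad_scale(tape, ad_matmul(tape, qn, ad_node(tape, t(kn$value),
                                                         list(kn),
                                                         function(g) list(t(g)))),
                       1 / sqrt(dh))
    if (!is.null(bias_node)) logits <- ad_add(tape, logits, bias_node)
    attn <- ad_softmax_rows(tape, logits)
    head_outs[[q]] <- ad_matmul(tape, attn, vn)
  }
  cat_node <- head_outs[[1L]]
  if (config$heads > 1L) {
    for (q in 2:config$heads) cat_node <- ad_cbind(tape, cat_node, head_outs[[q]])
  }
  a_gt <- ad_matmul(tape, cat_node, ad_leaf(tape, state$W_O))
  a_tilde <- ad_layernorm(tape, ad_add(tape, a_gt, x),
                          ad_leaf(tape, state$ln1_gain),
                          ad_leaf(tape, state$ln1_offset), eps = config$ln_eps)
  ffn <- ad_add_bias(tape,
                     ad_matmul(tape,
                               ad_relu(tape,
                                       ad_add_bias(tape,
                                                   ad_matmul(tape, a_tilde,
                                                             ad_leaf(tape, state$ffn_W1)),
                                                   ad_leaf(tape, state$ffn_b1))),
                               ad_leaf(tape, state$ffn_W2)),
                     ad_leaf(tape, state$ffn_b2))
  ad_layernorm(tape, ad_add(tape, ffn, a_tilde),
               ad_leaf(tape, state$ln2_gain),
               ad_leaf(tape, state$ln2_offset), eps = config$ln_eps)
}

#' Stacked graph convolutions on a normalised adjacency
#'
#' `X^(e) = ReLU(A_hat X^(e-1) W^(e))`, applied once per weight matrix.
#'
#' @param features Initial node feature matrix `X^(0)`.
#' @param norm_adjacency Symmetric renormalised adjacency.
#' @param weights List of layer weight matrices.
#' @return The final layer output.
#' @export
graph_conv_stack <- function(features, norm_adjacency, weights) {
  x <- features
  for (w in weights) x <- pmax(norm_adjacency %*% (x %*% w), 0)
  x
}

#' Negative Gaussian attention bias from hop distances
#'
#' `bias(i, j) = -|omega * k_ij^2 + b|`; always non-positive, so distant
#' pairs are down-weighted and a negative `b` penalises self-attention.
#'
#' @param hop Integer matrix of hop distances.
#' @param omega,b Learnable scalars (scale and self-penalty).
#' @return Non-positive bias matrix.
#' @export
gaussian_bias <- function(hop, omega, b) {
  -abs(omega * hop^2 + b)
}

#' One biased self-attention head
#'
#' `softmax(Q K^T / sqrt(d) + bias) V` with `Q = X W_Q`, `K = X W_K`,
#' `V = X W_V`.
#'
#' @param X Node feature matrix.
#' @param W_Q,W_K,W_V Projection matrices.
#' @param bias Square additive bias matrix (may be 0).
#' @param d Head dimension used in the temperature.
#' @return The head output matrix.
#' @export
biased_attention_head <- function(X, W_Q, W_K, W_V, bias, d) {
  if (d <= 0) stop("head dimension must be positive")
  q <- X %*% W_Q; k <- X %*% W_K; v <- X %*% W_V
  logits <- q %*% t(k) / sqrt(d) + bias
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  (ex / rowSums(ex)) %*% v
}

#' Concatenate attention heads and project
#' @param head_outputs List of equally tall matrices.
#' @param W_O Output projection.
#' @return The projected concatenation.
#' @export
concat_heads <- function(head_outputs, W_O) {
  rows <- vapply(head_outputs, nrow, integer(1))
  if (length(unique(rows)) != 1L) stop("head outputs must have equal row counts")
  do.call(cbind, head_outputs) %*% W_O
}

# Numeric row-wise layer norm (gain/offset vectors of length D).
layer_norm_rows <- function(x, gain, offset, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  xhat <- xc / sqrt(va + eps)
  sweep(sweep(xhat, 2L, gain, "*"), 2L, offset, "+")
}

#' Residual + layer-norm + feed-forward transformer block
#'
#' `A~ = LayerNorm(attn_out + X_L)` then
#' `H = LayerNorm(FFN(A~) + A~)` with a two-layer ReLU feed-forward net.
#'
#' @param X_L Convolution-stack output (the residual source).
#' @param attn_out Projected multi-head attention output.
#' @param ffn List with `W1`, `b1`, `W2`, `b2`, and optional layer-norm
#'   terms `ln1_gain`, `ln1_offset`, `ln2_gain`, `ln2_offset`, `eps`.
#' @return The block output matrix.
#' @export
transformer_block <- function(X_L, attn_out, ffn) {
  eps <- ffn$eps %||% 1e-5
  d <- ncol(X_L)
  g1 <- ffn$ln1_gain %||% rep(1, d); o1 <- ffn$ln1_offset %||% rep(0, d)
  g2 <- ffn$ln2_gain %||% rep(1, d); o2 <- ffn$ln2_offset %||% rep(0, d)
  a_tilde <- layer_norm_rows(attn_out + X_L, g1, o1, eps)
  h <- pmax(sweep(a_tilde %*% ffn$W1, 2L, as.numeric(ffn$b1), "+"), 0)
  out <- sweep(h %*% ffn$W2, 2L, as.numeric(ffn$b2), "+")
  layer_norm_rows(out + a_tilde, g2, o2, eps)
}

#' Encode a heterogeneous graph with the transformer encoder
#'
#' Deterministic forward pass returning the `(M+N) x D` embedding.
#'
#' @param graph A `hetero_graph`.
#' @param config A [gct_config()].
#' @param state A `gct_state`.
#' @return Numeric embedding matrix.
#' @export
encode_gct <- function(graph, config, state) {
  tape <- ad_tape()
  f_node <- ad_const(tape, graph$features)
  k2 <- graph$hop_distance^2
  forward_gct(tape, f_node, graph$norm_adjacency, k2, config, state)$value
}
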
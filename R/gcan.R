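# Graph convolutional attention encoder: a GCN pre-encoding pass feeds
# multi-head edge attention layers whose outputs are fused by learnable
# skip-connection weights.

#' Configuration for the graph convolutional attention encoder
#'
#' @param dim Embedding width D (must be divisible by `heads`).
#' @param heads Number of attention heads Q.
#' @param att_layers Number of attention layers L.
#' @param gcn_layers Number of GCN pre-encoding layers.
#' @param leaky_slope Negative slope of the LeakyReLU in the attention logits.
#' @param dropout Dropout probability (held in the config for completeness;
#'   stochastic regularisation is applied in the gating stack).
#' @param use_gcn_pre Set `FALSE` to bypass the GCN pre-encoding and run a
#'   plain graph attention encoder (ablation variant).
#' @return A `gcan_config` list.
#' @export
gcan_config <- function(dim = 512L, heads = 4L, att_layers = 2L,
                        gcn_layers = 1L, leaky_slope = 0.2, dropout = 0.5,
                        use_gcn_pre = TRUE) {
  stopifnot(dim >= 1L, heads >= 1L, dim %% heads == 0L,
            att_layers >= 1L, gcn_layers >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(dim = as.integer(dim), heads = as.integer(heads),
                 att_layers = as.integer(att_layers),
                 gcn_layers = as.integer(gcn_layers),
                 leaky_slope = leaky_slope, dropout = dropout,
                 use_gcn_pre = isTRUE(use_gcn_pre)),
            class = "gcan_config")
}

# Parameter set for the encoder; draws from the current RNG stream.
init_gcan_state <- function(config, in_dim) {
  dh <- config$dim %/% config$heads
  gcn_w <- list()
  d_in <- in_dim
  if (config$use_gcn_pre) {
    for (l in seq_len(config$gcn_layers)) {
      gcn_w[[l]] <- ad_param(xavier_mat(d_in, config$dim))
      d_in <- config$dim
    }
  }
  att <- vector("list", config$att_layers)
  for (l in seq_len(config$att_layers)) {
    heads <- vector("list", config$heads)
    for (q in seq_len(config$heads)) {
      heads[[q]] <- list(
        W_h = ad_param(xavier_mat(d_in, dh)),
        a_src = ad_param(xavier_mat(dh, 1L)),
        a_dst = ad_param(xavier_mat(dh, 1L))
      )
    }
    att[[l]] <- heads
    d_in <- config$dim
  }
  L <- config$att_layers
  skip <- if (L > 1L) {
    lapply(seq_len(L - 1L), function(l) {
      ad_param(matrix(1 / (L - 1L), 1L, 1L), decay = FALSE)
    })
  } else list()
  structure(list(gcn_w = gcn_w, att = att, skip = skip),
            class = "gcan_state")
}

gcan_params <- function(state) {
  c(state$gcn_w,
    unlist(lapply(state$att, function(layer) {
      unlist(lapply(layer, function(h) list(h$W_h, h$a_src, h$a_dst)),
             recursive = FALSE)
    }), recursive = FALSE),
    state$skip)
}

# Constants derived from the neighbour lists: the GCN propagation matrix
# (self-loop-inclusive degrees) and the 0/-Inf attention mask (self excluded
# unless a node's only neighbour is itself).
gcan_graph_consts <- function(neighbors) {
  n <- length(neighbors)
  # aggregation set N(i) + {i} as a set: a fallback self-edge must not
  # count the node twice
  sets <- lapply(seq_len(n), function(i) unique(c(neighbors[[i]], i)))
  deg <- lengths(sets)
  cmat <- matrix(0, n, n)
  mask <- matrix(-Inf, n, n)
  for (i in seq_len(n)) {
    js <- sets[[i]]
    cmat[i, js] <- 1 / sqrt(deg[i] * deg[js])
    mask[i, neighbors[[i]]] <- 0
  }
  list(cmat = cmat, mask = mask)
}

# Autodiff forward pass; returns the embedding node on `tape`.
forward_gcan <- function(tape, f_node, consts, config, state) {
  h <- f_node
  if (config$use_gcn_pre) {
    cnode <- ad_const(tape, consts$cmat)
    for (w in state$gcn_w) {
      h <- ad_relu(tape, ad_matmul(tape, cnode, ad_matmul(tape, h, ad_leaf(tape, w))))
    }
  }
  layer_outs <- vector("list", config$att_layers)
  for (l in seq_len(config$att_layers)) {
    heads <- vector("list", config$heads)
    for (q in seq_len(config$heads)) {
      hp <- state$att[[l]][[q]]
      hw <- ad_matmul(tape, h, ad_leaf(tape, hp$W_h))
      u <- ad_matmul(tape, hw, ad_leaf(tape, hp$a_src))
      v <- ad_matmul(tape, hw, ad_leaf(tape, hp$a_dst))
      e <- ad_leakyrelu(tape, ad_outer_sum(tape, u, v), config$leaky_slope)
      alpha <- ad_softmax_rows(tape, e, mask = consts$mask)
      heads[[q]] <- ad_relu(tape, ad_matmul(tape, alpha, hw))
    }
    out <- heads[[1L]]
    if (config$heads > 1L) {
      for (q in 2:config$heads) out <- ad_cbind(tape, out, heads[[q]])
    }
    layer_outs[[l]] <- out
    h <- out
  }
  h_ag <- layer_outs[[config$att_layers]]
  if (config$att_layers > 1L) {
    for (l in seq_len(config$att_layers - 1L)) {
      h_ag <- ad_add(tape, h_ag,
                     ad_scalar_mul(tape, ad_leaf(tape, state$skip[[l]]),
                                   layer_outs[[l]]))
    }
  }
  h_ag
}

#' One GCN propagation step over explicit neighbour lists
#'
#' Computes `h_i' = ReLU(sum_{j in N(i) + {i}} W h_j / sqrt(d_i d_j))` with
#' self-loop-inclusive degrees `d = |N(.)| + 1`.
#'
#' @param features Node-by-dimension input matrix.
#' @param neighbors List of integer neighbour vectors (self excluded).
#' @param weight Transformation matrix applied to every neighbour feature.
#' @return The propagated node-by-dimension matrix.
#' @export
gcn_layer <- function(features, neighbors, weight) {
  n <- nrow(features)
  if (any(unlist(neighbors) < 1L) || any(unlist(neighbors) > n)) {
    stop("neighbor index out of range")
  }
  hw <- features %*% weight
  sets <- lapply(seq_len(n), function(i) unique(c(neighbors[[i]], i)))
  deg <- lengths(sets)
  out <- matrix(0, n, ncol(hw))
  for (i in seq_len(n)) {
    js <- sets[[i]]
    coef <- 1 / sqrt(deg[i] * deg[js])
    out[i, ] <- colSums(hw[js, , drop = FALSE] * coef)
  }
  pmax(out, 0)
}

#' Raw attention logit for an ordered node pair
#'
#' `e_ij = LeakyReLU(a^T [W_h h_i || W_h h_j])`; note the concatenation
#' order makes this asymmetric in general.
#'
#' @param h_i,h_j Feature vectors of source and neighbour node.
#' @param a Attention vector of length `2 * nrow(W_h %*% h)`.
#' @param W_h Shared transformation matrix.
#' @param slope LeakyReLU negative slope.
#' @return A single logit value.
#' @export
attention_coefficients <- function(h_i, h_j, a, W_h, slope = 0.2) {
  wi <- as.numeric(W_h %*% h_i)
  wj <- as.numeric(W_h %*% h_j)
  if (length(a) != length(wi) + length(wj)) stop("attention vector length mismatch")
  x <- sum(a * c(wi, wj))
  if (x > 0) x else slope * x
}

#' Softmax normalisation of attention logits over a neighbourhood
#' @param coeffs Numeric vector of logits (at least one).
#' @return Probabilities summing to 1.
#' @export
attention_weights <- function(coeffs) {
  if (length(coeffs) == 0L) {
    stop("empty neighbourhood: caller must provide a fallback self-edge")
  }
  ex <- exp(coeffs - max(coeffs))
  ex / sum(ex)
}

#' Attention-weighted neighbour aggregation
#'
#' `z_i = ReLU(sum_j alpha_ij W_h h_j)`.
#'
#' @param weights Attention probabilities (must sum to 1 within 1e-6).
#' @param neighbor_feats Matrix whose rows are the neighbour features `h_j`.
#' @param W_h Shared transformation matrix.
#' @return Aggregated feature vector.
#' @export
attention_aggregate <- function(weights, neighbor_feats, W_h) {
  if (abs(sum(weights) - 1) > 1e-6) stop("attention weights must sum to 1")
  z <- colSums((neighbor_feats %*% t(W_h)) * weights)
  pmax(z, 0)
}

#' Learnable skip fusion of attention-layer outputs
#'
#' `H = h^(L) + sum_{l < L} alpha_l h^(l)`.
#'
#' @param layer_outputs List of L equally shaped matrices.
#' @param skip_weights Numeric vector of length `L - 1`.
#' @return The fused matrix.
#' @export
skip_fusion <- function(layer_outputs, skip_weights) {
  L <- length(layer_outputs)
  if (length(skip_weights) != L - 1L) stop("skip weight length must be L - 1")
  out <- layer_outputs[[L]]
  for (l in seq_len(L - 1L)) out <- out + skip_weights[l] * layer_outputs[[l]]
  out
}

#' Encode a heterogeneous graph with the attention encoder
#'
#' Deterministic forward pass (no dropout); returns the `(M+N) x D`
#' embedding.
#'
#' @param graph A `hetero_graph` from [build_hetero_graph()].
#' @param config A [gcan_config()].
#' @param state A `gcan_state` (from the internal initialiser or a fit).
#' @return Numeric embedding matrix.
#' @export
encode_gcan <- function(graph, config, state) {
  tape <- ad_tape()
  consts <- gcan_graph_consts(graph$neighbors)
  f_node <- ad_const(tape, graph$features)
  forward_gcan(tape, f_node, consts, config, state)$value
}
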
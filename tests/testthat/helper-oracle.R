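# Independent dense brute-force re-implementations of both encoders and the
# gating stack, written as explicit loops over the defining equations.  They
# share nothing with the package's tape-based forward passes and serve as
# the oracle in the equivalence tests.

oracle_relu <- function(x) pmax(x, 0)
oracle_lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
oracle_softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# Attention encoder: GCN pre-encoding, per-edge multi-head attention,
# learnable skip fusion.
oracle_gcan <- function(features, neighbors, config, state) {
  n <- nrow(features)
  h <- features
  if (config$use_gcn_pre) {
    sets <- lapply(seq_len(n), function(i) unique(c(neighbors[[i]], i)))
    deg <- lengths(sets)
    for (w in state$gcn_w) {
      wv <- w$value
      out <- matrix(0, n, ncol(wv))
      for (i in seq_len(n)) {
        acc <- numeric(ncol(wv))
        for (j in sets[[i]]) {
          acc <- acc + (1 / sqrt(deg[i] * deg[j])) * as.numeric(h[j, ] %*% wv)
        }
        out[i, ] <- oracle_relu(acc)
      }
      h <- out
    }
  }
  layer_outs <- list()
  for (l in seq_len(config$att_layers)) {
    head_mats <- list()
    for (q in seq_len(config$heads)) {
      hp <- state$att[[l]][[q]]
      hw <- h %*% hp$W_h$value
      z <- matrix(0, n, ncol(hw))
      for (i in seq_len(n)) {
        nb <- neighbors[[i]]
        e <- sapply(nb, function(j) {
          oracle_lrelu(sum(hp$a_src$value * hw[i, ]) +
                         sum(hp$a_dst$value * hw[j, ]), config$leaky_slope)
        })
        alpha <- oracle_softmax(e)
        acc <- numeric(ncol(hw))
        for (k in seq_along(nb)) acc <- acc + alpha[k] * hw[nb[k], ]
        z[i, ] <- oracle_relu(acc)
      }
      head_mats[[q]] <- z
    }
    h <- do.call(cbind, head_mats)
    layer_outs[[l]] <- h
  }
  out <- layer_outs[[config$att_layers]]
  if (config$att_layers > 1) {
    for (l in seq_len(config$att_layers - 1)) {
      out <- out + state$skip[[l]]$value[1] * layer_outs[[l]]
    }
  }
  out
}

oracle_layernorm <- function(x, gain, offset, eps = 1e-5) {
  out <- x
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    out[i, ] <- (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * gain + offset
  }
  out
}

# Transformer encoder: conv stack, Gaussian-biased self-attention,
# residual + layer norm + feed-forward.
oracle_gct <- function(features, norm_adj, hop, config, state) {
  n <- nrow(features)
  x <- features
  if (config$use_conv) {
    for (w in state$conv_w) x <- oracle_relu(norm_adj %*% x %*% w$value)
  } else {
    x <- x %*% state$conv_w[[1]]$value
  }
  if (!config$use_attention) return(x)
  dh <- config$dim / config$heads
  bias <- if (config$use_gaussian_bias) {
    -abs(state$omega$value[1] * hop^2 + state$b$value[1])
  } else matrix(0, n, n)
  heads <- list()
  for (q in seq_len(config$heads)) {
    hp <- state$heads[[q]]
    qm <- x %*% hp$W_Q$value; km <- x %*% hp$W_K$value; vm <- x %*% hp$W_V$value
    out <- matrix(0, n, dh)
    for (i in seq_len(n)) {
      logit <- sapply(seq_len(n), function(j) {
        sum(qm[i, ] * km[j, ]) / sqrt(dh) + bias[i, j]
      })
      a <- oracle_softmax(logit)
      for (j in seq_len(n)) out[i, ] <- out[i, ] + a[j] * vm[j, ]
    }
    heads[[q]] <- out
  }
  a_gt <- do.call(cbind, heads) %*% state$W_O$value
  a_tilde <- oracle_layernorm(a_gt + x, as.numeric(state$ln1_gain$value),
                              as.numeric(state$ln1_offset$value), config$ln_eps)
  ffn <- oracle_relu(sweep(a_tilde %*% state$ffn_W1$value, 2,
                           as.numeric(state$ffn_b1$value), "+")) %*%
    state$ffn_W2$value
  ffn <- sweep(ffn, 2, as.numeric(state$ffn_b2$value), "+")
  oracle_layernorm(ffn + a_tilde, as.numeric(state$ln2_gain$value),
                   as.numeric(state$ln2_offset$value), config$ln_eps)
}

# Gating stack unrolled by hand (evaluation mode).
oracle_gating <- function(h_ag, h_tr, config, state) {
  if (config$concat_fusion) {
    return(sweep(cbind(h_ag, h_tr) %*% state$W_c$value, 2,
                 as.numeric(state$b_c$value), "+"))
  }
  h_a <- h_ag; h_b <- h_tr; out <- NULL
  for (i in seq_len(config$depth)) {
    lp <- state$layers[[i]]
    cat_m <- cbind(h_a, h_b)
    g <- 1 / (1 + exp(-sweep(cat_m %*% lp$W_g$value, 2,
                             as.numeric(lp$b_g$value), "+")))
    h_fused <- g * h_a + (1 - g) * h_b
    h_res <- h_fused + (h_a + h_b) / 2
    f <- tanh(sweep(cat_m %*% lp$W_f$value, 2, as.numeric(lp$b_f$value), "+"))
    out <- h_res + f
    h_a <- out
    if (config$recurse_on == "previous") h_b <- out
  }
  out
}

# Small random graph + matching encoder states for the oracle tests.
random_tiny_instance <- function(seed, n_nodes = NULL, dim = 8L, heads = 2L) {
  withr::local_seed(seed)
  n <- if (is.null(n_nodes)) sample(3:6, 1) else n_nodes
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- sample(setdiff(seq_len(n), i), 1)
    adj[i, j] <- adj[j, i] <- 1
  }
  extra <- which(upper.tri(adj) & adj == 0)
  if (length(extra) > 0) {
    pick <- sample(extra, min(length(extra), sample(0:2, 1)))
    adj[pick] <- 1
    adj <- pmax(adj, t(adj))
  }
  neighbors <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  for (i in seq_len(n)) if (length(neighbors[[i]]) == 0) neighbors[[i]] <- i
  features <- matrix(runif(n * n), n, n)
  list(n = n, adj = adj, neighbors = neighbors, features = features,
       norm_adj = normalize_adjacency(adj), hop = hop_distances(adj, cap = 5))
}
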
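# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a node on a tape; ops append nodes in
# evaluation order, so a single reverse sweep in creation order is a valid
# topological backward pass.  Values are always base-R matrices (scalars are
# 1x1) and gradients have the shape of their value.  Only what the encoders
# need is implemented; each backward rule is checked against central finite
# differences in the test suite.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$param <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- node
  node
}

# Learnable parameter: value + gradient accumulator + Adam moments.
ad_param <- function(value, decay = TRUE) {
  p <- new.env(parent = emptyenv())
  p$value <- as.matrix(value)
  p$grad <- matrix(0, nrow(p$value), ncol(p$value))
  p$m <- matrix(0, nrow(p$value), ncol(p$value))
  p$v <- matrix(0, nrow(p$value), ncol(p$value))
  p$decay <- decay
  class(p) <- "ad_param"
  p
}

# Bind a parameter onto a tape as a leaf node.
ad_leaf <- function(tape, param) {
  node <- ad_node(tape, param$value)
  node$param <- param
  node
}

ad_const <- function(tape, x) ad_node(tape, as.matrix(x))

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(node)
}

# Reverse sweep from `loss` (any node; seeded with ones of its shape).
ad_backward <- function(tape, loss) {
  loss$grad <- array(1, dim(loss$value))
  dim(loss$grad) <- dim(loss$value)
  for (k in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[k]]
    if (is.null(node$grad)) next
    if (!is.null(node$backward)) {
      gs <- node$backward(node$grad)
      for (i in seq_along(gs)) {
        if (!is.null(gs[[i]])) ad_accum(node$parents[[i]], gs[[i]])
      }
    }
    if (!is.null(node$param)) {
      node$param$grad <- node$param$grad + node$grad
    }
  }
  invisible(NULL)
}

## ---- ops ------------------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

# Add a 1 x D bias row to every row of a.
ad_add_bias <- function(tape, a, bias) {
  stopifnot(ncol(a$value) == ncol(bias$value), nrow(bias$value) == 1L)
  ad_node(tape, sweep(a$value, 2L, as.numeric(bias$value), "+"), list(a, bias),
          function(g) list(g, matrix(colSums(g), 1L)))
}

# Multiply by a fixed scalar.
ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(g) list(g * s))
}

# Elementwise product with a constant matrix (dropout masks etc.).
ad_mul_const <- function(tape, a, cmat) {
  ad_node(tape, a$value * cmat, list(a), function(g) list(g * cmat))
}

# scalar node (1x1) times a constant matrix.
ad_smul_const <- function(tape, s, cmat) {
  ad_node(tape, s$value[1L] * cmat, list(s), function(g) {
    list(matrix(sum(g * cmat), 1L, 1L))
  })
}

# add a scalar node (1x1) to every element of a.
ad_sadd <- function(tape, a, s) {
  ad_node(tape, a$value + s$value[1L], list(a, s), function(g) {
    list(g, matrix(sum(g), 1L, 1L))
  })
}

# scalar node (1x1) times a node matrix (skip-connection weights).
ad_scalar_mul <- function(tape, s, a) {
  ad_node(tape, s$value[1L] * a$value, list(s, a), function(g) {
    list(matrix(sum(g * a$value), 1L, 1L), s$value[1L] * g)
  })
}

# -(|x|): the Gaussian attention bias envelope; d/dx = -sign(x).
ad_negabs <- function(tape, a) {
  ad_node(tape, -abs(a$value), list(a), function(g) list(-sign(a$value) * g))
}

ad_relu <- function(tape, a) {
  ad_node(tape, pmax(a$value, 0), list(a), function(g) {
    list(g * (a$value > 0))
  })
}

ad_leakyrelu <- function(tape, a, slope = 0.2) {
  ad_node(tape, ifelse(a$value > 0, a$value, slope * a$value), list(a),
          function(g) list(g * ifelse(a$value > 0, 1, slope)))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, list(a), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(tape, a) {
  th <- tanh(a$value)
  ad_node(tape, th, list(a), function(g) list(g * (1 - th^2)))
}

# Row-wise softmax with an optional additive constant mask (0 / -Inf entries
# admit or exclude edges).  Every row must keep at least one finite logit.
ad_softmax_rows <- function(tape, a, mask = NULL) {
  x <- a$value
  if (!is.null(mask)) x <- x + mask
  mx <- apply(x, 1L, max)
  ex <- exp(x - mx)
  ex[is.nan(ex)] <- 0 # -Inf - -Inf rows cannot occur by contract
  y <- ex / rowSums(ex)
  ad_node(tape, y, list(a), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

ad_cbind <- function(tape, a, b) {
  na <- ncol(a$value)
  ad_node(tape, cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

# Row selection with scatter-add backward (indices may repeat).
ad_rows <- function(tape, a, idx) {
  idx <- as.integer(idx)
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    agg <- rowsum(g, group = idx)
    da[as.integer(rownames(agg)), ] <- agg
    list(da)
  })
}

# E[i, j] = u[i] + v[j] for column vectors u, v (GAT logit decomposition).
ad_outer_sum <- function(tape, u, v) {
  uu <- as.numeric(u$value)
  vv <- as.numeric(v$value)
  ad_node(tape, outer(uu, vv, "+"), list(u, v), function(g) {
    list(matrix(rowSums(g), ncol = 1L), matrix(colSums(g), ncol = 1L))
  })
}

# Row-wise layer normalisation with learnable gain/offset (1 x D each).
ad_layernorm <- function(tape, a, gain, offset, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, as.numeric(gain$value), "*")
  y <- sweep(y, 2L, as.numeric(offset$value), "+")
  ad_node(tape, y, list(a, gain, offset), function(g) {
    dgain <- matrix(colSums(g * xhat), 1L)
    doff <- matrix(colSums(g), 1L)
    dxhat <- sweep(g, 2L, as.numeric(gain$value), "*")
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, dgain, doff)
  })
}

# Inverted dropout with an externally drawn 0/1 mask.
ad_dropout <- function(tape, a, mask, p) {
  keep <- mask / (1 - p)
  ad_mul_const(tape, a, keep)
}

# Mean binary cross-entropy of probabilities against 0/1 labels, with the
# probabilities clamped to [eps, 1 - eps]; gradient is zero in the clamp zone.
ad_bce <- function(tape, p, y, eps = 1e-7) {
  pv <- as.numeric(p$value)
  yv <- as.numeric(y)
  n <- length(pv)
  stopifnot(n == length(yv), n >= 1L)
  pc <- pmin(pmax(pv, eps), 1 - eps)
  val <- -mean(yv * log(pc) + (1 - yv) * log(1 - pc))
  ad_node(tape, matrix(val, 1L, 1L), list(p), function(g) {
    inside <- (pv > eps) & (pv < 1 - eps)
    dp <- ifelse(inside, (-yv / pc + (1 - yv) / (1 - pc)) / n, 0)
    list(matrix(g[1L] * dp, ncol = 1L))
  })
}

## ---- optimiser ------------------------------------------------------------

# One Adam step over a flat list of ad_param objects; classic L2 coupling
# (weight decay added to the raw gradient) on parameters flagged decay = TRUE.
adam_step <- function(params, t, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  for (p in params) {
    g <- p$grad
    if (weight_decay > 0 && p$decay) g <- g + weight_decay * p$value
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad[] <- 0
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# Xavier-uniform matrix initialiser (draws from the current RNG stream).
xavier_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}
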
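# Fine-grained multi-layer feature-interaction gating: a sigmoid gate mixes
# the two encoder embeddings elementwise, a residual adds their mean, and a
# tanh interaction unit captures cross-feature structure; layers are applied
# recursively with dropout during training.

#' Configuration for the gating fusion stack
#'
#' @param depth Number of gating layers d.
#' @param dim Embedding width D.
#' @param dropout Dropout probability applied to each layer output during
#'   training.
#' @param concat_fusion `TRUE` replaces the whole gating stack by plain
#'   concatenation + linear projection (ablation variant).
#' @param recurse_on Second operand of layers 2..d: `"transformer"`
#'   (default; each layer re-reads the transformer embedding) or
#'   `"previous"` (self-composition of the running output).
#' @return A `gating_config` list.
#' @export
gating_config <- function(depth = 2L, dim = 512L, dropout = 0.5,
                          concat_fusion = FALSE,
                          recurse_on = c("transformer", "previous")) {
  stopifnot(depth >= 1L, dim >= 1L, dropout >= 0, dropout < 1)
  structure(list(depth = as.integer(depth), dim = as.integer(dim),
                 dropout = dropout, concat_fusion = isTRUE(concat_fusion),
                 recurse_on = match.arg(recurse_on)),
            class = "gating_config")
}

init_gating_state <- function(config) {
  d <- config$dim
  if (config$concat_fusion) {
    return(structure(list(
      W_c = ad_param(xavier_mat(2L * d, d)),
      b_c = ad_param(matrix(0, 1L, d), decay = FALSE)
    ), class = "gating_state"))
  }
  layers <- lapply(seq_len(config$depth), function(i) {
    list(W_g = ad_param(xavier_mat(2L * d, d)),
         b_g = ad_param(matrix(0, 1L, d), decay = FALSE),
         W_f = ad_param(xavier_mat(2L * d, d)),
         b_f = ad_param(matrix(0, 1L, d), decay = FALSE))
  })
  structure(list(layers = layers), class = "gating_state")
}

gating_params <- function(state) {
  if (!is.null(state$W_c)) return(list(state$W_c, state$b_c))
  unlist(lapply(state$layers, function(l) list(l$W_g, l$b_g, l$W_f, l$b_f)),
         recursive = FALSE)
}

# Autodiff forward; dropout masks (one 0/1 matrix per layer) are drawn by
# the caller so the whole training step shares a single RNG stream.
forward_gating <- function(tape, h_ag, h_tr, config, state,
                           dropout_masks = NULL) {
  if (config$concat_fusion) {
    cat_node <- ad_cbind(tape, h_ag, h_tr)
    return(ad_add_bias(tape, ad_matmul(tape, cat_node, ad_leaf(tape, state$W_c)),
                       ad_leaf(tape, state$b_c)))
  }
  h_a <- h_ag
  h_b <- h_tr
  out <- NULL
  for (i in seq_len(config$depth)) {
    lp <- state$layers[[i]]
    cat_node <- ad_cbind(tape, h_a, h_b)
    g <- ad_sigmoid(tape, ad_add_bias(tape,
                                      ad_matmul(tape, cat_node, ad_leaf(tape, lp$W_g)),
                                      ad_leaf(tape, lp$b_g)))
    # G*Ha + (1-G)*Hb written as Hb + G*(Ha - Hb)
    h_fused <- ad_add(tape, h_b, ad_mul(tape, g, ad_sub(tape, h_a, h_b)))
    h_res <- ad_add(tape, h_fused,
                    ad_scale(tape, ad_add(tape, h_a, h_b), 0.5))
    f <- ad_tanh(tape, ad_add_bias(tape,
                                   ad_matmul(tape, cat_node, ad_leaf(tape, lp$W_f)),
                                   ad_leaf(tape, lp$b_f)))
    out <- ad_add(tape, h_res, f)
    if (!is.null(dropout_masks) && config$dropout > 0) {
      out <- ad_dropout(tape, out, dropout_masks[[i]], config$dropout)
    }
    h_a <- out
    if (config$recurse_on == "previous") h_b <- out
  }
  out
}

#' Sigmoid gate matrix for two embeddings
#'
#' `G = sigmoid([H_a || H_b] W_g + b_g)`, elementwise in (0, 1).
#'
#' @param H_AG,H_TR Equal-shape embedding matrices.
#' @param W_g `2D x D` weight matrix.
#' @param b_g Bias vector of length D.
#' @return Gate matrix in (0, 1).
#' @export
gate_weights <- function(H_AG, H_TR, W_g, b_g) {
  if (!all(dim(H_AG) == dim(H_TR))) stop("embedding shapes differ")
  z <- sweep(cbind(H_AG, H_TR) %*% W_g, 2L, as.numeric(b_g), "+")
  1 / (1 + exp(-z))
}

#' Gated convex combination of two embeddings
#'
#' `G * H_AG + (1 - G) * H_TR`, elementwise.
#'
#' @param G Gate matrix in \[0, 1\].
#' @param H_AG,H_TR Embeddings to mix.
#' @return The fused matrix.
#' @export
gated_fusion <- function(G, H_AG, H_TR) {
  G * H_AG + (1 - G) * H_TR
}

#' One full gating layer (numeric, evaluation mode unless masks given)
#'
#' Gate, convex mix, mean-residual, tanh interaction, and optional dropout:
#' `H_out = H_fused + (H_a + H_b)/2 + tanh([H_a || H_b] W_f + b_f)`.
#'
#' @param H_a,H_b Input embeddings.
#' @param layer_state List with `W_g`, `b_g`, `W_f`, `b_f` (numeric).
#' @param p Dropout probability.
#' @param training If `TRUE`, applies inverted dropout with `mask` (0/1
#'   matrix); evaluation mode is the identity.
#' @param mask Optional dropout mask; required when `training` and `p > 0`.
#' @return The layer output matrix.
#' @export
gating_layer <- function(H_a, H_b, layer_state, p = 0.5, training = FALSE,
                         mask = NULL) {
  if (!all(dim(H_a) == dim(H_b))) stop("embedding shapes differ")
  g <- gate_weights(H_a, H_b, layer_state$W_g, layer_state$b_g)
  h_res <- gated_fusion(g, H_a, H_b) + (H_a + H_b) / 2
  f <- tanh(sweep(cbind(H_a, H_b) %*% layer_state$W_f, 2L,
                  as.numeric(layer_state$b_f), "+"))
  out <- h_res + f
  if (training && p > 0) {
    if (is.null(mask)) stop("training-mode dropout needs a mask")
    out <- out * mask / (1 - p)
  }
  out
}

#' Multi-layer gated fusion of the two encoder embeddings (evaluation mode)
#'
#' Layer 1 consumes `(H_AG, H_TR)`; each subsequent layer consumes the
#' previous output together with `H_TR` (or with itself when the config
#' says `recurse_on = "previous"`).
#'
#' @param H_AG,H_TR Encoder embeddings.
#' @param config A [gating_config()].
#' @param state A `gating_state`.
#' @return The final fused embedding matrix.
#' @export
fuse_multilayer <- function(H_AG, H_TR, config, state) {
  if (config$concat_fusion) {
    return(sweep(cbind(H_AG, H_TR) %*% state$W_c$value, 2L,
                 as.numeric(state$b_c$value), "+"))
  }
  if (length(state$layers) != config$depth) stop("state depth mismatch")
  h_a <- H_AG
  h_b <- H_TR
  out <- NULL
  for (i in seq_len(config$depth)) {
    lp <- state$layers[[i]]
    out <- gating_layer(h_a, h_b,
                        list(W_g = lp$W_g$value, b_g = lp$b_g$value,
                             W_f = lp$W_f$value, b_f = lp$b_f$value),
                        p = config$dropout, training = FALSE)
    h_a <- out
    if (config$recurse_on == "previous") h_b <- out
  }
  out
}
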
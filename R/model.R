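# Full model assembly: both encoders, the gating stack, and the MLP pair
# scorer, plus the single autodiff forward used for training and prediction.

#' Run configuration for the full association-prediction model
#'
#' Defaults follow the published hyperparameter study: embedding dimension
#' 512, 4 attention heads, 2 transformer convolution layers, 2 gating
#' layers, dropout 0.5, 5 folds on an 8:2 train/test split.
#'
#' @param dim Embedding width D.
#' @param heads Attention heads (both encoders).
#' @param gcan_att_layers Attention layers in the attention encoder.
#' @param gcan_gcn_layers GCN pre-encoding layers in the attention encoder.
#' @param gct_conv_layers Convolution layers in the transformer encoder.
#' @param gating_depth Gating layers.
#' @param dropout Dropout probability (gating stack).
#' @param leaky_slope LeakyReLU slope in attention logits.
#' @param folds Cross-validation folds.
#' @param test_fraction Held-out test share of the balanced pair set.
#' @param top_k Similarity neighbours per node in the attention graph.
#' @param distance_cap Hop-distance sentinel.
#' @param layout Feature-matrix layout (see [build_feature_matrix()]).
#' @param mirna_view,disease_view Similarity source per family:
#'   `"fused"` (functional/semantic averaged with GIP), `"functional"` /
#'   `"semantic"`, or `"gip"`.
#' @param variant Model variant: `"full"`, `"conv_only"` (transformer
#'   without self-attention), `"no_gcn_pre"` (plain graph attention
#'   encoder), `"concat_fusion"` (no gating), or `"vanilla_transformer"`
#'   (no graph convolutions, no distance bias).
#' @param recurse_on Gating recursion operand (see [gating_config()]).
#' @param lr,weight_decay,max_epochs,patience Adam learning rate, L2
#'   coupling, stage-one epoch budget, and early-stopping patience on
#'   validation AUC.
#' @param refit_epochs Fixed epoch budget of the stage-two refit on the
#'   full training split.
#' @param n_init Number of seeded initialisations refit and averaged into
#'   the final scorer (snapshot ensemble; reduces small-sample variance).
#' @param threshold Classification threshold for ACC/F1/recall/precision.
#' @return An `mda_config` list.
#' @export
mda_config <- function(dim = 512L, heads = 4L, gcan_att_layers = 2L,
                       gcan_gcn_layers = 1L, gct_conv_layers = 2L,
                       gating_depth = 2L, dropout = 0.5, leaky_slope = 0.2,
                       folds = 5L, test_fraction = 0.2, top_k = 10L,
                       distance_cap = 10L,
                       layout = c("block_with_assoc", "block_diagonal"),
                       mirna_view = c("fused", "functional", "gip"),
                       disease_view = c("fused", "semantic", "gip"),
                       variant = c("full", "conv_only", "no_gcn_pre",
                                   "concat_fusion", "vanilla_transformer"),
                       recurse_on = c("transformer", "previous"),
                       lr = 1e-3, weight_decay = 5e-4, max_epochs = 300L,
                       patience = 30L, refit_epochs = 300L, n_init = 3L,
                       threshold = 0.5) {
  stopifnot(folds >= 2L, test_fraction > 0, test_fraction < 1,
            refit_epochs >= 1L, n_init >= 1L)
  structure(list(
    dim = as.integer(dim), heads = as.integer(heads),
    gcan_att_layers = as.integer(gcan_att_layers),
    gcan_gcn_layers = as.integer(gcan_gcn_layers),
    gct_conv_layers = as.integer(gct_conv_layers),
    gating_depth = as.integer(gating_depth), dropout = dropout,
    leaky_slope = leaky_slope, folds = as.integer(folds),
    test_fraction = test_fraction, top_k = as.integer(top_k),
    refit_epochs = as.integer(refit_epochs), n_init = as.integer(n_init),
    distance_cap = as.integer(distance_cap), layout = match.arg(layout),
    mirna_view = match.arg(mirna_view),
    disease_view = match.arg(disease_view), variant = match.arg(variant),
    recurse_on = match.arg(recurse_on), lr = lr,
    weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), threshold = threshold
  ), class = "mda_config")
}

# Expand the run config into per-module configs honouring the variant.
module_configs <- function(config) {
  list(
    gcan = gcan_config(dim = config$dim, heads = config$heads,
                       att_layers = config$gcan_att_layers,
                       gcn_layers = config$gcan_gcn_layers,
                       leaky_slope = config$leaky_slope,
                       dropout = config$dropout,
                       use_gcn_pre = config$variant != "no_gcn_pre"),
    gct = gct_config(dim = config$dim, heads = config$heads,
                     conv_layers = config$gct_conv_layers,
                     distance_cap = config$distance_cap,
                     use_attention = config$variant != "conv_only",
                     use_conv = config$variant != "vanilla_transformer",
                     use_gaussian_bias = config$variant != "vanilla_transformer"),
    gating = gating_config(depth = config$gating_depth, dim = config$dim,
                           dropout = config$dropout,
                           concat_fusion = config$variant == "concat_fusion",
                           recurse_on = config$recurse_on)
  )
}

# Initialise every parameter of the model from the current RNG stream.
init_model <- function(config, in_dim) {
  cfgs <- module_configs(config)
  d <- config$dim
  structure(list(
    config = config,
    cfgs = cfgs,
    gcan = init_gcan_state(cfgs$gcan, in_dim),
    gct = init_gct_state(cfgs$gct, in_dim),
    gating = init_gating_state(cfgs$gating),
    mlp = list(W1 = ad_param(xavier_mat(3L * d, d)),
               b1 = ad_param(matrix(0, 1L, d), decay = FALSE),
               W2 = ad_param(xavier_mat(d, 1L)),
               b2 = ad_param(matrix(0, 1L, 1L), decay = FALSE))
  ), class = "mda_model")
}

model_params <- function(model) {
  c(gcan_params(model$gcan), gct_params(model$gct, model$cfgs$gct),
    gating_params(model$gating),
    list(model$mlp$W1, model$mlp$b1, model$mlp$W2, model$mlp$b2))
}

# One forward pass: embeddings -> pair vectors -> MLP probabilities.
# `pairs` is a matrix/data frame with miRNA index column `i` and disease
# index column `j` (1-based within each family).  Returns the tape and the
# score node; the caller attaches the loss.
forward_model <- function(model, graph, pairs, training = FALSE,
                          dropout_masks = NULL) {
  tape <- ad_tape()
  f_node <- ad_const(tape, graph$features)
  consts <- gcan_graph_consts(graph$neighbors)
  h_ag <- forward_gcan(tape, f_node, consts, model$cfgs$gcan, model$gcan)
  h_tr <- forward_gct(tape, f_node, graph$norm_adjacency,
                      graph$hop_distance^2, model$cfgs$gct, model$gct)
  fused <- forward_gating(tape, h_ag, h_tr, model$cfgs$gating, model$gating,
                          dropout_masks = if (training) dropout_masks)
  rows_m <- ad_rows(tape, fused, pairs$i)
  rows_d <- ad_rows(tape, fused, graph$n_mirna + pairs$j)
  # pair vector [h_i || h_j || h_i * h_j]: the elementwise product carries
  # the multiplicative affinity signal an MLP cannot recover from the
  # concatenation alone at small sample sizes
  pv <- ad_cbind(tape, ad_cbind(tape, rows_m, rows_d),
                 ad_mul(tape, rows_m, rows_d))
  hid <- ad_relu(tape, ad_add_bias(tape,
                                   ad_matmul(tape, pv, ad_leaf(tape, model$mlp$W1)),
                                   ad_leaf(tape, model$mlp$b1)))
  score <- ad_sigmoid(tape, ad_add_bias(tape,
                                        ad_matmul(tape, hid, ad_leaf(tape, model$mlp$W2)),
                                        ad_leaf(tape, model$mlp$b2)))
  list(tape = tape, score = score, fused = fused)
}

# Evaluation-mode scores for a pair table; plain numeric vector.
predict_pairs <- function(model, graph, pairs) {
  as.numeric(forward_model(model, graph, pairs, training = FALSE)$score$value)
}

#' Pair feature vector from a fused embedding
#'
#' Concatenates the miRNA row, the (offset) disease row and their
#' elementwise product: `[H[i, ], H[M + j, ], H[i, ] * H[M + j, ]]`.  The
#' product term gives the scorer direct access to dimension-wise affinity.
#'
#' @param H Node embedding matrix with miRNA rows first.
#' @param i miRNA index (1-based).
#' @param j Disease index (1-based, offset internally by `n_mirna`).
#' @param n_mirna Number of miRNA rows in `H`.
#' @return Numeric vector of length `3 * ncol(H)`.
#' @export
pair_embedding <- function(H, i, j, n_mirna) {
  if (i < 1L || i > n_mirna) stop("miRNA index out of range")
  if (j < 1L || n_mirna + j > nrow(H)) stop("disease index out of range")
  c(H[i, ], H[n_mirna + j, ], H[i, ] * H[n_mirna + j, ])
}

#' Score a pair vector with the MLP head
#'
#' Architecture `3D -> D -> 1`: ReLU hidden layer, sigmoid output.
#'
#' @param pair_vec Pair feature vector of length 2D.
#' @param mlp List with numeric `W1`, `b1`, `W2`, `b2`.
#' @return Probability in (0, 1).
#' @export
mlp_score <- function(pair_vec, mlp) {
  h <- pmax(as.numeric(pair_vec %*% mlp$W1) + as.numeric(mlp$b1), 0)
  z <- sum(h * mlp$W2) + as.numeric(mlp$b2)
  1 / (1 + exp(-z))
}

#' Fused node embedding of a trained or freshly initialised model
#'
#' @param model An `mda_model`.
#' @param graph A `hetero_graph`.
#' @return The `(M+N) x D` fused embedding matrix (evaluation mode).
#' @export
model_embedding <- function(model, graph) {
  fm <- forward_model(model, graph,
                      list(i = 1L, j = 1L), training = FALSE)
  fm$fused$value
}
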
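# Training protocol: balanced negative undersampling, stratified 8:2 split
# with k folds on the training side, Adam optimisation of the cross-entropy
# with early stopping on validation AUC, and leakage control by masking
# held-out positive edges out of the graph before encoding.

#' Balanced negative undersampling of unlabelled pairs
#'
#' Keeps every positive pair and draws an equal number of zero cells
#' uniformly without replacement; reproducible under `seed`.
#'
#' @param assoc An `assoc_matrix`.
#' @param seed RNG seed for the negative draw.
#' @return A tibble with miRNA index `i`, disease index `j`, `label`,
#'   `mirna` and `disease` identifiers.
#' @export
negative_undersample <- function(assoc, seed = 1L) {
  pos <- which(assoc$values == 1, arr.ind = TRUE)
  zero <- which(assoc$values == 0, arr.ind = TRUE)
  if (nrow(zero) < nrow(pos)) {
    stop("fewer zero cells than positives; cannot balance by undersampling")
  }
  neg <- with_seed(seed, zero[sample.int(nrow(zero), nrow(pos)), , drop = FALSE])
  idx <- rbind(pos, neg)
  tibble::tibble(
    i = as.integer(idx[, 1L]),
    j = as.integer(idx[, 2L]),
    label = rep(c(1L, 0L), each = nrow(pos)),
    mirna = assoc$mirna_ids[idx[, 1L]],
    disease = assoc$disease_ids[idx[, 2L]]
  )
}

#' Stratified train/test split with k folds on the training side
#'
#' Holds out `test_fraction` of the balanced pair set (stratified by label),
#' then partitions the remainder into `folds` label-stratified folds; each
#' fold's class counts differ by at most one.
#'
#' @param pairs Balanced pair tibble from [negative_undersample()].
#' @param folds Number of cross-validation folds.
#' @param test_fraction Held-out share.
#' @param seed RNG seed for the shuffles.
#' @return The pair tibble with a `fold` column: 0 marks the test set,
#'   1..k the training folds.
#' @export
split_and_folds <- function(pairs, folds = 5L, test_fraction = 0.2,
                            seed = 1L) {
  stopifnot(folds >= 2L)
  with_seed(seed, {
    fold <- integer(nrow(pairs))
    for (cls in c(1L, 0L)) {
      rows <- which(pairs$label == cls)
      rows <- rows[sample.int(length(rows))]
      n_test <- round(length(rows) * test_fraction)
      fold[rows[seq_len(n_test)]] <- 0L
      train_rows <- rows[-seq_len(n_test)]
      # stagger the starting fold per class so each fold stays balanced
      start <- if (cls == 1L) 0L else folds %/% 2L
      fold[train_rows] <- ((seq_along(train_rows) - 1L + start) %% folds) + 1L
    }
    if (!all(seq_len(folds) %in% fold)) {
      stop("not enough training pairs to populate ", folds, " folds")
    }
    dplyr::mutate(pairs, fold = fold)
  })
}

# Association matrix with the positive pairs of `mask_pairs` zeroed out
# (label-leakage control: held-out edges must not feed message passing).
mask_positives <- function(assoc, mask_pairs) {
  vals <- assoc$values
  mp <- mask_pairs[mask_pairs$label == 1L, , drop = FALSE]
  if (nrow(mp) > 0L) vals[cbind(mp$i, mp$j)] <- 0
  structure(list(mirna_ids = assoc$mirna_ids, disease_ids = assoc$disease_ids,
                 values = vals), class = "assoc_matrix")
}

# Resolve the configured similarity view for one family from the supplied
# view and the training-matrix GIP kernel.
resolve_view <- function(view, supplied, assoc, family) {
  if (view %in% c("functional", "semantic")) {
    if (is.null(supplied)) stop("view '", view, "' needs a supplied similarity")
    return(supplied)
  }
  gip <- gip_similarity(assoc, family)
  if (view == "gip") return(gip)
  if (is.null(supplied)) stop("view 'fused' needs a supplied similarity")
  fuse_similarities(supplied, gip, mode = "mean")
}

# Build the fold-specific graph from the train-masked association matrix.
training_graph <- function(assoc_train, m_sim, d_sim, config) {
  mv <- resolve_view(config$mirna_view, m_sim, assoc_train, "mirna")
  dv <- resolve_view(config$disease_view, d_sim, assoc_train, "disease")
  build_hetero_graph(assoc_train, mv, dv, layout = config$layout,
                     top_k = config$top_k,
                     distance_cap = config$distance_cap)
}

snapshot_params <- function(params) lapply(params, function(p) p$value)

restore_params <- function(params, snap) {
  for (k in seq_along(params)) params[[k]]$value <- snap[[k]]
  invisible(NULL)
}

# Core optimisation loop.  Assumes the RNG stream is already seeded by the
# caller; consumes it for dropout masks only.  With `fixed_epochs` set the
# loop runs exactly that many epochs with no snapshotting (refit stage);
# otherwise it early-stops on validation AUC and restores the best state.
fit_loop <- function(model, graph, train_pairs, val_pairs, config,
                     fixed_epochs = NULL, verbose = FALSE) {
  params <- model_params(model)
  n_nodes <- nrow(graph$features)
  need_masks <- config$dropout > 0 && model$cfgs$gating$depth >= 1L &&
    !model$cfgs$gating$concat_fusion
  best_auc <- -Inf
  best_snap <- if (is.null(fixed_epochs)) snapshot_params(params)
  best_epoch <- 0L
  wait <- 0L
  n_epochs <- fixed_epochs %||% config$max_epochs
  history <- vector("list", n_epochs)
  for (epoch in seq_len(n_epochs)) {
    masks <- if (need_masks) {
      lapply(seq_len(model$cfgs$gating$depth), function(i) {
        matrix(stats::rbinom(n_nodes * config$dim, 1L, 1 - config$dropout),
               n_nodes, config$dim)
      })
    }
    fm <- forward_model(model, graph, train_pairs, training = TRUE,
                        dropout_masks = masks)
    loss <- ad_bce(fm$tape, fm$score, train_pairs$label)
    if (!is.finite(loss$value[1L])) {
      stop("non-finite training loss at epoch ", epoch)
    }
    ad_backward(fm$tape, loss)
    adam_step(params, t = epoch, lr = config$lr,
              weight_decay = config$weight_decay)
    val_auc <- if (nrow(val_pairs) > 0L) {
      auc_score(predict_pairs(model, graph, val_pairs), val_pairs$label)
    } else NA_real_
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       loss = loss$value[1L],
                                       val_auc = val_auc)
    if (verbose && epoch %% 25L == 0L) {
      message(sprintf("epoch %3d  loss %.4f  val AUC %.4f",
                      epoch, loss$value[1L], val_auc))
    }
    if (is.null(fixed_epochs)) {
      if (val_auc > best_auc + 1e-6) {
        best_auc <- val_auc
        best_snap <- snapshot_params(params)
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    } else {
      best_epoch <- epoch
    }
  }
  if (is.null(fixed_epochs)) restore_params(params, best_snap)
  list(history = dplyr::bind_rows(history), best_epoch = best_epoch,
       best_val_auc = best_auc)
}

score_table <- function(model, graph, pairs, split, fold_id) {
  scores <- predict_pairs(model, graph, pairs)
  dplyr::mutate(pairs, score = scores, split = split, fold_id = fold_id,
                rank = rank(-scores, ties.method = "first"))
}

# Ensemble-averaged scores over a list of fitted models.
predict_pairs_ensemble <- function(models, graph, pairs) {
  rowMeans(vapply(models, function(m) predict_pairs(m, graph, pairs),
                  numeric(nrow(pairs))))
}

score_table_ensemble <- function(models, graph, pairs, split, fold_id) {
  scores <- predict_pairs_ensemble(models, graph, pairs)
  dplyr::mutate(pairs, score = scores, split = split, fold_id = fold_id,
                rank = rank(-scores, ties.method = "first"))
}

#' Train the association model on one train/validation/test split
#'
#' Runs the full pipeline: balanced negative undersampling, stratified
#' 8:2 split with k folds, graph construction from the train-masked
#' association matrix (GIP similarity recomputed on it), and two-stage
#' Adam training.  Stage one trains on the folds other than `val_fold`
#' with validation and test positives masked out of the graph, early
#' stopping on validation AUC to choose the epoch budget; stage two
#' refits on the whole training split (only test positives masked) for
#' exactly that many epochs.  Validation metrics come from stage one,
#' test metrics from the refit model.
#'
#' @param assoc An `assoc_matrix`.
#' @param m_sim,d_sim Supplied similarity views (may be `NULL` for pure
#'   GIP views).
#' @param config An [mda_config()].
#' @param seed Global run seed; every stochastic step derives from it.
#' @param val_fold Which training fold to use for validation/early
#'   stopping.
#' @param holdout_disease Optional disease identifier whose known
#'   associations are removed before training ("new disease" protocol).
#' @param refit Set `FALSE` to skip stage two and evaluate the
#'   early-stopped stage-one model on the test split directly.
#' @param verbose Print progress every 25 epochs.
#' @return An `mda_fit` object: trained `model`, `graph`, `scores` tibble
#'   (validation + test), per-split `metrics`, training `history`, the
#'   `pairs` table with fold assignments, `config`, `seed` and a run
#'   `manifest`.
#' @export
train_mda <- function(assoc, m_sim = NULL, d_sim = NULL,
                      config = mda_config(), seed = 1L, val_fold = 1L,
                      holdout_disease = NULL, refit = TRUE,
                      verbose = FALSE) {
  stopifnot(val_fold >= 1L, val_fold <= config$folds)
  if (!is.null(holdout_disease)) {
    jd <- match(holdout_disease, assoc$disease_ids)
    if (is.na(jd)) stop("unknown disease id: ", holdout_disease)
    assoc$values[, jd] <- 0
    if (sum(assoc$values) == 0) stop("holdout removed every association")
  }
  pairs <- negative_undersample(assoc, seed = child_seed(seed, 11L))
  pairs <- split_and_folds(pairs, folds = config$folds,
                           test_fraction = config$test_fraction,
                           seed = child_seed(seed, 12L))
  test_pairs <- pairs[pairs$fold == 0L, ]
  val_pairs <- pairs[pairs$fold == val_fold, ]
  train_pairs <- pairs[pairs$fold != 0L & pairs$fold != val_fold, ]

  # stage one: early-stopped run to pick the epoch budget
  assoc_sel <- mask_positives(assoc, rbind(test_pairs, val_pairs))
  graph_sel <- training_graph(assoc_sel, m_sim, d_sim, config)
  stage1 <- with_seed(child_seed(seed, 13L), {
    model <- init_model(config, in_dim = ncol(graph_sel$features))
    prog <- fit_loop(model, graph_sel, train_pairs, val_pairs, config,
                     verbose = verbose)
    list(model = model, prog = prog)
  })
  val_scores <- score_table(stage1$model, graph_sel, val_pairs,
                            "validation", val_fold)

  # stage two: refit on the full training split (only test edges masked)
  # for a fixed epoch budget, once per initialisation seed; test scores are
  # the ensemble average over initialisations
  if (refit) {
    assoc_train <- mask_positives(assoc, test_pairs)
    graph <- training_graph(assoc_train, m_sim, d_sim, config)
    all_train <- rbind(train_pairs, val_pairs)
    models <- lapply(seq_len(config$n_init), function(k) {
      with_seed(child_seed(seed, 13L + k), {
        model <- init_model(config, in_dim = ncol(graph$features))
        fit_loop(model, graph, all_train, val_pairs[0L, ], config,
                 fixed_epochs = config$refit_epochs, verbose = verbose)
        model
      })
    })
  } else {
    assoc_train <- assoc_sel
    graph <- graph_sel
    models <- list(stage1$model)
  }
  scores <- dplyr::bind_rows(
    val_scores,
    score_table_ensemble(models, graph, test_pairs, "test", 0L)
  )
  metrics <- dplyr::bind_rows(
    dplyr::mutate(evaluate_scores(scores[scores$split == "validation", ],
                                  threshold = config$threshold),
                  split = "validation", .before = 1L),
    dplyr::mutate(evaluate_scores(scores[scores$split == "test", ],
                                  threshold = config$threshold),
                  split = "test", .before = 1L)
  )
  manifest <- list(
    config = unclass(config), seed = seed, val_fold = val_fold,
    holdout_disease = holdout_disease, refit = refit,
    n_mirna = length(assoc$mirna_ids), n_disease = length(assoc$disease_ids),
    n_positive = sum(assoc$values), best_epoch = stage1$prog$best_epoch,
    refit_epochs = if (refit) config$refit_epochs else NA_integer_,
    n_init = length(models),
    assoc_digest = rlang::hash(assoc$values)
  )
  structure(list(model = models[[1L]], models = models, graph = graph,
                 assoc = assoc,
                 assoc_train = assoc_train, pairs = pairs, scores = scores,
                 metrics = metrics, history = stage1$prog$history,
                 config = config, seed = seed, manifest = manifest),
            class = "mda_fit")
}

#' Capacity check: overfit a small balanced pair subset
#'
#' Trains the model (dropout disabled, as usual for a capacity test) on a
#' small balanced subset of pairs with no edge masking and reports the
#' training AUC per epoch; a healthy implementation separates the subset
#' perfectly well within the epoch budget.
#'
#' @inheritParams train_mda
#' @param n_pairs Total subset size (half positives, half negatives).
#' @param epochs Epoch budget.
#' @return A list with `train_auc` (final), `epochs_to_perfect` (first
#'   epoch reaching AUC 1, or `NA`), and the `history` tibble.
#' @export
capacity_check <- function(assoc, m_sim = NULL, d_sim = NULL,
                           config = mda_config(), seed = 1L,
                           n_pairs = 50L, epochs = 200L) {
  config$dropout <- 0
  pairs <- negative_undersample(assoc, seed = child_seed(seed, 21L))
  take <- min(n_pairs %/% 2L, sum(pairs$label == 1), sum(pairs$label == 0))
  sub <- with_seed(child_seed(seed, 22L), {
    pos <- pairs[pairs$label == 1L, ][sample.int(sum(pairs$label == 1), take), ]
    neg <- pairs[pairs$label == 0L, ][sample.int(sum(pairs$label == 0), take), ]
    rbind(pos, neg)
  })
  graph <- training_graph(assoc, m_sim, d_sim, config)
  hist <- with_seed(child_seed(seed, 23L), {
    model <- init_model(config, in_dim = ncol(graph$features))
    params <- model_params(model)
    rows <- vector("list", epochs)
    for (epoch in seq_len(epochs)) {
      fm <- forward_model(model, graph, sub, training = TRUE)
      loss <- ad_bce(fm$tape, fm$score, sub$label)
      ad_backward(fm$tape, loss)
      adam_step(params, t = epoch, lr = config$lr,
                weight_decay = config$weight_decay)
      auc <- auc_score(predict_pairs(model, graph, sub), sub$label)
      rows[[epoch]] <- tibble::tibble(epoch = epoch, loss = loss$value[1L],
                                      train_auc = auc)
      if (auc >= 1) break
    }
    dplyr::bind_rows(rows)
  })
  perfect <- which(hist$train_auc >= 1)
  list(train_auc = hist$train_auc[nrow(hist)],
       epochs_to_perfect = if (length(perfect)) perfect[1L] else NA_integer_,
       history = hist)
}

#' k-fold cross-validation of the association model
#'
#' Rotates the validation fold over the k training folds of a single
#' balanced, stratified split (one negative sample per run seed) and
#' reports per-fold validation metrics plus the mean and standard
#' deviation.
#'
#' @inheritParams train_mda
#' @return An `mda_cv` object with `fits` (list of `mda_fit`),
#'   `fold_metrics`, and `summary` (mean and sd per metric).
#' @export
crossvalidate_mda <- function(assoc, m_sim = NULL, d_sim = NULL,
                              config = mda_config(), seed = 1L,
                              verbose = FALSE) {
  fits <- lapply(seq_len(config$folds), function(f) {
    train_mda(assoc, m_sim, d_sim, config = config, seed = seed,
              val_fold = f, verbose = verbose)
  })
  fold_metrics <- dplyr::bind_rows(lapply(seq_along(fits), function(f) {
    dplyr::mutate(fits[[f]]$metrics[fits[[f]]$metrics$split == "validation", ],
                  fold = f, .before = 1L)
  }))
  num <- c("acc", "f1", "recall", "precision", "auc", "auprc")
  summary <- dplyr::bind_rows(
    dplyr::summarise(fold_metrics,
                     dplyr::across(dplyr::all_of(num), mean),
                     stat = "mean"),
    dplyr::summarise(fold_metrics,
                     dplyr::across(dplyr::all_of(num), stats::sd),
                     stat = "sd")
  )
  structure(list(fits = fits, fold_metrics = fold_metrics,
                 summary = summary, config = config, seed = seed),
            class = "mda_cv")
}

#' Logistic-regression baseline on raw interaction profiles
#'
#' Independent reference model: ridge-regularised logistic regression
#' (glmnet) on the concatenated association profiles of the train-masked
#' matrix, with the scored cell itself zeroed out of both profiles so the
#' training label is not readable from the features.
#'
#' @param assoc_train Train-masked `assoc_matrix`.
#' @param train_pairs,eval_pairs Pair tibbles with `i`, `j`, `label`.
#' @param lambda Ridge penalty.
#' @return Numeric vector of predicted probabilities for `eval_pairs`.
#' @export
logistic_baseline <- function(assoc_train, train_pairs, eval_pairs,
                              lambda = 0.01) {
  featurize <- function(pairs) {
    x <- cbind(assoc_train$values[pairs$i, , drop = FALSE],
               t(assoc_train$values)[pairs$j, , drop = FALSE])
    n_d <- ncol(assoc_train$values)
    for (r in seq_len(nrow(pairs))) {
      x[r, pairs$j[r]] <- 0
      x[r, n_d + pairs$i[r]] <- 0
    }
    x
  }
  fit <- glmnet::glmnet(featurize(train_pairs), factor(train_pairs$label),
                        family = "binomial", alpha = 0, lambda = lambda)
  as.numeric(stats::predict(fit, featurize(eval_pairs), type = "response"))
}

#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA against the query disease with the trained model and
#' returns the top k, optionally masking miRNAs whose association with the
#' disease was available at training time; ties are broken by miRNA
#' identifier.
#'
#' @param fit An `mda_fit`.
#' @param disease_id Disease identifier.
#' @param k Number of candidates to return.
#' @param exclude_known Drop training-known positive miRNAs of the disease.
#' @return A tibble with `rank`, `mirna`, `disease`, `score`, `known`.
#' @export
rank_candidates <- function(fit, disease_id, k = 20L, exclude_known = TRUE) {
  j <- match(disease_id, fit$assoc$disease_ids)
  if (is.na(j)) stop("unknown disease id: ", disease_id)
  m <- length(fit$assoc$mirna_ids)
  pairs <- tibble::tibble(i = seq_len(m), j = j)
  scores <- predict_pairs_ensemble(fit$models, fit$graph, pairs)
  known <- fit$assoc_train$values[, j] == 1
  tab <- tibble::tibble(mirna = fit$assoc$mirna_ids, disease = disease_id,
                        score = scores, known = known)
  if (exclude_known) tab <- tab[!tab$known, ]
  tab <- tab[order(-tab$score, tab$mirna), ]
  tab <- utils::head(tab, k)
  dplyr::mutate(tab, rank = dplyr::row_number(), .before = 1L)
}

#' Ablation harness over all model variants
#'
#' Trains the full model and its four ablations on the same data and seed
#' and reports test metrics per variant (ordering is reported, not
#' asserted).
#'
#' @inheritParams train_mda
#' @param variants Character vector of variants to run.
#' @return An `mda_ablation` object with a `report` tibble and the fits.
#' @export
run_ablation <- function(assoc, m_sim = NULL, d_sim = NULL,
                         config = mda_config(), seed = 1L,
                         variants = c("full", "conv_only", "no_gcn_pre",
                                      "concat_fusion", "vanilla_transformer"),
                         verbose = FALSE) {
  fits <- lapply(variants, function(v) {
    cfg <- config
    cfg$variant <- v
    train_mda(assoc, m_sim, d_sim, config = cfg, seed = seed,
              verbose = verbose)
  })
  names(fits) <- variants
  report <- dplyr::bind_rows(lapply(variants, function(v) {
    dplyr::mutate(fits[[v]]$metrics[fits[[v]]$metrics$split == "test", ],
                  variant = v, .before = 1L)
  }))
  structure(list(report = report, fits = fits, seed = seed),
            class = "mda_ablation")
}
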
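#' @importFrom generics tidy glance
#' @importFrom rlang %||% .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-split metrics of a fit
#'
#' @param x An `mda_fit`.
#' @param ... Unused.
#' @return A tibble of metrics per split.
#' @method tidy mda_fit
#' @export
tidy.mda_fit <- function(x, ...) x$metrics

#' One-row summary of a fit
#'
#' @param x An `mda_fit`.
#' @param ... Unused.
#' @return A one-row tibble with test AUC/AUPRC, best epoch and sizes.
#' @method glance mda_fit
#' @export
glance.mda_fit <- function(x, ...) {
  te <- x$metrics[x$metrics$split == "test", ]
  tibble::tibble(
    auc = te$auc, auprc = te$auprc, acc = te$acc, f1 = te$f1,
    best_epoch = x$manifest$best_epoch,
    n_train = sum(x$pairs$fold > 0),
    n_test = sum(x$pairs$fold == 0),
    variant = x$config$variant, seed = x$seed
  )
}

#' Tidy per-fold validation metrics of a cross-validation run
#'
#' @param x An `mda_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold.
#' @method tidy mda_cv
#' @export
tidy.mda_cv <- function(x, ...) x$fold_metrics

#' Mean and dispersion of cross-validated metrics
#'
#' @param x An `mda_cv`.
#' @param ... Unused.
#' @return A one-row tibble of mean metrics with sd columns.
#' @method glance mda_cv
#' @export
glance.mda_cv <- function(x, ...) {
  mu <- x$summary[x$summary$stat == "mean", ]
  sdv <- x$summary[x$summary$stat == "sd", ]
  tibble::tibble(auc = mu$auc, auc_sd = sdv$auc, auprc = mu$auprc,
                 auprc_sd = sdv$auprc, acc = mu$acc, f1 = mu$f1,
                 folds = nrow(x$fold_metrics))
}

#' @export
print.mda_fit <- function(x, ...) {
  te <- x$metrics[x$metrics$split == "test", ]
  cat("miRNA-disease association fit (variant:", x$config$variant, ")\n")
  cat(sprintf("  nodes: %d miRNA x %d disease, dim %d\n",
              x$graph$n_mirna, x$graph$n_disease, x$config$dim))
  cat(sprintf("  stopped at epoch %d; test AUC %.4f, AUPRC %.4f\n",
              x$manifest$best_epoch, te$auc, te$auprc))
  invisible(x)
}

#' @export
print.mda_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("%d-fold CV: AUC %.4f +/- %.4f, AUPRC %.4f +/- %.4f\n",
              g$folds, g$auc, g$auc_sd, g$auprc, g$auprc_sd))
  invisible(x)
}

#' @export
print.mda_ablation <- function(x, ...) {
  cat("Ablation report (test split):\n")
  print(as.data.frame(x$report[, c("variant", "auc", "auprc", "f1")]),
        row.names = FALSE)
  invisible(x)
}

# ROC and PR curve coordinates for a score table.
curve_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.numeric(labels)[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  tibble::tibble(
    tpr = tp / sum(y), fpr = fp / sum(1 - y),
    precision = tp / seq_along(y), recall = tp / sum(y)
  )
}

#' ROC and precision-recall diagnostics of a fit
#'
#' @param object An `mda_fit`.
#' @param split Which score split to plot (`"test"` or `"validation"`).
#' @param ... Unused.
#' @return A ggplot with ROC and PR panels.
#' @method autoplot mda_fit
#' @export
autoplot.mda_fit <- function(object, split = "test", ...) {
  tab <- object$scores[object$scores$split == split, ]
  cp <- curve_points(tab$score, tab$label)
  df <- dplyr::bind_rows(
    tibble::tibble(x = c(0, cp$fpr), y = c(0, cp$tpr), panel = "ROC"),
    tibble::tibble(x = cp$recall, y = cp$precision, panel = "Precision-recall")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s split: AUC %.3f, AUPRC %.3f",
                                  split,
                                  auc_score(tab$score, tab$label),
                                  auprc_score(tab$score, tab$label))) +
    ggplot2::theme_minimal()
}

#' Training-history diagnostics
#'
#' @param object An `mda_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and validation AUC per epoch.
#' @export
plot_history <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_auc"),
                           names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
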
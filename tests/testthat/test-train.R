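test_that("negative undersampling balances classes reproducibly", {
  dat <- tiny_dataset()
  p1 <- negative_undersample(dat$assoc, seed = 5)
  expect_equal(sum(p1$label == 1), sum(p1$label == 0))
  expect_equal(sum(p1$label == 1), sum(dat$assoc$values))
  # positives are exactly the known associations
  expect_true(all(dat$assoc$values[cbind(p1$i, p1$j)[p1$label == 1, ]] == 1))
  expect_true(all(dat$assoc$values[cbind(p1$i, p1$j)[p1$label == 0, ]] == 0))
  # no duplicated sampled negatives
  neg <- p1[p1$label == 0, ]
  expect_false(anyDuplicated(paste(neg$i, neg$j)) > 0)
  expect_identical(p1, negative_undersample(dat$assoc, seed = 5))
  p2 <- negative_undersample(dat$assoc, seed = 6)
  expect_false(identical(p1, p2))

  # a forced 2x3 grid with three positives: every zero cell must be drawn
  a <- association_matrix(edge_df(c("m1", "d1"), c("m1", "d2"), c("m2", "d3")))
  forced <- negative_undersample(a, seed = 1)
  expect_equal(nrow(forced), 6L)
  expect_setequal(paste(forced$i, forced$j),
                  paste(rep(1:2, each = 3), rep(1:3, 2)))
  # and balancing fails when zeros are scarcer than ones
  b <- association_matrix(edge_df(c("m1", "d1"), c("m1", "d2"), c("m2", "d1"),
                                  c("m2", "d2")))
  expect_error(negative_undersample(b, seed = 1), "balance")
})

test_that("splits are stratified 8:2 with balanced folds", {
  # ten balanced pairs: 2 test, folds of sizes {2, 2, 2, 1, 1}
  pairs <- tibble::tibble(i = rep(1:5, 2), j = rep(1:2, each = 5),
                          label = rep(c(1L, 0L), length.out = 10))
  sp <- split_and_folds(pairs, folds = 5, test_fraction = 0.2, seed = 3)
  expect_equal(sum(sp$fold == 0), 2L)
  expect_equal(sort(table(sp$fold[sp$fold > 0]), decreasing = TRUE),
               sort(c(2, 2, 2, 1, 1), decreasing = TRUE), ignore_attr = TRUE)

  dat <- tiny_dataset()
  pairs <- negative_undersample(dat$assoc, seed = 5)
  sp <- split_and_folds(pairs, folds = 5, test_fraction = 0.2, seed = 3)
  # test split is 20% and stratified
  expect_equal(sum(sp$fold == 0), round(0.2 * nrow(sp)))
  expect_equal(sum(sp$label[sp$fold == 0] == 1),
               sum(sp$label[sp$fold == 0] == 0))
  # folds partition the training pairs with per-fold class balance +/- 1
  for (f in 1:5) {
    tf <- sp[sp$fold == f, ]
    expect_lte(abs(sum(tf$label == 1) - sum(tf$label == 0)), 1)
  }
  expect_equal(sum(sp$fold > 0) + sum(sp$fold == 0), nrow(pairs))
})

test_that("held-out positive edges are masked out of the training graph", {
  dat <- tiny_dataset()
  pairs <- negative_undersample(dat$assoc, seed = 5)
  sp <- split_and_folds(pairs, folds = 5, test_fraction = 0.2, seed = 3)
  heldout <- sp[sp$fold %in% c(0, 1), ]
  masked <- mdfuse:::mask_positives(dat$assoc, heldout)
  hp <- heldout[heldout$label == 1, ]
  expect_true(all(masked$values[cbind(hp$i, hp$j)] == 0))
  kept <- sp[sp$fold > 1 & sp$label == 1, ]
  expect_true(all(masked$values[cbind(kept$i, kept$j)] == 1))
})

test_that("pair embeddings and the MLP head obey their contracts", {
  h <- matrix(rnorm(50), 10, 5)
  pe <- pair_embedding(h, 2, 3, n_mirna = 6)
  expect_length(pe, 15L)
  expect_equal(pe, c(h[2, ], h[9, ], h[2, ] * h[9, ]))
  expect_error(pair_embedding(h, 7, 3, n_mirna = 6), "miRNA index")
  expect_error(pair_embedding(h, 1, 5, n_mirna = 6), "disease index")

  mlp0 <- list(W1 = matrix(0, 15, 5), b1 = rep(0, 5),
               W2 = matrix(0, 5, 1), b2 = 0)
  expect_equal(mlp_score(pe, mlp0), 0.5)
  mlp_hi <- mlp0; mlp_hi$b2 <- 50
  expect_gt(mlp_score(pe, mlp_hi), 1 - 1e-12)
})

test_that("an untrained model scores held-out pairs at chance level", {
  dat <- default_fixture()
  cfg <- recovery_config()
  pairs <- negative_undersample(dat$assoc, seed = mdfuse:::child_seed(1, 11))
  graph <- mdfuse:::training_graph(dat$assoc, dat$m_sim, dat$d_sim, cfg)
  aucs <- sapply(1:12, function(k) {
    mdfuse:::with_seed(1000 + k, {
      model <- mdfuse:::init_model(cfg, ncol(graph$features))
      auc_score(mdfuse:::predict_pairs(model, graph, pairs), pairs$label)
    })
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("training is deterministic given config and seed", {
  dat <- tiny_dataset()
  cfg <- fast_config()
  f1 <- train_mda(dat$assoc, dat$m_sim, dat$d_sim, config = cfg, seed = 11)
  f2 <- train_mda(dat$assoc, dat$m_sim, dat$d_sim, config = cfg, seed = 11)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$metrics, f2$metrics)
  f3 <- train_mda(dat$assoc, dat$m_sim, dat$d_sim, config = cfg, seed = 12)
  expect_false(identical(f3$scores$score, f1$scores$score))
})

test_that("training reduces the loss and the fit exposes tidy accessors", {
  dat <- tiny_dataset()
  fit <- train_mda(dat$assoc, dat$m_sim, dat$d_sim,
                   config = fast_config(max_epochs = 60), seed = 2)
  h <- fit$history
  expect_lt(min(h$loss[-1]), h$loss[1])
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
  expect_true(all(fit$scores$score >= 0 & fit$scores$score <= 1))
  # ranks are a permutation within each split
  for (s in unique(fit$scores$split)) {
    r <- fit$scores$rank[fit$scores$split == s]
    expect_setequal(r, seq_along(r))
  }
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("cross-validation rotates the validation fold and summarises", {
  dat <- tiny_dataset()
  cv <- crossvalidate_mda(dat$assoc, dat$m_sim, dat$d_sim,
                          config = fast_config(folds = 3), seed = 4)
  expect_length(cv$fits, 3L)
  expect_equal(nrow(cv$fold_metrics), 3L)
  expect_equal(cv$fold_metrics$fold, 1:3)
  g <- glance(cv)
  expect_true(g$auc >= 0 && g$auc <= 1)
  expect_false(is.na(g$auc_sd))
})

test_that("candidate ranking masks known positives and breaks ties by id", {
  dat <- tiny_dataset()
  fit <- train_mda(dat$assoc, dat$m_sim, dat$d_sim, config = fast_config(),
                   seed = 2)
  did <- dat$assoc$disease_ids[3]
  m <- length(dat$assoc$mirna_ids)
  full <- rank_candidates(fit, did, k = m, exclude_known = FALSE)
  expect_setequal(full$mirna, dat$assoc$mirna_ids)
  known <- dat$assoc$mirna_ids[fit$assoc_train$values[, 3] == 1]
  excl <- rank_candidates(fit, did, k = m, exclude_known = TRUE)
  expect_setequal(setdiff(full$mirna, excl$mirna), known)
  expect_equal(nrow(rank_candidates(fit, did, k = 5)), 5L)
  expect_error(rank_candidates(fit, "no-such-disease"), "unknown disease")
})

test_that("the new-disease protocol removes a disease's links before training", {
  dat <- tiny_dataset()
  did <- dat$assoc$disease_ids[which.max(colSums(dat$assoc$values))]
  fit <- train_mda(dat$assoc, dat$m_sim, dat$d_sim, config = fast_config(),
                   seed = 2, holdout_disease = did)
  j <- match(did, dat$assoc$disease_ids)
  expect_true(all(fit$assoc$values[, j] == 0))
  expect_true(all(fit$assoc_train$values[, j] == 0))
  ranked <- rank_candidates(fit, did, k = 10)
  expect_equal(nrow(ranked), 10L)
})

test_that("the profile baseline produces sane probabilities", {
  dat <- tiny_dataset()
  pairs <- negative_undersample(dat$assoc, seed = 5)
  sp <- split_and_folds(pairs, folds = 5, test_fraction = 0.2, seed = 3)
  tr <- sp[sp$fold > 0, ]; te <- sp[sp$fold == 0, ]
  masked <- mdfuse:::mask_positives(dat$assoc, te)
  p <- logistic_baseline(masked, tr, te)
  expect_length(p, nrow(te))
  expect_true(all(p > 0 & p < 1))
})
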
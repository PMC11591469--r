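test_that("association matrices are built with sorted ids and 0/1 entries", {
  a <- association_matrix(edge_df(c("m1", "d1"), c("m1", "d2"), c("m2", "d1")))
  expect_equal(a$mirna_ids, c("m1", "m2"))
  expect_equal(a$disease_ids, c("d1", "d2"))
  expect_equal(unname(a$values), rbind(c(1, 1), c(1, 0)))

  # duplicates collapse to a single entry, with a warning
  expect_warning(
    b <- association_matrix(edge_df(c("m1", "d1"), c("m1", "d1"), c("m2", "d1"))),
    "duplicate"
  )
  expect_equal(sum(b$values), 2)

  expect_error(association_matrix(data.frame()), "empty")
})

test_that("association TSV round-trips through read/write", {
  a <- tiny_dataset()$assoc
  path <- withr::local_tempfile(fileext = ".tsv")
  write_associations(a, path)
  b <- read_associations(path)
  expect_identical(b$values, a$values)
  expect_identical(b$mirna_ids, a$mirna_ids)
})

test_that("similarity matrices round-trip and reject asymmetry", {
  s <- tiny_dataset()$m_sim
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity(s, path)
  r <- read_similarity(path, family = "mirna", source = "functional")
  expect_equal(r$values, s$values, tolerance = 1e-12)

  bad <- s$values
  bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(similarity_view(bad, "mirna", "functional"), "symmetric")
})

test_that("GIP kernel matches its closed form and contracts", {
  # two orthogonal unit profiles: gamma = 2/2 = 1, sim = exp(-2)
  a <- association_matrix(edge_df(c("m1", "d1"), c("m2", "d2")))
  g <- gip_similarity(a, "mirna")
  expect_equal(g$values[1, 2], exp(-2), tolerance = 1e-12)
  expect_true(all(diag(g$values) == 1))

  # identical nonzero profiles give similarity exactly 1
  b <- association_matrix(edge_df(c("m1", "d1"), c("m2", "d1")))
  expect_equal(gip_similarity(b, "mirna")$values[1, 2], 1)

  # all-zero matrix is rejected (vacuous bandwidth)
  z <- a; z$values[] <- 0
  expect_error(gip_similarity(z, "mirna"), "undefined")

  # property: symmetric, unit diagonal, entries in (0, 1], 1 iff equal rows
  dat <- tiny_dataset()
  for (fam in c("mirna", "disease")) {
    g <- gip_similarity(dat$assoc, fam)$values
    expect_lt(max(abs(g - t(g))), 1e-10)
    expect_true(all(diag(g) == 1))
    expect_true(all(g > 0 & g <= 1))
    prof <- if (fam == "mirna") dat$assoc$values else t(dat$assoc$values)
    same <- outer(seq_len(nrow(prof)), seq_len(nrow(prof)), Vectorize(function(i, j) {
      all(prof[i, ] == prof[j, ])
    }))
    expect_equal(g == 1, same, ignore_attr = TRUE)
  }
})

test_that("similarity fusion obeys both rules", {
  dat <- tiny_dataset()
  a <- dat$m_sim
  b <- gip_similarity(dat$assoc, "mirna")
  expect_equal(fuse_similarities(a, a, "mean")$values, a$values)
  expect_equal(fuse_similarities(a, a, "prefer_a_nonzero")$values, a$values)
  fm <- fuse_similarities(a, b, "mean")$values
  off <- row(fm) != col(fm)
  expect_equal(fm[off], ((a$values + b$values) / 2)[off])
  # prefer_a_nonzero falls back to b where a is zero
  a0 <- a; a0$values[1, 2] <- a0$values[2, 1] <- 0
  pf <- fuse_similarities(a0, b, "prefer_a_nonzero")$values
  expect_equal(pf[1, 2], (b$values[1, 2] + b$values[2, 1]) / 2)
  d <- dat$d_sim
  expect_error(fuse_similarities(a, d, "mean"), "famil")
})

test_that("block adjacency is symmetric with zero diagonal blocks", {
  withr::local_seed(11)
  for (rep in 1:100) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    vals <- matrix(rbinom(m * n, 1, 0.4), m, n)
    assoc <- structure(list(mirna_ids = sprintf("m%02d", 1:m),
                            disease_ids = sprintf("d%02d", 1:n),
                            values = vals), class = "assoc_matrix")
    adj <- build_heterogeneous_adjacency(assoc)
    expect_identical(dim(adj), c(m + n, m + n))
    expect_equal(adj, t(adj), ignore_attr = TRUE)
    expect_true(all(adj[1:m, 1:m] == 0))
    expect_true(all(adj[m + 1:n, m + 1:n] == 0))
    expect_equal(unname(adj[1:m, m + 1:n, drop = FALSE]), vals)
  }
})

test_that("adjacency normalisation matches hand values and is equivariant", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  two <- rbind(c(0, 1), c(1, 0))
  expect_equal(normalize_adjacency(two), matrix(0.5, 2, 2))

  withr::local_seed(5)
  a <- matrix(rbinom(49, 1, 0.3), 7, 7)
  a <- pmax(a, t(a)); diag(a) <- 0
  na <- normalize_adjacency(a)
  expect_equal(na, t(na))
  expect_lte(max(abs(eigen(na, only.values = TRUE)$values)), 1 + 1e-6)
  p <- sample(7)
  expect_equal(normalize_adjacency(a[p, p]), na[p, p])
})

test_that("feature matrix layouts agree with their contracts", {
  dat <- tiny_dataset()
  m <- length(dat$assoc$mirna_ids); n <- length(dat$assoc$disease_ids)
  f <- build_feature_matrix(dat$m_sim, dat$d_sim, dat$assoc)
  expect_identical(dim(f), c(m + n, m + n))
  expect_equal(unname(f[1:m, m + 1:n]), unname(dat$assoc$values))

  # identity similarities + zero associations give the identity matrix
  zero <- dat$assoc; zero$values[] <- 0
  ms <- similarity_view(diag(m), "mirna", "functional")
  ds <- similarity_view(diag(n), "disease", "semantic")
  expect_equal(build_feature_matrix(ms, ds, zero), diag(m + n),
               ignore_attr = TRUE)
  expect_equal(build_feature_matrix(ms, ds, zero, "block_diagonal"),
               build_feature_matrix(ms, ds, zero, "block_with_assoc"),
               ignore_attr = TRUE)
})

test_that("hop distances match brute-force shortest paths below the cap", {
  # 3-node path: endpoints at distance 2; disconnected pair gets the cap
  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(hop_distances(path3, 10)[1, 3], 2L)
  disc <- matrix(0, 2, 2)
  expect_equal(hop_distances(disc, 10)[1, 2], 10L)
  expect_error(hop_distances(path3, 0), "cap")

  withr::local_seed(21)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    a <- matrix(rbinom(n * n, 1, 0.15), n, n)
    a <- pmax(a, t(a)); diag(a) <- 0
    d <- hop_distances(a, cap = n + 5L)
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    # Floyd-Warshall oracle
    fw <- matrix(Inf, n, n); diag(fw) <- 0; fw[a == 1] <- 1
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
      fw[i, j] <- min(fw[i, j], fw[i, k] + fw[k, j])
    }
    fw[!is.finite(fw)] <- n + 5L
    expect_equal(d, fw, ignore_attr = TRUE)
  }
})

test_that("top-k sparsification keeps the right neighbours and symmetrises", {
  s <- similarity_view(rbind(c(1, 0.9, 0.1), c(0.9, 1, 0.5), c(0.1, 0.5, 1)),
                       "mirna", "functional")
  nb <- sparsify_similarity(s, top_k = 1)
  expect_equal(nb[[1]], 2L)
  # union symmetrisation: 3 picks 2, so 2 also lists 3
  expect_true(3L %in% nb[[2]])
  # identity similarity: all off-diagonal ties resolve to the lowest index
  id <- similarity_view(diag(4), "mirna", "functional")
  nbi <- sparsify_similarity(id, top_k = 1)
  expect_equal(nbi[[2]][1], 1L)
  expect_warning(sparsify_similarity(id, top_k = 10), "top_k")
  expect_error(sparsify_similarity(id, top_k = 0), "top_k")
})

test_that("assembled graphs include fallback self-edges and family offsets", {
  dat <- tiny_dataset()
  g <- build_hetero_graph(dat$assoc, dat$m_sim, dat$d_sim, top_k = 3)
  expect_s3_class(g, "hetero_graph")
  expect_true(all(lengths(g$neighbors) >= 1))
  m <- g$n_mirna
  # association neighbours of miRNA 1 appear with the disease offset
  dis <- which(dat$assoc$values[1, ] == 1)
  expect_true(all((m + dis) %in% g$neighbors[[1]]))
})
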
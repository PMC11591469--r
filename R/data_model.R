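#' Build an association matrix from an edge table
#'
#' Converts a tidy edge list of validated miRNA-disease links into the binary
#' M x N association matrix used throughout the package.  Identifiers are
#' deduplicated and sorted lexicographically so indexing is reproducible
#' across runs; duplicate pairs are accepted once with a warning.
#'
#' @param edges A data frame whose first two columns are miRNA and disease
#'   identifiers; an optional third column of 0/1 labels defaults to 1.
#' @return An object of class `assoc_matrix`: a list with `mirna_ids`,
#'   `disease_ids` and the binary `values` matrix (rows = miRNAs).
#' @examples
#' edges <- tibble::tibble(mirna = c("m1", "m1", "m2"),
#'                         disease = c("d1", "d2", "d1"))
#' association_matrix(edges)
#' @export
association_matrix <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) stop("edge table is empty")
  if (ncol(edges) < 2L) stop("edge table needs at least two columns")
  mir <- as.character(edges[[1L]])
  dis <- as.character(edges[[2L]])
  lab <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, nrow(edges))
  if (!all(lab %in% c(0, 1))) stop("labels must be 0/1")
  keep <- lab == 1
  mir <- mir[keep]; dis <- dis[keep]
  if (length(mir) == 0L) stop("no positive associations in edge table")
  if (anyDuplicated(paste(mir, dis, sep = "\r"))) {
    warning("duplicate association pairs collapsed to single entries")
  }
  mids <- sort(unique(mir))
  dids <- sort(unique(dis))
  values <- matrix(0, length(mids), length(dids),
                   dimnames = list(mids, dids))
  values[cbind(match(mir, mids), match(dis, dids))] <- 1
  structure(list(mirna_ids = mids, disease_ids = dids, values = values),
            class = "assoc_matrix")
}

#' Read a miRNA-disease association edge list from TSV
#'
#' The file holds `mirna_id<TAB>disease_id[<TAB>label]`; a header row is
#' detected and skipped when the first field is not a plausible identifier
#' pair seen elsewhere (any row whose third field is non-numeric is treated
#' as a header).
#'
#' @param path Path to a tab-separated edge list.
#' @return An `assoc_matrix` (see [association_matrix()]).
#' @export
read_associations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("association file is empty: ", path)
  # drop a header row if the optional third column is non-numeric there
  first <- df[1L, ]
  looks_header <- (ncol(df) >= 3L && is.na(suppressWarnings(as.numeric(first[[3L]])))) ||
    tolower(first[[1L]]) %in% c("mirna", "mirna_id", "mir")
  if (looks_header) df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L) stop("association file has a header but no rows: ", path)
  if (ncol(df) >= 3L) df[[3L]] <- as.numeric(df[[3L]])
  association_matrix(df)
}

#' Write an association matrix back to its TSV edge-list form
#' @param assoc An `assoc_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  idx <- which(assoc$values == 1, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  df <- data.frame(mirna = assoc$mirna_ids[idx[ord, 1L]],
                   disease = assoc$disease_ids[idx[ord, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a similarity view
#'
#' A similarity view is a symmetric matrix in \[0, 1\] with unit diagonal for
#' one node family (miRNA or disease) and one source (functional, semantic,
#' gip or fused).
#'
#' @param values Square numeric matrix, symmetric within `1e-6`.
#' @param family `"mirna"` or `"disease"`.
#' @param source One of `"functional"`, `"semantic"`, `"gip"`, `"fused"`.
#' @param ids Optional node identifiers (defaults to rownames).
#' @return A `similarity_view` object.
#' @export
similarity_view <- function(values, family, source, ids = rownames(values)) {
  family <- match.arg(family, c("mirna", "disease"))
  source <- match.arg(source, c("functional", "semantic", "gip", "fused"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (max(abs(values - t(values))) > 1e-6) {
    stop("similarity matrix is not symmetric within 1e-6")
  }
  if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop("similarity entries must lie in [0, 1]")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 1
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  structure(list(family = family, source = source, values = values),
            class = "similarity_view")
}

#' Read a labelled similarity matrix from CSV/TSV
#'
#' First row and first column carry node identifiers; symmetry is validated
#' within `1e-6`.
#'
#' @inheritParams similarity_view
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @return A `similarity_view`.
#' @export
read_similarity <- function(path, family, source) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE)
  similarity_view(as.matrix(df), family = family, source = source)
}

#' Write a similarity view to CSV/TSV (ids in first row/column)
#' @param sim A `similarity_view`.
#' @param path Output path; `.tsv` writes tabs, anything else commas.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- as.data.frame(sim$values)
  utils::write.table(cbind(id = rownames(sim$values), df), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' For binary interaction profiles `IP(i)` (rows of the association matrix
#' for miRNAs, columns for diseases), the kernel is
#' `sim(i, j) = exp(-gamma * ||IP(i) - IP(j)||^2)` with the bandwidth
#' normalised by the mean squared profile norm,
#' `gamma = n / sum_i ||IP(i)||^2`.
#'
#' @param assoc An `assoc_matrix`.
#' @param family `"mirna"` (row profiles) or `"disease"` (column profiles).
#' @return A `similarity_view` with source `"gip"`.
#' @examples
#' a <- association_matrix(data.frame(m = c("m1", "m2"), d = c("d1", "d2")))
#' gip_similarity(a, "mirna")$values  # off-diagonal exp(-2)
#' @export
gip_similarity <- function(assoc, family = c("mirna", "disease")) {
  family <- match.arg(family)
  prof <- if (family == "mirna") assoc$values else t(assoc$values)
  norms2 <- rowSums(prof^2)
  if (sum(norms2) == 0) {
    stop("all-zero association matrix: GIP bandwidth is undefined")
  }
  gamma <- nrow(prof) / sum(norms2)
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(norms2, norms2, "+") - 2 * prof %*% t(prof)
  d2[d2 < 0] <- 0
  ids <- if (family == "mirna") assoc$mirna_ids else assoc$disease_ids
  similarity_view(exp(-gamma * d2), family = family, source = "gip", ids = ids)
}

#' Fuse two similarity views of the same family
#'
#' `mode = "mean"` averages elementwise; `mode = "prefer_a_nonzero"` keeps
#' `a` where it is nonzero and falls back to `b` elsewhere.  The result is
#' re-symmetrised and the diagonal forced to 1.
#'
#' @param a,b `similarity_view` objects of equal family and size.
#' @param mode Fusion rule.
#' @return A `similarity_view` with source `"fused"`.
#' @export
fuse_similarities <- function(a, b, mode = c("mean", "prefer_a_nonzero")) {
  mode <- match.arg(mode)
  if (a$family != b$family) stop("similarity views are for different families")
  if (!all(dim(a$values) == dim(b$values))) stop("similarity size mismatch")
  out <- switch(mode,
    mean = (a$values + b$values) / 2,
    prefer_a_nonzero = ifelse(a$values > 0, a$values, b$values)
  )
  out <- (out + t(out)) / 2
  diag(out) <- 1
  similarity_view(out, family = a$family, source = "fused",
                  ids = rownames(a$values))
}

#' Heterogeneous block adjacency of the bipartite association graph
#'
#' Returns the (M+N) x (M+N) binary matrix
#' `[[0, G_md], [G_md^T, 0]]` whose off-diagonal blocks hold the association
#' sub-matrix and its transpose; the diagonal blocks are exactly zero.
#'
#' @param assoc An `assoc_matrix`.
#' @return A symmetric binary matrix with miRNA nodes first.
#' @export
build_heterogeneous_adjacency <- function(assoc) {
  m <- length(assoc$mirna_ids)
  n <- length(assoc$disease_ids)
  adj <- matrix(0, m + n, m + n)
  adj[seq_len(m), m + seq_len(n)] <- assoc$values
  adj[m + seq_len(n), seq_len(m)] <- t(assoc$values)
  rownames(adj) <- colnames(adj) <- c(assoc$mirna_ids, assoc$disease_ids)
  adj
}

#' Symmetric renormalised adjacency with self-loops
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `D` is the degree matrix of
#' `A + I` -- the standard GCN propagation operator.  Isolated nodes keep a
#' self-loop of weight 1.
#'
#' @param adj Symmetric binary adjacency matrix.
#' @return Symmetric real matrix with spectral radius at most 1.
#' @export
normalize_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (max(abs(adj - t(adj))) > 0) stop("adjacency must be symmetric")
  ai <- adj + diag(nrow(adj))
  dinv <- 1 / sqrt(rowSums(ai))
  ai * outer(dinv, dinv)
}

#' Node feature matrix from similarity views and association profiles
#'
#' Stacks miRNA and disease similarity matrices into a single
#' `(M+N) x (M+N)` feature matrix.  With `layout = "block_with_assoc"`
#' (default) the off blocks carry association profiles: the row for miRNA i
#' is `[m_sim row i, assoc row i]` and the row for disease j is
#' `[assoc column j, d_sim row j]`.  `"block_diagonal"` zeroes the off
#' blocks.
#'
#' @param m_sim,d_sim `similarity_view`s for miRNAs and diseases.
#' @param assoc The `assoc_matrix` (dimension check + off-block content).
#' @param layout `"block_with_assoc"` or `"block_diagonal"`.
#' @return A real `(M+N) x (M+N)` matrix.
#' @export
build_feature_matrix <- function(m_sim, d_sim, assoc,
                                 layout = c("block_with_assoc", "block_diagonal")) {
  layout <- match.arg(layout)
  m <- length(assoc$mirna_ids)
  n <- length(assoc$disease_ids)
  if (nrow(m_sim$values) != m || nrow(d_sim$values) != n) {
    stop("similarity dimensions do not match the association matrix")
  }
  av <- if (layout == "block_with_assoc") assoc$values else matrix(0, m, n)
  rbind(cbind(m_sim$values, av), cbind(t(av), d_sim$values))
}

#' All-pairs hop distances on a graph
#'
#' Breadth-first shortest path length between every node pair;
#' unreachable pairs receive the sentinel `cap`.
#'
#' @param adj Symmetric binary adjacency matrix.
#' @param cap Positive integer sentinel (also an upper bound: finite
#'   distances above `cap` are truncated to `cap`).
#' @return Integer matrix of hop counts with zero diagonal.
#' @export
hop_distances <- function(adj, cap = 10L) {
  if (cap < 1L) stop("cap must be >= 1")
  g <- igraph::graph_from_adjacency_matrix(as.matrix(adj) > 0,
                                           mode = "undirected", diag = FALSE)
  d <- igraph::distances(g)
  d[!is.finite(d)] <- cap
  d[d > cap] <- cap
  storage.mode(d) <- "integer"
  d
}

#' Top-k sparsification of a similarity matrix into neighbour lists
#'
#' Keeps, for each node, its `top_k` most similar other nodes (ties broken
#' toward the lower index), then symmetrises the edge set by union.
#'
#' @param sim A `similarity_view`.
#' @param top_k Number of neighbours to keep per node.
#' @return A list of integer neighbour index vectors, one per node.
#' @export
sparsify_similarity <- function(sim, top_k = 10L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  s <- sim$values
  n <- nrow(s)
  if (top_k >= n) {
    warning("top_k >= matrix size; keeping all other nodes")
    top_k <- n - 1L
  }
  picked <- vector("list", n)
  for (i in seq_len(n)) {
    v <- s[i, ]
    v[i] <- -Inf
    # order(): decreasing similarity, ties by lower index
    picked[[i]] <- order(v, seq_len(n), decreasing = c(TRUE, FALSE),
                         method = "radix")[seq_len(top_k)]
  }
  nb <- picked
  for (i in seq_len(n)) {
    for (j in picked[[i]]) nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(x) sort(unique(x)))
}

#' Assemble the heterogeneous graph consumed by both encoders
#'
#' Bundles the block adjacency, its symmetric renormalisation, the node
#' feature matrix, the hop-distance matrix, and the neighbour lists used by
#' the attention encoder (association edges plus top-k similarity edges,
#' self excluded; isolated nodes get a fallback self-edge so every
#' attention neighbourhood is non-empty).
#'
#' @inheritParams build_feature_matrix
#' @param top_k Similarity neighbours kept per node (within each family).
#' @param distance_cap Sentinel/ceiling for hop distances.
#' @return A `hetero_graph` list: `adjacency`, `norm_adjacency`, `features`,
#'   `hop_distance`, `neighbors`, `n_mirna`, `n_disease`, `node_ids`.
#' @export
build_hetero_graph <- function(assoc, m_sim, d_sim,
                               layout = c("block_with_assoc", "block_diagonal"),
                               top_k = 10L, distance_cap = 10L) {
  layout <- match.arg(layout)
  m <- length(assoc$mirna_ids)
  n <- length(assoc$disease_ids)
  adj <- build_heterogeneous_adjacency(assoc)
  nb_m <- sparsify_similarity(m_sim, top_k = min(top_k, m - 1L))
  nb_d <- sparsify_similarity(d_sim, top_k = min(top_k, n - 1L))
  neighbors <- vector("list", m + n)
  for (i in seq_len(m)) {
    neighbors[[i]] <- sort(unique(c(nb_m[[i]], m + which(assoc$values[i, ] == 1))))
  }
  for (j in seq_len(n)) {
    neighbors[[m + j]] <- sort(unique(c(m + nb_d[[j]],
                                        which(assoc$values[, j] == 1))))
  }
  for (i in seq_along(neighbors)) {
    if (length(neighbors[[i]]) == 0L) neighbors[[i]] <- i
  }
  structure(list(
    adjacency = adj,
    norm_adjacency = normalize_adjacency(adj),
    features = build_feature_matrix(m_sim, d_sim, assoc, layout = layout),
    hop_distance = hop_distances(adj, cap = distance_cap),
    neighbors = neighbors,
    n_mirna = m,
    n_disease = n,
    node_ids = c(assoc$mirna_ids, assoc$disease_ids)
  ), class = "hetero_graph")
}
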
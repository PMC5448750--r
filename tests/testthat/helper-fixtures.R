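# Small fixtures and independent oracles shared across the test files.

toy_expression <- function(values, genes = NULL, ages = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(ages)) ages <- paste0("a", seq_len(ncol(values)))
  expression_table(values, genes, ages)
}

write_expression_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Exhaustive minimal k-partition inertia by enumerating all label vectors
# (first point pinned to cluster 1 to kill label symmetry). Independent of
# the package's Lloyd implementation.
brute_force_inertia <- function(x, k) {
  n <- nrow(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n - 1)))
  L <- cbind(1L, grid)
  total <- sum(x^2)
  explained <- 0
  valid <- rep(TRUE, nrow(L))
  parts <- matrix(0, nrow(L), k)
  for (cc in seq_len(k)) {
    M <- L == cc
    nc <- rowSums(M)
    valid <- valid & nc > 0
    S <- M %*% x
    parts[, cc] <- ifelse(nc > 0, rowSums(S^2) / nc, 0)
  }
  inertia <- total - rowSums(parts)
  min(inertia[valid])
}

# Direct numeric iteration of the MCL map on a small dense matrix,
# written without the package internals; returns the component partition
# of the limit matrix's nonzero structure.
mcl_oracle_partition <- function(adj, inflation = 2, iters = 200) {
  diag(adj) <- apply(adj, 2, max)
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
    M[M < 1e-12] <- 0
  }
  # connected components of the symmetrized support
  supp <- (M + t(M)) > 0
  n <- nrow(supp)
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(supp[v, ] & is.na(comp)))
    }
  }
  comp
}

# contingency table from a raw count matrix, bypassing build_contingency
ct_from_matrix <- function(O) {
  O <- as.matrix(O)
  if (is.null(rownames(O))) rownames(O) <- seq_len(nrow(O)) - 1
  if (is.null(colnames(O))) colnames(O) <- paste0("c", seq_len(ncol(O)))
  structure(list(observed = O, row_totals = rowSums(O),
                 col_totals = colSums(O), grand_total = sum(O),
                 excluded_genes = character(0)),
            class = "ContingencyTable")
}

# adjusted Rand index oracle (mclust when present, else exact formula)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  cn2 <- function(x) sum(choose(x, 2))
  idx <- cn2(tab); rs <- cn2(rowSums(tab)); cs <- cn2(colSums(tab))
  expected <- rs * cs / choose(sum(tab), 2)
  (idx - expected) / ((rs + cs) / 2 - expected)
}
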
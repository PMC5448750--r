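#' @name ortholog_screen
#' @title Orthology screen: Markov clustering of a protein-similarity graph
#' @description
#' The conserved-label screen clusters an all-versus-all protein-similarity
#' matrix spanning the human, mouse, fly and worm proteomes with the
#' Markov Cluster (MCL) algorithm, then keeps clusters that contain both a
#' mammalian and an invertebrate member and a mammalian transmembrane
#' protein carrying an extracellular motif typical of guidance molecules,
#' excluding families whose guidance role is already established.
NULL

#' Motifs characteristic of known guidance and adhesion molecules
#' @rdname ortholog_screen
#' @export
MOTIF_WHITELIST <- c("Ig", "FN3", "cadherin", "LRR", "EGF", "CUB",
                     "sema", "plexin_repeat")

#' Gene families with demonstrated guidance/connectivity roles,
#' excluded from the novelty screen
#' @rdname ortholog_screen
#' @export
FAMILY_BLACKLIST <- c("DCC", "Neogenin", "Robo", "Slit", "L1CAM",
                      "Contactin", "Eph-receptor", "Ephrin", "FGF",
                      "FGFR", "RPTP", "Cadherin", "Protocadherin",
                      "Semaphorin", "Plexin", "Integrin")

#' Build an undirected similarity graph from per-query ranked hits
#'
#' Keeps each query's top `n` hits by score (all hits tied with the score
#' at rank `n` are kept), drops self-hits, and symmetrizes directed pairs
#' by the maximum of the two directed scores.
#'
#' @param hits data frame with columns `query`, `hit`, `score` (>= 0; bit
#'   scores or -log E-values -- the semantics are opaque to the
#'   clustering).
#' @param n hits retained per query (default 200).
#' @return Object of class `SimilarityGraph`: list with `edges` (data
#'   frame `from`, `to`, `weight`, each unordered pair once) and `nodes`
#'   (character vector of ids).
#' @export
top_n_edges <- function(hits, n = 200) {
  stopifnot(all(c("query", "hit", "score") %in% names(hits)))
  if (any(hits$score < 0)) stop("negative similarity score")
  hits <- hits[hits$query != hits$hit, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query), function(i) {
    s <- hits$score[i]
    if (length(i) <= n) return(i)
    cut <- sort(s, decreasing = TRUE)[n]
    i[s >= cut]  # ties at rank n are all retained
  }), use.names = FALSE)
  kept <- hits[keep, , drop = FALSE]
  a <- pmin(kept$query, kept$hit)
  b <- pmax(kept$query, kept$hit)
  w <- tapply(kept$score, paste(a, b, sep = "\r"), max)
  pair <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  edges <- data.frame(from = pair[, 1], to = pair[, 2],
                      weight = as.numeric(w), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(hits$query, hits$hit)))),
            class = "SimilarityGraph")
}

#' Similarity graph from an explicit edge list
#'
#' @param edges data frame `from`, `to`, `weight` (undirected, no
#'   self-edges).
#' @param nodes optional node ids beyond those present in `edges`.
#' @rdname top_n_edges
#' @export
similarity_graph <- function(edges, nodes = NULL) {
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and >= 0")
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$from, edges$to, nodes)))),
            class = "SimilarityGraph")
}

#' Markov clustering (MCL) of a weighted similarity graph
#'
#' Deterministic graph clustering by simulating flow: the symmetrized
#' adjacency matrix gains self-loops (weight = the node's maximum incident
#' edge weight, for robustness to heterogeneous score ranges), is
#' column-normalized to a stochastic matrix, then alternates expansion
#' (matrix power `e`, spreading flow) and inflation (entrywise power `r`
#' followed by column renormalization, strengthening strong flows) with
#' pruning of entries below `prune`, until the matrix change falls below
#' `tol`. Clusters are read off the attractor structure: rows with nonzero
#' diagonal mass are attractors, and every node joins the cluster of the
#' attractor(s) it flows to; nodes reached by several attractors go to the
#' lowest-id attractor so the output is a partition.
#'
#' @param g a [similarity_graph()] / [top_n_edges()] graph.
#' @param inflation inflation exponent r > 1 (default 2.0); larger values
#'   give finer clusters.
#' @param expansion expansion power e >= 2 (default 2).
#' @param prune entries below this are zeroed each iteration (default
#'   1e-5).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence threshold on the maximum entry change (default
#'   1e-6).
#' @param self_loop `"max"` (default, maximum incident weight) or a
#'   positive number used for every node.
#' @return Object of class `ClusterSet`: list with `clusters` (list of
#'   character id vectors, ordered by lowest member), `membership` (named
#'   integer vector), `iterations`, `converged` (logical; a `FALSE` comes
#'   with a warning).
#' @export
mcl <- function(g, inflation = 2.0, expansion = 2L, prune = 1e-5,
                max_iter = 100L, tol = 1e-6, self_loop = "max") {
  stopifnot(inherits(g, "SimilarityGraph"))
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be >= 2")
  ids <- g$nodes
  nn <- length(ids)
  if (nn == 0) stop("empty graph")
  A <- matrix(0, nn, nn, dimnames = list(ids, ids))
  if (nrow(g$edges) > 0) {
    i <- match(g$edges$from, ids); j <- match(g$edges$to, ids)
    A[cbind(i, j)] <- pmax(A[cbind(i, j)], g$edges$weight)
    A[cbind(j, i)] <- A[cbind(i, j)]
  }
  loop <- if (identical(self_loop, "max")) {
    w <- apply(A, 2, max)
    ifelse(w > 0, w, 1)
  } else rep(as.numeric(self_loop), nn)
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (p in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1  # a fully pruned column would otherwise divide by 0
    Mnew <- sweep(Minf, 2, cs, "/")
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations")
  membership <- interpret_mcl(M, prune)
  names(membership) <- ids
  cl <- split(ids, membership)
  names(cl) <- NULL
  structure(list(clusters = cl, membership = membership,
                 iterations = it, converged = converged),
            class = "ClusterSet")
}

# Read the attractor structure of the converged flow matrix into a
# partition: attractor rows have positive diagonal; node j belongs to
# attractor i when M[i, j] > 0; multiple attractors reaching one node tie
# to the lowest attractor index; unreached nodes become singletons.
interpret_mcl <- function(M, prune) {
  nn <- nrow(M)
  attractors <- which(diag(M) > prune)
  membership <- rep(NA_integer_, nn)
  # attractors reaching each other belong to one attractor system
  sys_of <- stats::setNames(seq_along(attractors), attractors)
  for (i in attractors) for (j in attractors) {
    if (j > i && (M[i, j] > 0 || M[j, i] > 0)) {
      a <- sys_of[[as.character(i)]]; b <- sys_of[[as.character(j)]]
      sys_of[sys_of == max(a, b)] <- min(a, b)
    }
  }
  for (j in seq_len(nn)) {
    reach <- attractors[M[attractors, j] > 0]
    if (length(reach) > 0)
      membership[j] <- min(sys_of[as.character(reach)])
  }
  loose <- which(is.na(membership))
  if (length(loose) > 0)
    membership[loose] <- max(c(0L, membership), na.rm = TRUE) +
      seq_along(loose)
  match(membership, sort(unique(membership)))
}

#' Filter MCL clusters for conserved transmembrane motif-bearing families
#'
#' A cluster passes when it has (a) a mammalian (human or mouse) member,
#' (b) an invertebrate (fly or worm) member, (c) a mammalian member that
#' is transmembrane and carries a whitelisted motif, and (d) no member of
#' a blacklisted (already characterised) family. The strict variant
#' additionally requires an invertebrate member to be transmembrane with a
#' whitelisted motif.
#'
#' @param cs a [mcl()] `ClusterSet`.
#' @param nodes data frame with columns `id`, `taxon` (one of `human`,
#'   `mouse`, `fly`, `worm`), `has_tm` (logical), `motifs`
#'   (`;`-separated string, may be empty), `family` (optional family name,
#'   `NA`/empty if none).
#' @param motif_whitelist,family_blacklist defaults [MOTIF_WHITELIST],
#'   [FAMILY_BLACKLIST].
#' @param strict also require the TM+motif test on an invertebrate member.
#' @return data frame: `cluster`, `n_members`, `passes`, `reason` (empty
#'   when passing, else the first failed criterion).
#' @export
filter_candidate_clusters <- function(cs, nodes,
                                      motif_whitelist = MOTIF_WHITELIST,
                                      family_blacklist = FAMILY_BLACKLIST,
                                      strict = FALSE) {
  stopifnot(inherits(cs, "ClusterSet"),
            all(c("id", "taxon", "has_tm", "motifs") %in% names(nodes)))
  missing_ids <- setdiff(unlist(cs$clusters), nodes$id)
  if (length(missing_ids) > 0)
    stop("unannotated node(s): ", paste(missing_ids, collapse = ", "))
  bad_taxon <- !nodes$taxon %in% c("human", "mouse", "fly", "worm")
  if (any(bad_taxon))
    stop("unknown taxon for node(s): ",
         paste(nodes$id[bad_taxon], collapse = ", "))
  fam <- if (is.null(nodes$family)) rep(NA_character_, nrow(nodes))
         else nodes$family
  motif_hit <- vapply(strsplit(nodes$motifs, ";", fixed = TRUE),
                      function(mm) any(trimws(mm) %in% motif_whitelist),
                      logical(1))
  rows <- lapply(seq_along(cs$clusters), function(ci) {
    idx <- match(cs$clusters[[ci]], nodes$id)
    mam <- nodes$taxon[idx] %in% c("human", "mouse")
    inv <- nodes$taxon[idx] %in% c("fly", "worm")
    tm_motif <- nodes$has_tm[idx] & motif_hit[idx]
    blacklisted <- !is.na(fam[idx]) & fam[idx] %in% family_blacklist
    reason <- if (!any(mam)) "no mammalian member"
      else if (!any(inv)) "no invertebrate member"
      else if (!any(mam & tm_motif))
        "no mammalian TM member with whitelisted motif"
      else if (strict && !any(inv & tm_motif))
        "no invertebrate TM member with whitelisted motif"
      else if (any(blacklisted))
        paste0("blacklisted family: ",
               paste(unique(fam[idx][blacklisted]), collapse = ", "))
      else ""
    data.frame(cluster = ci, n_members = length(idx),
               passes = reason == "", reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
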
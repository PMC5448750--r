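#' Multi-restart k-means over temporal profiles
#'
#' Lloyd's algorithm with Euclidean distance. Each restart draws k distinct
#' rows as initial centroids, alternates nearest-centroid assignment and
#' centroid recomputation until the largest centroid shift falls below
#' `tol` (or `max_iter` is reached), and the restart with the smallest
#' total within-cluster squared distance (inertia) is returned. Restarting
#' many times guards against poor local minima of the stochastic
#' initialization; the screen's own analyses used a thousand restarts.
#'
#' An emptied cluster is re-seeded at the point farthest from its assigned
#' centroid, keeping all k clusters non-empty deterministically.
#'
#' @param m numeric matrix (observations x features), no missing values.
#' @param k number of clusters, `2 <= k <= nrow(m)`.
#' @param restarts number of random initializations (default 1000).
#' @param max_iter Lloyd iteration cap per restart.
#' @param tol convergence threshold on the maximum centroid coordinate
#'   shift.
#' @param seed integer seed; results are deterministic given the seed.
#' @param init optional k x ncol(m) matrix of starting centroids; when
#'   supplied a single Lloyd run is performed from it (used for oracle
#'   comparisons).
#' @return Object of class `ClusterModel`: list with `k`, `assignments`
#'   (named integer vector, labels in `0:(k-1)`), `centroids`, `inertia`,
#'   `restarts`, `seed`, `iterations` (of the winning restart).
#' @export
kmeans_profiles <- function(m, k, restarts = 1000, max_iter = 300,
                            tol = 1e-8, seed = 1, init = NULL) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite values in input matrix")
  n <- nrow(m)
  if (k < 1 || k > n) stop("k must be in [1, nrow(m)]")
  if (!is.null(init)) {
    best <- lloyd_once(m, k, init, max_iter, tol)
  } else {
    set.seed(as.integer(seed))
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- m[sample.int(n, k), , drop = FALSE]
      fit <- lloyd_once(m, k, centers, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  }
  assignments <- best$cluster - 1L
  names(assignments) <- rownames(m)
  structure(
    list(k = as.integer(k), assignments = assignments,
         centroids = best$centers, inertia = best$inertia,
         restarts = if (is.null(init)) as.integer(restarts) else 1L,
         seed = if (is.null(init)) as.integer(seed) else NA_integer_,
         iterations = best$iter),
    class = "ClusterModel")
}

# Squared Euclidean distances from every row of m to every row of centers.
.sqdist <- function(m, centers) {
  d <- outer(rowSums(m^2), rowSums(centers^2), "+") - 2 * tcrossprod(m, centers)
  d[d < 0] <- 0
  d
}

# One Lloyd run from given starting centroids.
lloyd_once <- function(m, k, centers, max_iter, tol) {
  n <- nrow(m)
  for (it in seq_len(max_iter)) {
    d2 <- .sqdist(m, centers)
    cl <- max.col(-d2, ties.method = "first")
    # re-seed emptied clusters at the point farthest from its own centroid
    for (j in which(tabulate(cl, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(n), cl)])
      cl[far] <- j
      d2[far, ] <- Inf; d2[far, j] <- 0
    }
    new_centers <- rowsum(m, cl, reorder = TRUE) / tabulate(cl, k)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- .sqdist(m, centers)
  cl <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), cl)])
  list(cluster = cl, centers = centers, inertia = inertia, iter = it)
}

#' Map clusters of one partition onto another and score their agreement
#'
#' For each cluster of partition `b`, the parent is the cluster of
#' partition `a` sharing the most members (ties broken toward the lower
#' `a` label). The stability score is the summed maximal overlaps divided
#' by the number of genes: it equals 1 exactly when `b` refines `a`
#' (clusters are only subdivided, never reshuffled), and drops toward the
#' size of the largest-cluster fraction under arbitrary reshuffling.
#'
#' @param a,b integer label vectors over the same genes (same names/order).
#' @return list with `parent` (named integer vector: b-label -> a-label)
#'   and `stability` (numeric in (0, 1]).
#' @export
cluster_correspondence <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions cover different gene sets")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different gene sets")
    b <- b[names(a)]
  }
  ov <- table(b = b, a = a)
  parent <- apply(ov, 1, which.max)  # ties -> first (lowest) a label
  parent <- stats::setNames(as.integer(colnames(ov)[parent]), rownames(ov))
  stability <- sum(apply(ov, 1, max)) / length(a)
  list(parent = parent, stability = stability)
}

#' Sweep k-means over a range of cluster counts
#'
#' Fits one [kmeans_profiles()] model per k and, for each adjacent pair
#' (k, k+1), records the parent map and stability score of
#' [cluster_correspondence()]. High stability across the sweep indicates
#' that increasing k subdivides clusters rather than reshuffling them --
#' a roughly hierarchical organisation.
#'
#' @inheritParams kmeans_profiles
#' @param k_min,k_max inclusive sweep bounds (defaults 6 and 18).
#' @return Object of class `KSweepResult`: list with `models` (named by k)
#'   and `transitions` (per adjacent pair: `from`, `to`, `parent`,
#'   `stability`).
#' @export
sweep_k <- function(m, k_min = 6, k_max = 18, restarts = 1000,
                    max_iter = 300, tol = 1e-8, seed = 1) {
  if (k_min < 2 || k_max < k_min) stop("need 2 <= k_min <= k_max")
  ks <- k_min:k_max
  models <- lapply(ks, function(k)
    kmeans_profiles(m, k, restarts, max_iter, tol, seed = seed + k))
  names(models) <- ks
  transitions <- lapply(seq_len(length(ks) - 1), function(i) {
    cc <- cluster_correspondence(models[[i]]$assignments,
                                 models[[i + 1]]$assignments)
    list(from = ks[i], to = ks[i + 1], parent = cc$parent,
         stability = cc$stability)
  })
  structure(list(models = models, transitions = transitions),
            class = "KSweepResult")
}

#' Summarize clusters by mean profile and chronology of peak expression
#'
#' Averages normalized profiles per cluster (over present values per age),
#' finds each cluster's peak age (ties resolved to the earliest age) and
#' orders clusters chronologically by peak age. Peak-age ties in the
#' ordering are broken toward the larger mean at the peak, then the lower
#' label.
#'
#' @param nt a `NormalizedTable` covering the clustered genes.
#' @param cm a `ClusterModel` whose assignments cover `nt`'s genes.
#' @return Object of class `ClusterSummary`: list with `profiles` (k x age
#'   matrix of means), `peak_age` (character), `peak_index` (integer),
#'   `chron_rank` (integer, 0-based permutation ordered by peak age),
#'   `size` (member counts), `labels`.
#' @export
summarize_clusters <- function(nt, cm) {
  stopifnot(inherits(nt, "ExpressionTable"), inherits(cm, "ClusterModel"))
  lab <- cm$assignments[nt$gene_ids]
  if (anyNA(lab)) stop("assignments do not cover the table's genes")
  sizes <- table(factor(lab, levels = 0:(cm$k - 1)))
  if (any(sizes == 0)) stop("empty cluster label(s): ",
                            paste(names(sizes)[sizes == 0], collapse = ", "))
  prof <- t(vapply(0:(cm$k - 1), function(l)
    colMeans(nt$values[lab == l, , drop = FALSE], na.rm = TRUE),
    numeric(length(nt$age_labels))))
  dimnames(prof) <- list(0:(cm$k - 1), nt$age_labels)
  peak_idx <- apply(prof, 1, which.max)  # which.max -> earliest on ties
  peak_val <- prof[cbind(seq_len(nrow(prof)), peak_idx)]
  ord <- order(peak_idx, -peak_val, as.integer(rownames(prof)))
  rank <- integer(cm$k)
  rank[ord] <- 0:(cm$k - 1)
  structure(
    list(profiles = prof, peak_age = nt$age_labels[peak_idx],
         peak_index = peak_idx, chron_rank = rank,
         size = as.integer(sizes), labels = 0:(cm$k - 1)),
    class = "ClusterSummary")
}
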
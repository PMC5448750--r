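#' Normalize densities to per-gene relative temporal profiles
#'
#' Each gene's densities are divided by that gene's mean density over its
#' present (non-missing) ages, so a value of 1 marks the gene's own average
#' expression level and the profile describes temporal shape rather than
#' absolute level. Missing cells stay missing.
#'
#' Genes whose present values are all zero have an undefined profile; they
#' are dropped from the returned table and reported, since a flat-zero gene
#' cannot inform temporal clustering. Genes missing at every age must be
#' removed first with [filter_all_missing()].
#'
#' @param t an [expression_table()].
#' @return An object of class `NormalizedTable`: like `ExpressionTable`,
#'   plus `gene_means` (the per-gene divisor) and `zero_mean_genes`
#'   (character vector of excluded all-zero genes).
#' @export
normalize_per_gene <- function(t) {
  stopifnot(inherits(t, "ExpressionTable"))
  n_present <- rowSums(!t$missing_mask)
  if (any(n_present == 0))
    stop("gene(s) with all ages missing: ",
         paste(t$gene_ids[n_present == 0], collapse = ", "),
         "; run filter_all_missing() first")
  means <- rowMeans(t$values, na.rm = TRUE)
  zero <- means == 0
  if (any(zero))
    warning("excluding ", sum(zero),
            " gene(s) with all-zero measurements: ",
            paste(t$gene_ids[zero], collapse = ", "))
  vals <- t$values[!zero, , drop = FALSE] / means[!zero]
  out <- expression_table(vals, t$gene_ids[!zero], t$age_labels)
  out$gene_means <- unname(means[!zero])
  out$zero_mean_genes <- t$gene_ids[zero]
  class(out) <- c("NormalizedTable", "ExpressionTable")
  out
}

#' Produce a dense profile matrix for clustering
#'
#' k-means requires a complete matrix. Under the default `fill-with-one`
#' policy, a missing cell is set to 1.0 -- the gene's own average level --
#' which is neutral under Euclidean distance on normalized profiles and
#' keeps every gene in the analysis. Under `drop-gene`, genes with any
#' missing age are removed instead.
#'
#' @param nt a `NormalizedTable` from [normalize_per_gene()].
#' @param policy `"fill-with-one"` (default) or `"drop-gene"`.
#' @return list with `matrix` (dense, no `NA`), `gene_ids` (rows retained)
#'   and `dropped` (gene ids removed under `drop-gene`, else empty).
#' @export
impute_for_clustering <- function(nt,
                                  policy = c("fill-with-one", "drop-gene")) {
  stopifnot(inherits(nt, "NormalizedTable"))
  policy <- match.arg(policy)
  m <- nt$values
  if (policy == "fill-with-one") {
    m[is.na(m)] <- 1.0
    dropped <- character(0)
  } else {
    incomplete <- rowSums(is.na(m)) > 0
    dropped <- nt$gene_ids[incomplete]
    m <- m[!incomplete, , drop = FALSE]
  }
  list(matrix = m, gene_ids = rownames(m), dropped = dropped)
}
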
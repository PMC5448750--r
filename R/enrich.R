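#' Build a cluster x category contingency table
#'
#' Counts genes per (cluster, category) cell. Genes whose category is in
#' `exclude` (by default the unannotated ones, which carry no localisation
#' information) are dropped before counting, so the tests run on a single
#' consistent annotated population.
#'
#' @param assignments named integer vector (or data frame with `gene_id`,
#'   `cluster`) of cluster labels per gene.
#' @param categories named character vector (or data frame with `gene_id`,
#'   `category`) of category labels per gene.
#' @param exclude categories to drop (default `"unannotated"`).
#' @return Object of class `ContingencyTable`: list with `observed`
#'   (integer matrix, clusters x categories), `row_totals`, `col_totals`,
#'   `grand_total`, `excluded_genes`.
#' @export
build_contingency <- function(assignments, categories,
                              exclude = "unannotated") {
  if (is.data.frame(assignments))
    assignments <- stats::setNames(assignments$cluster, assignments$gene_id)
  if (is.data.frame(categories))
    categories <- stats::setNames(categories$category, categories$gene_id)
  genes <- names(assignments)
  if (is.null(genes) || is.null(names(categories)))
    stop("assignments and categories must be named by gene id")
  cat_for <- categories[genes]
  if (anyNA(cat_for))
    stop("gene(s) with a cluster but no category: ",
         paste(utils::head(genes[is.na(cat_for)], 10), collapse = ", "))
  drop <- cat_for %in% exclude
  tab <- table(cluster = factor(assignments[!drop]),
               category = factor(cat_for[!drop]))
  obs <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  structure(
    list(observed = obs, row_totals = rowSums(obs),
         col_totals = colSums(obs), grand_total = sum(obs),
         excluded_genes = genes[drop]),
    class = "ContingencyTable")
}

#' Pearson chi-square test of cluster-category independence
#'
#' Expected counts come from the marginal products
#' \eqn{E_{ij} = R_i C_j / N} (the independence model); the statistic is
#' the plain Pearson form \eqn{\sum (O-E)^2/E} with no continuity
#' correction, on \eqn{(r-1)(c-1)} degrees of freedom, with the p-value
#' from the upper tail of the chi-square distribution. When `m > 1` tests
#' share the family-wise level `alpha`, the Bonferroni-adjusted threshold
#' `alpha/m` governs the enrichment conclusion.
#'
#' @param ct a [build_contingency()] table.
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of tests in the family (default 1; pass e.g. the number
#'   of per-category tests to apply the Bonferroni correction).
#' @return Object of class `ChiSquareResult`: list with `statistic`, `df`,
#'   `p_value`, `expected`, `alpha`, `n_tests`, `threshold`
#'   (`alpha/m`), `bonferroni_applied` (`m > 1`), `conclusion`
#'   (`"enriched"` or `"not_enriched"`).
#' @export
chi_square <- function(ct, alpha = 0.05, m = 1L) {
  stopifnot(inherits(ct, "ContingencyTable"))
  O <- ct$observed
  if (nrow(O) < 2 || ncol(O) < 2)
    stop("need at least 2 rows and 2 columns")
  if (ct$grand_total <= 0) stop("empty table")
  if (any(ct$row_totals == 0) || any(ct$col_totals == 0))
    stop("degenerate margin: zero row or column total")
  E <- outer(ct$row_totals, ct$col_totals) / ct$grand_total
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  thr <- bonferroni_threshold(alpha, m)
  structure(
    list(statistic = stat, df = df, p_value = p, expected = E,
         alpha = alpha, n_tests = as.integer(m), threshold = thr,
         bonferroni_applied = m > 1,
         conclusion = if (p <= thr) "enriched" else "not_enriched"),
    class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p %s (threshold %.4g%s): %s\n",
              x$statistic, x$df, format_p(x$p_value), x$threshold,
              if (x$bonferroni_applied)
                sprintf(", Bonferroni m = %d", x$n_tests) else "",
              x$conclusion))
  invisible(x)
}

# banded display used in the human-readable report
format_p <- function(p) {
  bands <- c(1e-4, 1e-3, 5e-3, 1e-2, 5e-2, 1e-1)
  for (b in bands) if (p < b) return(paste("<", format(b)))
  "> 0.1"
}

#' Collapse a contingency table to one category versus the rest
#'
#' Keeps the focus category's column and sums all other columns into a
#' single `rest` column, preserving the cluster rows, for per-category
#' enrichment tests. Genes excluded when the table was built stay
#' excluded, so `rest` means "other annotated categories".
#'
#' @param ct a [build_contingency()] table.
#' @param category one of `colnames(ct$observed)`.
#' @return A `ContingencyTable` with two columns.
#' @export
category_vs_rest <- function(ct, category) {
  stopifnot(inherits(ct, "ContingencyTable"))
  O <- ct$observed
  if (!category %in% colnames(O)) stop("unknown category: ", category)
  if (ncol(O) == 2) return(ct)
  obs <- cbind(O[, category, drop = FALSE],
               rest = rowSums(O[, colnames(O) != category, drop = FALSE]))
  structure(
    list(observed = obs, row_totals = rowSums(obs),
         col_totals = colSums(obs), grand_total = sum(obs),
         excluded_genes = ct$excluded_genes),
    class = "ContingencyTable")
}

#' Bonferroni-adjusted significance threshold
#'
#' Family-wise error control for `m` tests at level `alpha`: each test is
#' judged at `alpha/m`. Returned unrounded; display layers may round
#' (0.05/6 prints as 0.008).
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Observed-over-expected enrichment profile
#'
#' The ratio of each cell count to its independence expectation. A value
#' of 1 means the category is represented in the cluster exactly as its
#' margins predict; above 1 indicates enrichment, below 1 depletion.
#'
#' @param ct a [build_contingency()] table.
#' @return numeric matrix of ratios (clusters x categories); cells with a
#'   zero expectation are `NA` with a warning.
#' @export
observed_over_expected <- function(ct) {
  stopifnot(inherits(ct, "ContingencyTable"))
  E <- outer(ct$row_totals, ct$col_totals) / ct$grand_total
  ratio <- ct$observed / E
  if (any(E == 0)) {
    warning("zero expected count(s); corresponding ratios are NA")
    ratio[E == 0] <- NA_real_
  }
  dimnames(ratio) <- dimnames(ct$observed)
  ratio
}

#' Full enrichment report for one annotation scheme
#'
#' Runs the omnibus chi-square on the full cluster x category table, then
#' one category-versus-rest test per category at the Bonferroni-corrected
#' threshold, and attaches the observed/expected profile.
#'
#' @inheritParams build_contingency
#' @param alpha family-wise level (default 0.05).
#' @return list with `table`, `overall` (`ChiSquareResult`), `per_category`
#'   (named list of `ChiSquareResult`), `obs_exp` (ratio matrix),
#'   `threshold` (the Bonferroni-corrected per-category threshold).
#' @export
enrichment_report <- function(assignments, categories,
                              exclude = "unannotated", alpha = 0.05) {
  ct <- build_contingency(assignments, categories, exclude)
  cats <- colnames(ct$observed)
  overall <- chi_square(ct, alpha, m = 1L)
  per_cat <- lapply(cats, function(cc)
    chi_square(category_vs_rest(ct, cc), alpha, m = length(cats)))
  names(per_cat) <- cats
  list(table = ct, overall = overall, per_category = per_cat,
       obs_exp = observed_over_expected(ct),
       threshold = bonferroni_threshold(alpha, length(cats)))
}
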
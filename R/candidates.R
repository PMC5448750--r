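#' Select clusters of interest from enrichment profiles
#'
#' The screen targets clusters that look like reservoirs of connectivity
#' labels: over-represented for GPI-anchored/single-pass surface proteins
#' and for the axon-guidance/adhesion or synapse functional groups. The
#' default rule selects clusters whose observed/expected ratio exceeds 1
#' for `gpi_or_single_pass` and exceeds 1 for functional group 1 or 2. An
#' explicit label vector overrides the rule.
#'
#' @param loc_profile obs/exp matrix from [observed_over_expected()] over
#'   localisation categories (must contain a `gpi_or_single_pass` column).
#' @param fun_profile obs/exp matrix over functional groups (columns
#'   `"1"`..`"6"`).
#' @param labels optional explicit cluster labels; returned as-is.
#' @return integer vector of selected cluster labels (possibly empty, with
#'   a warning).
#' @export
select_clusters_of_interest <- function(loc_profile, fun_profile,
                                        labels = NULL) {
  if (!is.null(labels)) return(as.integer(labels))
  if (!identical(rownames(loc_profile), rownames(fun_profile)))
    stop("profiles are over different clusters")
  surface <- loc_profile[, "gpi_or_single_pass"] > 1
  guidance <- fun_profile[, "1"] > 1 | fun_profile[, "2"] > 1
  sel <- as.integer(rownames(loc_profile)[surface & guidance])
  if (length(sel) == 0)
    warning("no cluster passes the selection rule; empty funnel")
  sel
}

#' Funnel genes of the selected clusters down to candidates
#'
#' Counts the genes in the clusters of interest, intersects with the
#' extracellular localisation calls (secreted, GPI/single-pass or
#' multi-pass), and removes genes flagged as uniformly expressed in the
#' visual screen. Genes without a flag are kept as `unknown`.
#'
#' @param annotations data frame with columns `gene_id`, `cluster`,
#'   `category` and optionally `differential_flag` (one of `selective`,
#'   `differential`, `uniform`, `unknown`).
#' @param clusters_of_interest integer vector of cluster labels.
#' @return Object of class `FunnelReport`: list with
#'   `clusters_of_interest`, `n_in_clusters`, `n_extracellular`,
#'   `candidates` (data frame of the surviving genes).
#' @export
funnel <- function(annotations, clusters_of_interest) {
  stopifnot(all(c("gene_id", "cluster", "category") %in% names(annotations)))
  unknown <- setdiff(clusters_of_interest, annotations$cluster)
  if (length(unknown) > 0)
    stop("unknown cluster label(s): ", paste(unknown, collapse = ", "))
  if (is.null(annotations$differential_flag))
    annotations$differential_flag <- "unknown"
  annotations$differential_flag[is.na(annotations$differential_flag)] <-
    "unknown"
  inset <- annotations[annotations$cluster %in% clusters_of_interest, ,
                       drop = FALSE]
  extra <- inset[inset$category %in%
                   c("secreted", "gpi_or_single_pass", "multi_pass"), ,
                 drop = FALSE]
  cand <- extra[extra$differential_flag != "uniform", , drop = FALSE]
  structure(
    list(clusters_of_interest = as.integer(clusters_of_interest),
         n_in_clusters = nrow(inset), n_extracellular = nrow(extra),
         candidates = cand),
    class = "FunnelReport")
}

#' @export
print.FunnelReport <- function(x, ...) {
  cat(sprintf(
    "funnel: clusters {%s} -> %d genes -> %d extracellular -> %d candidates\n",
    paste(x$clusters_of_interest, collapse = ","), x$n_in_clusters,
    x$n_extracellular, nrow(x$candidates)))
  invisible(x)
}

#' Apply visual-screen differential-expression flags to a funnel report
#'
#' The visual screen of atlas images classifies each candidate's spatial
#' pattern as `selective`, `differential` or `uniform`; uniformly
#' expressed genes are discarded. The judgement is human and arrives as a
#' flag table; genes not covered keep flag `unknown` and are retained.
#' Idempotent for a fixed flag table.
#'
#' @param report a [funnel()] report.
#' @param flags data frame with `gene_id`, `flag` columns (optionally a
#'   `source` provenance column, carried through).
#' @return The updated `FunnelReport`.
#' @export
apply_differential_flags <- function(report, flags) {
  stopifnot(inherits(report, "FunnelReport"),
            all(c("gene_id", "flag") %in% names(flags)))
  cand <- report$candidates
  hit <- match(cand$gene_id, flags$gene_id)
  cand$differential_flag <- ifelse(is.na(hit), "unknown", flags$flag[hit])
  cand$flag_source <- if (!is.null(flags$source))
    ifelse(is.na(hit), NA_character_, flags$source[hit]) else NA_character_
  report$candidates <- cand[cand$differential_flag != "uniform", ,
                            drop = FALSE]
  report
}

#' Read a candidate gene list (one symbol per line, `#` comments)
#'
#' The package ships the screen's two curated candidate lists under
#' `system.file("extdata", ..., package = "connscreen")`:
#' `candidate_labels_conserved.txt` (orthology strategy) and
#' `candidate_labels_devaba.txt` (expression strategy).
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_candidate_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Combine the two screening strategies' candidate lists
#'
#' The conserved-orthology screen and the expression-profile screen each
#' yield a candidate list; the screen's final catalogue is their union,
#' with genes recovered by both strategies reported separately.
#'
#' @param conserved,expression character vectors of gene symbols.
#' @return list with `union` (sorted unique symbols), `n_union`, `shared`
#'   (genes on both lists), `n_conserved`, `n_expression`.
#' @export
combine_candidate_lists <- function(conserved, expression) {
  conserved <- unique(as.character(conserved))
  expression <- unique(as.character(expression))
  u <- sort(union(conserved, expression))
  list(union = u, n_union = length(u),
       shared = sort(intersect(conserved, expression)),
       n_conserved = length(conserved), n_expression = length(expression))
}
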
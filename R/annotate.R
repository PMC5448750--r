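#' @name annotate
#' @title Consensus protein localisation and functional grouping
#' @description
#' The screen folds the outputs of four sequence-analysis predictors --
#' signal-peptide detection, GPI-modification-site prediction, a
#' compartment classifier and two independent transmembrane-helix counters
#' -- into a single five-way localisation call per gene, with an emphasis
#' on recognising extracellular (secreted or surface) proteins. Functional
#' annotation sorts genes into six priority-ordered groups derived from GO
#' keywords.
NULL

#' Localisation categories
#' @rdname annotate
#' @export
LOC_CATEGORIES <- c("secreted", "gpi_or_single_pass", "multi_pass",
                    "cytoplasmic", "nuclear", "unannotated")

# compartment vocabulary of the classifier
PSORT_COMPARTMENTS <- c("gol", "cyt", "csk", "end", "ext",
                        "mit", "nuc", "per", "pla", "ves")

#' Call consensus localisation from predictor evidence
#'
#' Applies a deterministic decision table, one row per gene:
#' \enumerate{
#'   \item Extracellular evidence: a signal peptide, a predicted
#'     GPI-modification site (quality `P` or `S`), or a compartment call of
#'     `ext` (extracellular) or `pla` (plasma membrane).
#'   \item Both helix counters report >= 2 helices: `multi_pass`.
#'   \item Counters agree on exactly 1 helix, or a GPI site is predicted:
#'     `gpi_or_single_pass`.
#'   \item Extracellular evidence with zero helices from both counters and
#'     no GPI site: `secreted`.
#'   \item No extracellular evidence: `nuclear` if the compartment call is
#'     `nuc`, else `cytoplasmic` (absorbing the organelle compartments).
#'   \item Counters disagree (and are not both >= 2): the call follows the
#'     larger count (1 -> `gpi_or_single_pass`, >= 2 -> `multi_pass`) and
#'     the gene is flagged `needs_curation`. Manual curation of such
#'     disagreements can be reproduced via an override table.
#' }
#'
#' @param evidence data frame with columns `gene_id`, `signal_peptide`
#'   (logical), `gpi_quality` (`"P"`, `"S"` or `"none"`),
#'   `psort_compartment` (one of the ten compartment codes),
#'   `psort_tm_count`, `tmhmm_tm_count` (integers >= 0).
#' @param overrides optional data frame (`gene_id`, `category`) applied
#'   after the decision table, e.g. to reproduce a manually curated table.
#' @return data frame: `gene_id`, `category` (one of [LOC_CATEGORIES]
#'   except `unannotated`, which only arises from overrides),
#'   `extracellular` (`TRUE` iff category is secreted, GPI/single-pass or
#'   multi-pass), `needs_curation`.
#' @export
call_localisation <- function(evidence, overrides = NULL) {
  req <- c("gene_id", "signal_peptide", "gpi_quality", "psort_compartment",
           "psort_tm_count", "tmhmm_tm_count")
  if (!all(req %in% names(evidence)))
    stop("evidence table must have columns: ", paste(req, collapse = ", "))
  bad <- !evidence$psort_compartment %in% PSORT_COMPARTMENTS
  if (any(bad))
    stop("unknown compartment code(s): ",
         paste(unique(evidence$psort_compartment[bad]), collapse = ", "))
  if (any(evidence$psort_tm_count < 0 | evidence$tmhmm_tm_count < 0))
    stop("transmembrane-helix counts must be >= 0")

  gpi <- evidence$gpi_quality %in% c("P", "S")
  extra_ev <- evidence$signal_peptide | gpi |
    evidence$psort_compartment %in% c("ext", "pla")
  tm1 <- evidence$psort_tm_count
  tm2 <- evidence$tmhmm_tm_count

  n <- nrow(evidence)
  category <- character(n)
  needs <- logical(n)
  for (i in seq_len(n)) {
    if (tm1[i] >= 2 && tm2[i] >= 2) {
      category[i] <- "multi_pass"
    } else if ((tm1[i] == 1 && tm2[i] == 1) || gpi[i]) {
      category[i] <- "gpi_or_single_pass"
    } else if (tm1[i] != tm2[i]) {
      needs[i] <- TRUE
      category[i] <- if (max(tm1[i], tm2[i]) == 1)
        "gpi_or_single_pass" else "multi_pass"
    } else if (extra_ev[i] && tm1[i] == 0 && tm2[i] == 0) {
      category[i] <- "secreted"
    } else {
      category[i] <- if (evidence$psort_compartment[i] == "nuc")
        "nuclear" else "cytoplasmic"
    }
  }
  out <- data.frame(gene_id = evidence$gene_id, category = category,
                    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    stopifnot(all(c("gene_id", "category") %in% names(overrides)),
              all(overrides$category %in% LOC_CATEGORIES))
    hit <- match(out$gene_id, overrides$gene_id)
    out$category[!is.na(hit)] <- overrides$category[hit[!is.na(hit)]]
    needs[!is.na(hit)] <- FALSE
  }
  out$extracellular <- out$category %in%
    c("secreted", "gpi_or_single_pass", "multi_pass")
  out$needs_curation <- needs
  out
}

#' Functional groups in priority order
#'
#' Group 1: axon guidance pathway and cell adhesion; 2: synapse;
#' 3: receptor tyrosine kinases, their ligands, and patterning;
#' 4: neurotransmission pathway (GPCRs, ion channels, gap junctions);
#' 5: chromatin and transcription-factor activity; 6: other annotated
#' functions plus unannotated genes.
#' @export
FUNCTION_KEYWORDS <- c("axon_guidance_or_adhesion", "synapse",
                       "rtk_ligand_or_patterning", "neurotransmission",
                       "chromatin_or_tf", "other_annotated")

#' Assign each gene to a single functional group
#'
#' Genes often carry several keywords; the first `TRUE` flag in priority
#' order wins (a receptor tyrosine kinase that is also an axon-guidance
#' gene lands in Group 1, not Group 3). Genes with no flag set fall into
#' Group 6 alongside the miscellaneous annotated ones.
#'
#' @param keywords data frame with column `gene_id` and the six logical
#'   columns of [FUNCTION_KEYWORDS].
#' @return data frame `gene_id`, `group` (integer 1-6).
#' @export
assign_group <- function(keywords) {
  if (!all(c("gene_id", FUNCTION_KEYWORDS) %in% names(keywords)))
    stop("keywords table must have columns: gene_id, ",
         paste(FUNCTION_KEYWORDS, collapse = ", "))
  flags <- as.matrix(keywords[, FUNCTION_KEYWORDS]) > 0
  first <- apply(flags, 1, function(f) which(f)[1])
  first[is.na(first)] <- 6L
  data.frame(gene_id = keywords$gene_id, group = as.integer(first),
             stringsAsFactors = FALSE)
}

#' Tabulate category membership for a gene set
#'
#' @param x character (or integer) vector of per-gene categories or
#'   groups.
#' @param levels the full category vocabulary; defaults to the observed
#'   values. Categories with no members count zero.
#' @return named integer vector of counts, summing to `length(x)`.
#' @export
tabulate_categories <- function(x, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(x))
  counts <- table(factor(x, levels = levels))
  stats::setNames(as.integer(counts), names(counts))
}
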
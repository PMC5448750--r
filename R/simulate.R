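#' Default synthetic-screen specification
#'
#' Study conditions emulating the real screen's scale: 1996 genes over the
#' seven atlas ages, one unimodal expression archetype peaking at each age
#' (equal mixing), multiplicative log-normal noise (`sigma = 0.3`), 1%
#' missing cells, and localisation / functional-group base frequencies
#' equal to the screen's printed marginal counts
#' (907/293/286/267/240/3 and 286/91/360/270/677/312 of 1996).
#'
#' Archetype curves are triangular bumps: density 0.85 at the peak age,
#' 0.30 at adjacent ages, 0.04 elsewhere (clipped to the unit interval
#' after noise), mimicking the "peaks at one age" temporal structure of
#' the clustered atlas profiles.
#'
#' @param n_genes number of genes.
#' @param age_labels developmental stages.
#' @param sigma log-normal noise level (sd of log multiplier).
#' @param missing_rate independent per-cell missingness probability.
#' @param n_archetypes number of planted temporal archetypes (peaks are
#'   spread evenly over the ages).
#' @param enrichment named list of per-archetype odds multipliers, see
#'   [simulate_annotations()].
#' @return list of generator settings (a `SyntheticSpec`).
#' @export
synthetic_spec <- function(n_genes = 1996, age_labels = DEV_AGES,
                           sigma = 0.3, missing_rate = 0.01,
                           n_archetypes = length(age_labels),
                           enrichment = list()) {
  stopifnot(sigma >= 0, missing_rate >= 0, missing_rate < 1,
            n_archetypes >= 1)
  loc_counts <- c(nuclear = 907, secreted = 293, gpi_or_single_pass = 286,
                  cytoplasmic = 267, multi_pass = 240, unannotated = 3)
  grp_counts <- c(`1` = 286, `2` = 91, `3` = 360, `4` = 270, `5` = 677,
                  `6` = 312)
  list(n_genes = as.integer(n_genes), age_labels = age_labels,
       sigma = sigma, missing_rate = missing_rate,
       n_archetypes = as.integer(n_archetypes),
       mixing = rep(1 / n_archetypes, n_archetypes),
       peak_value = 0.85, shoulder_value = 0.30, baseline_value = 0.04,
       loc_freq = loc_counts / sum(loc_counts),
       grp_freq = grp_counts / sum(grp_counts),
       enrichment = enrichment)
}

# triangular archetype curves, one row per archetype
archetype_curves <- function(spec) {
  n_age <- length(spec$age_labels)
  peaks <- round(seq(1, n_age, length.out = spec$n_archetypes))
  t(vapply(peaks, function(p) {
    v <- rep(spec$baseline_value, n_age)
    v[p] <- spec$peak_value
    if (p > 1) v[p - 1] <- spec$shoulder_value
    if (p < n_age) v[p + 1] <- spec$shoulder_value
    v
  }, numeric(n_age)))
}

#' Simulate an expression-density table with planted temporal archetypes
#'
#' Each gene is drawn from one archetype; its density at age t is the
#' archetype curve value times a log-normal factor `exp(sigma * z)`,
#' clipped to the unit interval (densities are pixel fractions). Cells are
#' then dropped independently at `missing_rate`. Byte-identical output for
#' a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return list with `table` (an [expression_table()]) and `archetype`
#'   (named integer vector of true labels, `0`-based).
#' @export
simulate_expression <- function(spec = synthetic_spec(), seed = 1) {
  if (abs(sum(spec$mixing) - 1) > 1e-9)
    stop("archetype mixing proportions must sum to 1")
  set.seed(as.integer(seed))
  n <- spec$n_genes
  n_age <- length(spec$age_labels)
  curves <- archetype_curves(spec)
  arch <- sample.int(spec$n_archetypes, n, replace = TRUE,
                     prob = spec$mixing)
  z <- matrix(stats::rnorm(n * n_age), n, n_age)
  vals <- curves[arch, , drop = FALSE] * exp(spec$sigma * z)
  vals <- pmin(pmax(vals, 0), 1)
  if (spec$missing_rate > 0)
    vals[matrix(stats::runif(n * n_age) < spec$missing_rate, n, n_age)] <-
      NA_real_
  ids <- sprintf("gene%04d", seq_len(n))
  rownames(vals) <- ids
  colnames(vals) <- spec$age_labels
  list(table = expression_table(vals),
       archetype = stats::setNames(arch - 1L, ids))
}

# sample categories with per-archetype odds multipliers on base
# frequencies; factors multiply the category's odds within that archetype
sample_categories <- function(base_freq, arch, enrichment) {
  cats <- names(base_freq)
  out <- character(length(arch))
  for (a in sort(unique(arch))) {
    p <- base_freq
    mult <- enrichment[[as.character(a)]]
    if (!is.null(mult)) {
      if (any(mult <= 0)) stop("enrichment factor must be > 0")
      odds <- p / (1 - p)
      odds[names(mult)] <- odds[names(mult)] * mult
      p <- odds / (1 + odds)
    }
    idx <- which(arch == a)
    out[idx] <- sample(cats, length(idx), replace = TRUE, prob = p / sum(p))
  }
  out
}

#' Simulate predictor evidence and functional keywords for labelled genes
#'
#' Draws a localisation category and a functional group per gene from the
#' spec's base frequencies, optionally tilted per archetype by odds
#' multipliers (`spec$enrichment$loc` / `spec$enrichment$grp`, each a list
#' keyed by 0-based archetype label holding named multiplier vectors).
#' Predictor evidence is then generated consistent with the category, so
#' [call_localisation()] recovers it; keyword flags are generated so
#' [assign_group()] recovers the group. `exact_quota = TRUE` replaces the
#' draw with a deterministic allocation at the base frequencies' exact
#' counts (ignoring enrichment), useful for fixing marginal totals.
#'
#' @param spec a [synthetic_spec()].
#' @param archetype named integer vector of 0-based archetype labels (from
#'   [simulate_expression()]).
#' @param seed integer seed.
#' @param exact_quota allocate categories at exact base-frequency counts.
#' @return list with `evidence` (data frame for [call_localisation()];
#'   unannotated genes carry neutral evidence and are listed in
#'   `unannotated`), `keywords` (data frame for [assign_group()]),
#'   `category` and `group` (the planted truths, named vectors),
#'   `unannotated` (gene ids with no localisation annotation).
#' @export
simulate_annotations <- function(spec = synthetic_spec(), archetype,
                                 seed = 1, exact_quota = FALSE) {
  set.seed(as.integer(seed))
  ids <- names(archetype)
  n <- length(archetype)
  if (exact_quota) {
    quota <- round(spec$loc_freq * n)
    quota[1] <- n - sum(quota[-1])
    category <- rep(names(quota), quota)[sample.int(n)]
    gquota <- round(spec$grp_freq * n)
    gquota[1] <- n - sum(gquota[-1])
    group <- rep(names(gquota), gquota)[sample.int(n)]
  } else {
    category <- sample_categories(spec$loc_freq, archetype,
                                  spec$enrichment$loc)
    group <- sample_categories(spec$grp_freq, archetype,
                               spec$enrichment$grp)
  }
  names(category) <- names(group) <- ids

  sigp <- logical(n)
  gpiq <- rep("none", n)
  comp <- rep("cyt", n)
  tm1 <- integer(n)
  tm2 <- integer(n)
  m <- category == "secreted"
  sigp[m] <- TRUE; comp[m] <- "ext"
  m <- category == "gpi_or_single_pass"
  gpi_flavour <- m & (stats::runif(n) < 0.5)
  gpiq[gpi_flavour] <- sample(c("P", "S"), sum(gpi_flavour),
                              replace = TRUE, prob = c(0.8, 0.2))
  single <- m & !gpi_flavour
  sigp[single] <- TRUE; tm1[single] <- 1L; tm2[single] <- 1L
  comp[m] <- "pla"
  m <- category == "multi_pass"
  tmn <- sample(2:12, sum(m), replace = TRUE)
  tm1[m] <- tmn; tm2[m] <- tmn; comp[m] <- "pla"
  m <- category == "cytoplasmic"
  comp[m] <- sample(c("cyt", "gol", "end", "mit", "per", "ves", "csk"),
                    sum(m), replace = TRUE,
                    prob = c(0.6, 0.08, 0.08, 0.08, 0.04, 0.08, 0.04))
  comp[category == "nuclear"] <- "nuc"
  ev <- data.frame(gene_id = ids, signal_peptide = sigp,
                   gpi_quality = gpiq, psort_compartment = comp,
                   psort_tm_count = tm1, tmhmm_tm_count = tm2,
                   stringsAsFactors = FALSE)

  g <- as.integer(group)
  flags <- matrix(FALSE, n, 6, dimnames = list(NULL, FUNCTION_KEYWORDS))
  for (gg in 1:5) {
    rows <- which(g == gg)
    flags[rows, gg] <- TRUE
    if (gg < 6 && length(rows) > 0) {
      # lower-priority flags may co-occur; priority still decides
      lower <- (gg + 1):6
      flags[rows, lower] <- flags[rows, lower, drop = FALSE] |
        matrix(stats::runif(length(rows) * length(lower)) < 0.15,
               length(rows), length(lower))
    }
  }
  rows6 <- which(g == 6)
  # group 6 mixes miscellaneous annotated genes with unannotated ones
  flags[rows6, "other_annotated"] <-
    stats::runif(length(rows6)) < 107 / 312
  kw <- data.frame(gene_id = ids, flags, stringsAsFactors = FALSE)
  list(evidence = ev, keywords = kw, category = category,
       group = stats::setNames(as.integer(group), ids),
       unannotated = ids[category == "unannotated"])
}

#' Simulate a planted-partition protein-similarity graph
#'
#' Families are planted as dense blocks: within-family node pairs gain an
#' edge with probability `p_intra` (scores uniform on
#' `intra_score`), between-family pairs with probability `p_inter`
#' (scores uniform on `inter_score`). Each family follows an annotation
#' template drawn from `templates` cyclically: taxa are assigned by
#' rotation over the template's taxa so conserved families mix mammalian
#' and invertebrate members.
#'
#' @param n_families number of planted families.
#' @param family_size members per family (scalar or vector).
#' @param p_intra,p_inter edge probabilities, `p_intra > p_inter`.
#' @param templates list of lists with elements `taxa` (character),
#'   `has_tm` (logical), `motifs` (string), `family` (string or `NA`);
#'   default alternates a conserved TM+Ig template, a conserved TM+LRR
#'   template and a mammal-only secreted template.
#' @param intra_score,inter_score score ranges (uniform).
#' @param seed integer seed.
#' @return list with `graph` (a [similarity_graph()]), `nodes` (annotation
#'   data frame for [filter_candidate_clusters()]), `family` (named
#'   integer truth vector).
#' @export
simulate_similarity_graph <- function(n_families = 10, family_size = 8,
                                      p_intra = 0.9, p_inter = 0.02,
                                      templates = NULL,
                                      intra_score = c(60, 300),
                                      inter_score = c(5, 40), seed = 1) {
  if (p_intra <= p_inter) stop("need p_intra > p_inter")
  sizes <- rep_len(family_size, n_families)
  if (any(sizes < 1)) stop("degenerate family size")
  if (is.null(templates))
    templates <- list(
      list(taxa = c("mouse", "human", "fly", "worm"), has_tm = TRUE,
           motifs = "Ig;FN3", family = NA_character_),
      list(taxa = c("mouse", "human", "worm"), has_tm = TRUE,
           motifs = "LRR", family = NA_character_),
      list(taxa = c("mouse", "human"), has_tm = FALSE, motifs = "EGF",
           family = NA_character_))
  set.seed(as.integer(seed))
  fam <- rep(seq_len(n_families), sizes)
  ids <- sprintf("prot%03d", seq_along(fam))
  tmpl <- templates[((seq_len(n_families) - 1) %% length(templates)) + 1]
  nodes <- do.call(rbind, lapply(seq_len(n_families), function(f) {
    tt <- tmpl[[f]]
    members <- ids[fam == f]
    data.frame(id = members,
               taxon = rep_len(tt$taxa, length(members)),
               has_tm = tt$has_tm, motifs = tt$motifs,
               family = tt$family, stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(length(ids), 2)
  same <- fam[pairs[1, ]] == fam[pairs[2, ]]
  u <- stats::runif(ncol(pairs))
  present <- ifelse(same, u < p_intra, u < p_inter)
  w <- numeric(ncol(pairs))
  w[same] <- stats::runif(sum(same), intra_score[1], intra_score[2])
  w[!same] <- stats::runif(sum(!same), inter_score[1], inter_score[2])
  edges <- data.frame(from = ids[pairs[1, present]],
                      to = ids[pairs[2, present]],
                      weight = w[present], stringsAsFactors = FALSE)
  list(graph = similarity_graph(edges, nodes = ids), nodes = nodes,
       family = stats::setNames(fam, ids))
}
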
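ev_row <- function(gene_id = "g", signal_peptide = FALSE,
                   gpi_quality = "none", psort_compartment = "cyt",
                   psort_tm_count = 0L, tmhmm_tm_count = 0L) {
  data.frame(gene_id = gene_id, signal_peptide = signal_peptide,
             gpi_quality = gpi_quality,
             psort_compartment = psort_compartment,
             psort_tm_count = psort_tm_count,
             tmhmm_tm_count = tmhmm_tm_count, stringsAsFactors = FALSE)
}

test_that("the localisation decision table covers the canonical cases", {
  cases <- list(
    list(ev_row(signal_peptide = TRUE, psort_compartment = "ext"),
         "secreted", FALSE),
    list(ev_row(psort_tm_count = 7L, tmhmm_tm_count = 7L,
                psort_compartment = "pla"), "multi_pass", FALSE),
    list(ev_row(psort_compartment = "nuc"), "nuclear", FALSE),
    list(ev_row(psort_compartment = "mit"), "cytoplasmic", FALSE),
    list(ev_row(gpi_quality = "P", psort_compartment = "pla"),
         "gpi_or_single_pass", FALSE),
    list(ev_row(signal_peptide = TRUE, psort_tm_count = 1L,
                tmhmm_tm_count = 1L), "gpi_or_single_pass", FALSE),
    # disagreeing helix counters: larger count decides, flagged
    list(ev_row(signal_peptide = TRUE, psort_tm_count = 1L,
                tmhmm_tm_count = 0L), "gpi_or_single_pass", TRUE),
    list(ev_row(psort_tm_count = 5L, tmhmm_tm_count = 0L),
         "multi_pass", TRUE))
  for (cs in cases) {
    out <- call_localisation(cs[[1]])
    expect_identical(out$category, cs[[2]])
    expect_identical(out$needs_curation, cs[[3]])
    expect_identical(out$extracellular, out$category %in%
                       c("secreted", "gpi_or_single_pass", "multi_pass"))
  }
})

test_that("localisation calls are total, row-order equivariant and overridable", {
  set.seed(51)
  n <- 120
  ev <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    signal_peptide = sample(c(TRUE, FALSE), n, TRUE),
    gpi_quality = sample(c("P", "S", "none"), n, TRUE, c(.1, .05, .85)),
    psort_compartment = sample(c("gol", "cyt", "csk", "end", "ext", "mit",
                                 "nuc", "per", "pla", "ves"), n, TRUE),
    psort_tm_count = sample(0:8, n, TRUE),
    tmhmm_tm_count = sample(0:8, n, TRUE), stringsAsFactors = FALSE)
  out <- call_localisation(ev)
  expect_equal(nrow(out), n)
  expect_true(all(out$category %in% LOC_CATEGORIES))
  perm <- sample(n)
  out_perm <- call_localisation(ev[perm, ])
  expect_equal(out_perm$category, out$category[perm])
  ov <- data.frame(gene_id = "g001", category = "unannotated")
  out_ov <- call_localisation(ev, overrides = ov)
  expect_identical(out_ov$category[1], "unannotated")
  expect_false(out_ov$extracellular[1])
  expect_identical(out_ov$category[-1], out$category[-1])

  bad <- ev_row(psort_compartment = "xyz")
  expect_error(call_localisation(bad), "unknown compartment")
  expect_error(call_localisation(ev_row(psort_tm_count = -1L)), ">= 0")
})

test_that("functional grouping follows the stated priority order", {
  kw <- function(...) {
    row <- data.frame(gene_id = "g", axon_guidance_or_adhesion = FALSE,
                      synapse = FALSE, rtk_ligand_or_patterning = FALSE,
                      neurotransmission = FALSE, chromatin_or_tf = FALSE,
                      other_annotated = FALSE, stringsAsFactors = FALSE)
    flags <- list(...)
    for (f in names(flags)) row[[f]] <- flags[[f]]
    row
  }
  expect_equal(assign_group(kw(axon_guidance_or_adhesion = TRUE,
                               rtk_ligand_or_patterning = TRUE))$group, 1L)
  expect_equal(assign_group(kw(synapse = TRUE))$group, 2L)
  expect_equal(assign_group(kw())$group, 6L)
  expect_equal(assign_group(kw(other_annotated = TRUE))$group, 6L)
  # setting any higher-priority flag never yields a lower-priority group
  set.seed(52)
  for (i in 1:50) {
    flags <- as.list(runif(6) < 0.4)
    names(flags) <- FUNCTION_KEYWORDS
    g0 <- assign_group(do.call(kw, flags))$group
    hi <- sample(seq_len(6), 1)
    flags[[FUNCTION_KEYWORDS[hi]]] <- TRUE
    g1 <- assign_group(do.call(kw, flags))$group
    expect_lte(g1, max(g0, hi))
    expect_lte(g1, g0)
  }
})

test_that("category tabulation counts every gene once", {
  expect_identical(tabulate_categories(character(0),
                                       levels = LOC_CATEGORIES),
                   setNames(integer(6), LOC_CATEGORIES))
  x <- c("a", "b", "a", "c", "a")
  counts <- tabulate_categories(x, levels = c("a", "b", "c", "d"))
  expect_identical(counts, c(a = 3L, b = 1L, c = 1L, d = 0L))
  expect_equal(sum(counts), length(x))
})
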
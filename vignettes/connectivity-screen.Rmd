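---
title: "Screening for candidate neural connectivity labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for candidate neural connectivity labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connscreen)
```

# The screening problem

Brain regions such as the dorsal thalamus are parcellated into dozens of
nuclei with highly selective axonal connectivity. The molecules thought to
encode that selectivity — "connectivity labels" — are surface or secreted
proteins (guidance receptors, adhesion molecules, synaptic organizers)
expressed in discrete spatial and temporal patterns while connections
form. `connscreen` implements two complementary computational strategies
for nominating such molecules genome-wide, each a funnel from thousands of
genes down to a tractable candidate list.

**Strategy 1 (orthology)** starts from all-versus-all protein similarity
scores across the human, mouse, fly and worm proteomes, groups them into
families by Markov clustering, and keeps families that are conserved
between mammals and invertebrates, transmembrane, and carry an
extracellular motif typical of guidance molecules (Ig, FN3, cadherin, LRR,
EGF, CUB, sema, plexin repeat), excluding families whose guidance role is
already established.

**Strategy 2 (expression)** starts from a developmental expression atlas:
per-gene expression densities (the fraction of expressing pixels among the
pixels intersecting the region of interest — a dimensionless quantity in
[0, 1]) at seven ages, E11.5 through P28, spanning patterning, axon
pathfinding, synaptogenesis and plasticity. Genes are clustered by the
shape of their temporal profile, clusters are tested for enrichment of
protein localisation categories and functional groups, and the clusters
that look like reservoirs of guidance molecules are funnelled down to
extracellular, differentially expressed candidates.

The union of the two strategies' curated lists is the screen's final
catalogue; the two lists shipped with the package contain 82 unique genes
with three recovered by both routes.

# Strategy 2 in detail

## Normalization

Densities are divided, gene by gene, by the gene's mean density over its
*present* ages (`normalize_per_gene()`). A value of 1 then marks the
gene's own average level, so Euclidean distances between profiles compare
temporal *shape* rather than absolute expression level. The choice of the
present-value mean is the only definition that preserves the "1 = average"
semantics when some ages are unmeasured. Two degenerate cases are handled
explicitly: genes missing at every age must be removed beforehand
(`filter_all_missing()` — in the atlas-scale data this removes 6 of 2002
genes), and genes whose present values are all zero are excluded from
clustering with a warning, since a flat-zero profile carries no temporal
information.

Missing cells survive normalization as missing. For clustering, which
needs a dense matrix, the default policy (`impute_for_clustering()`) fills
a missing cell with 1.0 — the gene's own average level. Under squared
Euclidean distance on normalized profiles this is the neutral choice: the
filled coordinate pulls the gene toward no particular temporal shape, and
every gene stays in the analysis. The alternative `drop-gene` policy is
available when a complete-case analysis is preferred. The original
atlas analysis did not document its handling of missing ages; the fill
policy is this package's declared surrogate, not a reconstruction.

## k-means and the choice of k

`kmeans_profiles()` is Lloyd's algorithm with Euclidean distance:
initial centroids are k distinct genes sampled at random, and assignment /
re-estimation alternates until the largest centroid shift drops below
`tol = 1e-8` or 300 iterations. Because the initialization is stochastic
and the objective non-convex, the model is fit many times (default 1000
restarts, as in the screen's own analyses) and the restart with minimal
within-cluster sum of squares is kept; results are deterministic given the
seed. An emptied cluster is re-seeded at the point farthest from its
current centroid, which keeps all k clusters non-empty without introducing
randomness. In tests, the implementation is checked against an exhaustive
enumeration of all partitions on a small planted problem and against
`stats::kmeans` (Lloyd variant) from shared initial centroids.

There is no single correct k for temporal profiles. The sweep
(`sweep_k()`, default 6–18) quantifies how partitions change as k grows:
for each adjacent pair, every (k+1)-cluster is mapped to the k-cluster
with which it shares most members (`cluster_correspondence()`), and the
summed maximal overlaps over the gene count give a stability score that
equals 1 exactly when the finer partition only subdivides the coarser one.
Scores near 1 across the sweep indicate a quasi-hierarchical cluster
structure, which justifies analysing a single intermediate k. The
package's default for downstream analysis is k = 10, the value at which
the atlas data separated into clusters peaking at every age while leaving
clusters large enough for contingency tests; it is a configurable default,
not a hard-wired constant. Cluster labels are arbitrary run-specific
integers — downstream logic addresses clusters by explicit label sets or
by chronological rank of the cluster's peak age (`summarize_clusters()`;
peak ties resolve to the earliest age, rank ties to the larger peak mean,
then the lower label).

## Localisation and functional annotation

Localisation evidence comes from four external predictors (run outside
this package): signal-peptide detection, GPI-modification-site prediction,
a ten-compartment classifier, and two independent transmembrane-helix
counters. `call_localisation()` folds them into five categories
(secreted, GPI-anchored/single-pass, multi-pass, cytoplasmic-or-organelle,
nuclear) with a deterministic decision table. Extracellular evidence is
any of: a signal peptide, a predicted GPI site, or a compartment call of
extracellular *or plasma membrane* — the latter included because surface
proteins are precisely the screen's target. Helix-counter agreement at
two-plus means multi-pass; agreement at one, or a GPI site, means
GPI/single-pass; extracellular evidence without helices means secreted;
otherwise the compartment call decides nuclear versus cytoplasmic (the
organelle compartments — Golgi, ER, mitochondria, peroxisome, vesicles,
cytoskeleton — are absorbed into cytoplasmic).

When the two helix counters disagree (and not both report two-plus), no
automated answer is reliable: the package takes the larger count's
category and sets a `needs_curation` flag. This replaces the original
manual curation step with a reproducible rule plus an override table
(gene → category) through which curated judgements can be injected and
audited. The disagreement rule is applied to *all* remaining
disagreements, including genes without extracellular evidence, because a
predicted helix from either program is stronger evidence of membrane
topology than a compartment guess; every such gene is flagged.

Functional annotation is six priority-ordered groups: (1) axon guidance
and cell adhesion, (2) synapse, (3) receptor tyrosine kinases/ligands and
patterning, (4) neurotransmission (GPCRs, channels, gap junctions),
(5) chromatin and transcription-factor activity, (6) other annotated plus
unannotated. A gene carrying several keywords lands in the
highest-priority group (`assign_group()`), so e.g. a guidance-annotated
kinase is Group 1, not Group 3.

## Enrichment statistics

`build_contingency()` crosses cluster labels with categories; for
localisation the unannotated genes (3 of 1996 at atlas scale) are excluded
so all tests run on one consistent annotated population. `chi_square()`
is the plain Pearson statistic with expectations from marginal products,
no continuity correction — the appropriate form for 10 × 5 and 10 × 6
tables with double-digit expected counts — and p-values from the upper
chi-square tail at (r−1)(c−1) degrees of freedom. Per-category tests
collapse the table to category-versus-rest (`category_vs_rest()`; "rest"
keeps the excluded genes excluded) and are judged at the Bonferroni
threshold α/m (`bonferroni_threshold()`): 0.05/5 = 0.01 for the five
localisation categories, 0.05/6 ≈ 0.008 for the six groups. Thresholds
are carried unrounded; only display rounds. Observed/expected ratios
(`observed_over_expected()`) visualise which cells drive a significant
omnibus test. Note that a planted k-fold frequency increase in one
cluster produces an observed/expected ratio *below* k, because the
enrichment inflates the category's margin too; the tests assert the
analytically derived value, not the naive multiplier.

## The candidate funnel

`select_clusters_of_interest()` encodes the screen's focusing rule:
clusters over-represented (obs/exp > 1) for GPI/single-pass surface
proteins *and* for Group 1 or Group 2. `funnel()` counts the genes in
those clusters, intersects with extracellular calls, and removes genes
flagged uniform by the visual inspection of atlas images
(`apply_differential_flags()`). That inspection is human judgement on
section images and is deliberately externalized as a flag file interface —
no surrogate statistic is imposed — so the package reproduces everything
up to and around the visual step, and documents exactly where it enters.

# Strategy 1 in detail

`top_n_edges()` keeps each query's 200 best similarity hits (all ties at
the cutoff retained) and symmetrizes directed score pairs by the maximum.
`mcl()` then simulates flow on the graph: add self-loops (weight = the
node's maximum incident edge weight, which is robust when score ranges are
heterogeneous; configurable), column-normalize, and alternate expansion
(matrix square by default) with inflation (entrywise power r = 2.0,
renormalize) and pruning of entries below 1e-5, to convergence at 1e-6 or
100 iterations. Clusters are the attractor systems of the limit matrix;
a node reachable from several attractors is assigned to the lowest-indexed
one so the output is always a partition, deterministically. Higher
inflation yields finer partitions; this is checked empirically on seeded
graphs rather than asserted as a theorem.

`filter_candidate_clusters()` applies the conservation screen: a passing
cluster needs a mammalian member, an invertebrate member, a mammalian
member that is transmembrane with a whitelisted motif, and no member of a
blacklisted family. The TM+motif requirement sits on a mammalian member
because the screen seeks mammalian candidates; a strict variant demanding
the invertebrate member also carry it is available behind a flag, since
either reading of the original criterion is defensible. Per-cluster
pass/fail reasons are returned for auditability.

# The synthetic-data generator

All pipeline stages are testable offline because `simulate_expression()`,
`simulate_annotations()` and `simulate_similarity_graph()` generate every
input with planted ground truth. The defaults are the study conditions:
1996 genes, seven ages, and category frequencies equal to the screen's
printed marginals (localisation 907/293/286/267/240/3; groups
286/91/360/270/677/312).

Expression profiles are unimodal triangular archetypes — density 0.85 at
the peak age, 0.30 at adjacent ages, 0.04 elsewhere, one archetype peaking
at each age, equal mixing — multiplied by log-normal noise
(σ = 0.3) and clipped to [0, 1], with cells dropped independently at 1%.
The triangular-bump-plus-multiplicative-noise model preserves
nonnegativity and the peaks-at-one-age structure seen in the real
clustered profiles; σ = 0.3 gives visibly noisy but recoverable archetypes
(adjusted Rand index ≳ 0.95 after normalization and k-means). Annotation
categories are drawn at base frequencies, optionally tilted per archetype
by odds multipliers to plant enrichment; predictor evidence is then
generated *consistent with* the drawn category, so the decision table
recovers it exactly — a round-trip property the tests rely on. The
similarity generator plants a partition (within-family edge probability
0.9, between 0.02, disjoint score ranges) with per-family annotation
templates cycling through conserved-TM-Ig, conserved-TM-LRR and
mammal-only-secreted.

What the generator does *not* emulate: correlated missingness (atlas
gaps cluster by age and experiment), skewed cluster sizes, overdispersed
or gene-correlated noise, ambiguous predictor evidence (evidence is
category-consistent by construction, so the `needs_curation` path is
exercised only by hand-built tests), and any spatial structure. Passing
tests therefore demonstrate correctness of the machinery under a clean
generative model, not robustness to every pathology of real atlas data.

# Numerical and testing choices

* k-means: `tol = 1e-8` on centroid shift, 300 iterations per restart,
  1000 restarts by default (tests use 10–100 on small problems);
  assignment ties go to the lowest centroid index.
* Chi-square: double precision throughout; banded p display (`< 0.001`
  style) only in printed output, full precision in JSON.
* MCL: prune 1e-5, tol 1e-6, max 100 iterations; non-convergence returns
  the current partition with a warning rather than failing.
* Statistical properties are tested at the study scale with fixed seeds:
  type-I calibration of the omnibus test over 1000 null tables
  (band 0.05 ± 0.02), ≥ 90% Bonferroni-corrected power for a 3× planted
  surface-protein enrichment over 100 replicates, archetype recovery at
  σ = 0.3 over 5 seeds, exact planted-family recovery for MCL over 5
  seeds. The whole suite runs in well under a minute on one CPU.

# Reproducing the published statistics

The package reproduces the screen's published *marginal* quantities
(gene counts, category totals, Bonferroni thresholds, the 82-gene
candidate union) from first principles. The published omnibus and
per-category chi-square values and the 896 → 426 funnel additionally
depend on the per-gene joint assignment of cluster, localisation and
group, which lives in the original supplementary workbooks and is not
reconstructible from marginals. Users with access to those workbooks can
export a four-column table (`gene_id`, `cluster`, `category`, `group`,
tab-separated) to
`inst/extdata/published_assignments_k10.tsv`; the acceptance tests then
verify the printed statistics — including the reconciliation of whether
the three unannotatable genes sit in the "rest" population — without any
code change. Re-running k-means does not reproduce the published
memberships exactly, because the original cluster assignment is
stochastic-initialization-dependent; this is why the enrichment
reproduction consumes published assignments rather than re-clustering.

# Limitations

* The visual-screen step (selective/differential/uniform) is an interface,
  not an algorithm; the package cannot regenerate the curated candidate
  subsets that depend on it.
* MCL is dense-matrix; graphs beyond a few thousand nodes will want a
  sparse implementation.
* The localisation decision table is a reconstruction of a partly manual
  procedure; the override table is the escape hatch for exact
  reproduction.
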
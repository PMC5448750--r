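test_that("top-n edge selection keeps ranks, ties and max-symmetrizes", {
  hits <- data.frame(query = c("a", "a", "a", "b"),
                     hit = c("b", "c", "d", "a"),
                     score = c(5, 3, 2, 7))
  g <- top_n_edges(hits, n = 200)          # fewer hits than n: all kept
  expect_equal(nrow(g$edges), 3)
  ab <- g$edges[g$edges$from == "a" & g$edges$to == "b", ]
  expect_equal(ab$weight, 7)               # max of the directed 5 / 7

  set.seed(71)
  many <- data.frame(query = "q", hit = sprintf("h%03d", 1:300),
                     score = sample(1:300))   # distinct: exactly n survive
  g2 <- top_n_edges(many, n = 10)
  kept <- g2$edges$weight
  expect_equal(length(kept), 10)
  expect_setequal(kept, 291:300)

  tied <- data.frame(query = "q", hit = sprintf("h%d", 1:5),
                     score = c(9, 8, 7, 7, 7))
  g3 <- top_n_edges(tied, n = 4)           # ties at rank n all kept
  expect_equal(nrow(g3$edges), 5)

  expect_error(top_n_edges(data.frame(query = "a", hit = "b", score = -1)),
               "negative")
  expect_error(similarity_graph(data.frame(from = "a", to = "a",
                                           weight = 1)), "self-edges")
})

test_that("MCL separates weakly bridged dense groups like the direct iteration", {
  ed <- data.frame(from = c("a", "a", "b", "d", "d", "e", "c"),
                   to = c("b", "c", "c", "e", "f", "f", "d"),
                   weight = 1)
  g <- similarity_graph(ed)
  cs <- mcl(g, inflation = 2.0)
  expect_length(cs$clusters, 2)
  expect_setequal(cs$clusters[[1]], c("a", "b", "c"))
  expect_setequal(cs$clusters[[2]], c("d", "e", "f"))
  # independent dense iteration of the same flow map
  ids <- g$nodes
  adj <- matrix(0, 6, 6, dimnames = list(ids, ids))
  adj[cbind(ed$from, ed$to)] <- 1
  adj <- pmax(adj, t(adj))
  oracle <- mcl_oracle_partition(adj)
  expect_equal(ari(cs$membership, oracle), 1)
})

test_that("MCL output is always a partition; disconnected parts never merge", {
  single <- similarity_graph(data.frame(from = character(0),
                                        to = character(0),
                                        weight = numeric(0)),
                             nodes = "lonely")
  expect_equal(mcl(single)$clusters, list("lonely"))
  set.seed(72)
  for (rep in 1:5) {
    sim <- simulate_similarity_graph(n_families = 4, family_size = 6,
                                     p_intra = 0.85, p_inter = 0,
                                     seed = 100 + rep)
    cs <- mcl(sim$graph)
    members <- sort(unlist(cs$clusters))
    expect_identical(members, sort(sim$graph$nodes))  # disjoint cover
    # clusters never span two planted (disconnected) families
    for (cl in cs$clusters)
      expect_length(unique(sim$family[cl]), 1)
  }
})

test_that("column stochasticity holds and stronger inflation never coarsens", {
  sim <- simulate_similarity_graph(n_families = 5, family_size = 6,
                                   p_intra = 0.9, p_inter = 0.05, seed = 73)
  n_low <- length(mcl(sim$graph, inflation = 1.6)$clusters)
  n_mid <- length(mcl(sim$graph, inflation = 2.0)$clusters)
  n_high <- length(mcl(sim$graph, inflation = 4.0)$clusters)
  expect_lte(n_low, n_mid)
  expect_lte(n_mid, n_high)
})

test_that("conserved TM/motif filter applies all four criteria with reasons", {
  nodes <- data.frame(
    id = c("m1", "f1", "m2", "m3", "w1", "m4", "h1", "w2"),
    taxon = c("mouse", "fly", "mouse", "mouse", "worm", "mouse", "human",
              "worm"),
    has_tm = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    motifs = c("Ig", "Ig", "Ig;FN3", "LRR", "LRR", "EGF", "EGF", "kinase"),
    family = c(NA, NA, NA, "Eph-receptor", "Eph-receptor", NA, NA, NA),
    stringsAsFactors = FALSE)
  cs <- structure(list(clusters = list(c("m1", "f1"), "m2",
                                       c("m3", "w1"), c("m4", "h1", "w2")),
                       membership = NULL, iterations = 0, converged = TRUE),
                  class = "ClusterSet")
  out <- filter_candidate_clusters(cs, nodes)
  expect_true(out$passes[1])                       # mouse TM+Ig with fly
  expect_false(out$passes[2])
  expect_match(out$reason[2], "no invertebrate")
  expect_false(out$passes[3])
  expect_match(out$reason[3], "blacklisted family: Eph-receptor")
  expect_false(out$passes[4])                      # no mammalian TM+motif
  expect_match(out$reason[4], "no mammalian TM")
  # strict variant also requires the invertebrate member to carry TM+motif
  nodes2 <- nodes; nodes2$motifs[nodes2$id == "f1"] <- "kinase"
  strict <- filter_candidate_clusters(cs, nodes2, strict = TRUE)
  expect_false(strict$passes[1])
  expect_match(strict$reason[1], "no invertebrate TM")
  cs_bad <- structure(list(clusters = list("nope")), class = "ClusterSet")
  expect_error(filter_candidate_clusters(cs_bad, nodes), "unannotated")
})
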
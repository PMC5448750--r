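test_that("separable clouds are recovered and degenerate k behaves", {
  set.seed(31)
  m <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 10, 0.1), 20))
  rownames(m) <- sprintf("p%d", 1:40)
  for (seed in c(1, 99, 1234)) {
    cm <- kmeans_profiles(m, 2, restarts = 5, seed = seed)
    expect_length(unique(cm$assignments[1:20]), 1)
    expect_length(unique(cm$assignments[21:40]), 1)
    expect_false(cm$assignments[1] == cm$assignments[21])
  }
  singletons <- kmeans_profiles(m[1:6, ], 6, restarts = 3, seed = 1)
  expect_equal(singletons$inertia, 0)
  expect_length(unique(singletons$assignments), 6)
  expect_error(kmeans_profiles(m, 50), "k must be")
  m2 <- m; m2[1] <- NA
  expect_error(kmeans_profiles(m2, 2), "non-finite")
})

test_that("restarted Lloyd attains the exhaustive optimum on 3 planted triads", {
  set.seed(32)
  centers <- matrix(c(0, 0, 8, 0, 4, 7), 3, 2, byrow = TRUE)
  x <- centers[rep(1:3, each = 4), ] + matrix(rnorm(24, 0, 0.4), 12, 2)
  best <- brute_force_inertia(x, 3)
  cm <- kmeans_profiles(x, 3, restarts = 50, seed = 7)
  expect_equal(cm$inertia, best, tolerance = 1e-10)
})

test_that("inertia is recomputable and best-of-restarts at least as good as one restart", {
  set.seed(33)
  m <- matrix(rnorm(300), 60, 5)
  multi <- kmeans_profiles(m, 4, restarts = 40, seed = 2)
  recomputed <- sum(vapply(seq_len(nrow(m)), function(i)
    sum((m[i, ] - multi$centroids[multi$assignments[i] + 1, ])^2),
    numeric(1)))
  expect_equal(multi$inertia, recomputed, tolerance = 1e-10)
  single <- kmeans_profiles(m, 4, restarts = 1, seed = 2)
  expect_lte(multi$inertia, single$inertia + 1e-12)
})

test_that("shared initial centroids reproduce the reference implementation", {
  set.seed(34)
  for (rep in 1:5) {
    m <- matrix(rnorm(60 * 4), 60, 4)
    init <- m[sample(60, 3), ]
    ours <- kmeans_profiles(m, 3, init = init)
    ref <- suppressWarnings(
      stats::kmeans(m, centers = init, algorithm = "Lloyd", iter.max = 300))
    expect_equal(ari(ours$assignments, ref$cluster), 1)
    expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
  }
})

test_that("correspondence scores refinement as 1 and reshuffling below 1", {
  a <- c(g1 = 0, g2 = 0, g3 = 0, g4 = 0, g5 = 0, g6 = 0)
  expect_equal(cluster_correspondence(a, a)$stability, 1)
  split <- c(g1 = 0, g2 = 0, g3 = 0, g4 = 1, g5 = 1, g6 = 1)
  cc <- cluster_correspondence(a, split)
  expect_equal(cc$stability, 1)
  expect_equal(unname(cc$parent), c(0L, 0L))
  a2 <- c(g1 = 0, g2 = 0, g3 = 1, g4 = 1)
  b2 <- c(g1 = 0, g2 = 1, g3 = 0, g4 = 1)
  expect_equal(cluster_correspondence(a2, b2)$stability, 0.5)
  # reshuffling half the labels drops stability below 1
  set.seed(35)
  base <- setNames(rep(0:3, each = 25), sprintf("g%d", 1:100))
  shuf <- base
  idx <- sample(100, 50)
  shuf[idx] <- sample(0:3, 50, replace = TRUE)
  expect_lt(cluster_correspondence(base, shuf)$stability, 1)
  expect_error(cluster_correspondence(a2, b2[1:3]), "different gene sets")
})

test_that("parent-map ties break toward the lower parent label", {
  a <- c(g1 = 0, g2 = 1, g3 = 2, g4 = 2)
  b <- c(g1 = 0, g2 = 0, g3 = 1, g4 = 1)
  cc <- cluster_correspondence(a, b)
  expect_equal(unname(cc$parent[1]), 0L)  # overlap tie {0,1} -> 0
})

test_that("k sweep records per-pair stability and recovers planted structure", {
  spec <- synthetic_spec(n_genes = 240, sigma = 0, missing_rate = 0,
                         n_archetypes = 4)
  sim <- simulate_expression(spec, seed = 41)
  dm <- impute_for_clustering(normalize_per_gene(sim$table))
  sw <- sweep_k(dm$matrix, 2, 6, restarts = 10, seed = 4)
  expect_named(sw$models, as.character(2:6))
  expect_length(sw$transitions, 4)
  stab45 <- sw$transitions[[3]]
  expect_equal(stab45$from, 4)
  expect_true(stab45$stability > 0 && stab45$stability <= 1)
  expect_equal(ari(sw$models[["4"]]$assignments, sim$archetype), 1)
})

test_that("cluster summaries average per age and order chronologically", {
  nt <- normalize_per_gene(toy_expression(rbind(c(0, 2), c(2, 0)),
                                          ages = c("E11.5", "P28")))
  cm <- structure(list(k = 1L, assignments = c(g1 = 0L, g2 = 0L)),
                  class = "ClusterModel")
  s <- summarize_clusters(nt, cm)
  expect_equal(unname(s$profiles[1, ]), c(1, 1))
  expect_identical(s$peak_age, "E11.5")  # tie -> earliest age

  spec <- synthetic_spec(n_genes = 350, sigma = 0, missing_rate = 0)
  sim <- simulate_expression(spec, seed = 42)
  nt7 <- normalize_per_gene(sim$table)
  cm7 <- structure(list(k = 7L, assignments = sim$archetype),
                   class = "ClusterModel")
  s7 <- summarize_clusters(nt7, cm7)
  expect_setequal(s7$peak_age, DEV_AGES)       # one peak per stage
  expect_setequal(s7$chron_rank, 0:6)
  expect_equal(order(s7$peak_index)[1], which(s7$chron_rank == 0))

  # a one-gene cluster's summary is that gene's own profile
  cm2 <- structure(list(k = 2L, assignments = c(g1 = 0L, g2 = 1L)),
                   class = "ClusterModel")
  s2 <- summarize_clusters(nt, cm2)
  expect_equal(unname(s2$profiles[2, ]), unname(nt$values["g2", ]))
  cm_bad <- structure(list(k = 3L, assignments = c(g1 = 0L, g2 = 1L)),
                      class = "ClusterModel")
  expect_error(summarize_clusters(nt, cm_bad), "empty cluster")
})
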
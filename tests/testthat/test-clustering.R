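test_that("Tanimoto similarity is 1 for duplicates and 0 for disjoint environments", {
  fps <- morgan_fingerprints(c(dup1 = "c1ccccc1N2CCNCC2",
                               dup2 = "c1ccccc1N2CCNCC2",
                               ethane = "CC",
                               benzene = "c1ccccc1"))
  sim <- tanimoto_matrix(fps)
  expect_equal(sim["dup1", "dup2"], 1.0)
  # saturated vs aromatic carbons share no circular environment
  expect_equal(sim["ethane", "benzene"], 0.0)
  expect_true(all(diag(sim) == 1))
  expect_equal(sim, t(sim))
  expect_true(all(sim >= 0 & sim <= 1))
})

test_that("similarities are invariant to compound input order", {
  smiles <- demo_molecule_set()[1:6]
  s1 <- tanimoto_matrix(morgan_fingerprints(smiles))
  perm <- c(4, 2, 6, 1, 3, 5)
  s2 <- tanimoto_matrix(morgan_fingerprints(smiles[perm]))
  expect_equal(s1[names(smiles)[perm], names(smiles)[perm]], s2,
               tolerance = 1e-12)
})

test_that("normalized cut separates two tight blobs and collapses trivial cases", {
  ids <- sprintf("m%d", 1:6)
  D <- matrix(0.9, 6, 6, dimnames = list(ids, ids))
  D[1:3, 1:3] <- 0.05; D[4:6, 4:6] <- 0.05
  diag(D) <- 0
  ca <- cluster_cut(D, 0.5)
  expect_equal(ca$n_clusters, 2L)
  expect_true(same_partition(ca$labels, c(1, 1, 1, 2, 2, 2)))

  expect_equal(cluster_cut(D, 1.0)$n_clusters, 1L)

  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(cluster_cut(Z, 0.3)$n_clusters, 1L)
  expect_error(cluster_cut(D[, 1:3], 0.5), "square")
  expect_error(cluster_cut(D, 0), "threshold")
})

test_that("cluster count never increases with the threshold", {
  set.seed(9)
  n <- 10
  D <- as.matrix(dist(matrix(runif(n * 2), n)))
  dimnames(D) <- list(sprintf("c%d", 1:n), sprintf("c%d", 1:n))
  ks <- vapply(seq(0.1, 1, by = 0.1),
               function(th) cluster_cut(D, th)$n_clusters, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("average-linkage cut equals a naive agglomerative oracle", {
  set.seed(17)
  for (i in 1:8) {
    n <- sample(4:12, 1)
    D <- as.matrix(dist(matrix(runif(n * 3), n)))
    dimnames(D) <- list(sprintf("c%d", 1:n), sprintf("c%d", 1:n))
    th <- runif(1, 0.2, 0.95)
    ca <- cluster_cut(D, th)
    o <- oracle_average_linkage(D, cut = ca$cut_height)
    expect_true(same_partition(unname(ca$labels), o$labels))
    full <- oracle_average_linkage(D)
    expect_equal(sort(ca$tree$height), sort(full$heights), tolerance = 1e-9)
  }
})

test_that("representatives come from large clusters, ranked by binding energy", {
  labels <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L)
  ca <- structure(list(labels = labels, tree = NULL, threshold = 0.5,
                       cut_height = 0.5, n_clusters = 2L),
                  class = "cluster_assignment")
  e <- energy_table(letters[1:5], c(-52, -47, -40, -60, -55), rep(-1, 5))
  hits <- select_representatives(ca, e, min_cluster_size = 3)
  expect_identical(hits$id, "a")

  hits2 <- select_representatives(ca, e, min_cluster_size = 2,
                                  reps_per_cluster = list("1" = 3, default = 1))
  expect_identical(hits2$id, c("a", "b", "c", "d"))

  expect_error(select_representatives(ca, e[1:3, ], min_cluster_size = 2), "missing")
})

test_that("phospholipid consistency check flags energy signs and shifts", {
  e <- energy_table(c("zinc", "lapatinib", "odd"),
                    c(-22.42, -45.73, 1.0),
                    c(-39.93, -19.26, -1.0))
  hits <- data.frame(id = c("zinc", "lapatinib", "odd"))
  chk <- consistency_check(hits, e)
  expect_true(chk$favorable_without[1] && chk$favorable_with[1])
  expect_false(chk$weaker_with_lipids[1])
  expect_true(chk$favorable_without[2] && chk$favorable_with[2])
  expect_true(chk$weaker_with_lipids[2])
  expect_false(chk$favorable_without[3])
})

test_that("the diversity tree exports as Newick text", {
  fps <- morgan_fingerprints(demo_molecule_set()[1:5])
  ca <- cluster_cut(1 - tanimoto_matrix(fps), 0.75)
  nwk <- hclust_to_newick(ca$tree)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "arylpip1")
})
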
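# Cover-quality metrics: closed forms, reductions, and independent oracles.

test_that("disjoint NMI matches its closed forms", {
  a <- list(c("1", "2"), c("3", "4"))
  expect_equal(nmi_disjoint(a, a), 1.0)
  one <- list(as.character(1:4))
  expect_equal(nmi_disjoint(one, a), 0.0)
  b <- list(c("1", "3"), c("2", "4"))
  expect_equal(nmi_disjoint(a, b), 0.0)     # confusion matrix is uniform
  expect_equal(nmi_disjoint(a, b), nmi_disjoint(b, a))
  expect_equal(nmi_disjoint(one, one), 1.0) # identical trivial partitions
})

test_that("disjoint NMI and modularity errors guard their preconditions", {
  a <- list(c("1", "2"), c("3", "4"))
  expect_error(nmi_disjoint(a, list(c("1", "2"), c("3", "5"))), "universe")
  ov <- list(c("1", "2", "3"), c("3", "4"))
  expect_error(nmi_disjoint(ov, ov), "disjoint")
  net <- elpa_network(edge_mat(1, 2, 2, 3, 3, 4, 4, 1))
  expect_error(modularity_gn(net, ov), "overlap")
  expect_error(modularity_overlapping(net, list(c("1", "2"))), "no community")
})

test_that("disjoint NMI agrees with the igraph oracle on random partitions", {
  set.seed(31)
  for (rep in 1:50) {
    net <- random_graph(sample(6:14, 1L))
    n <- net$n                                 # isolated vertices are dropped
    k1 <- sample(2:min(4L, n - 1L), 1L); k2 <- sample(2:min(4L, n - 1L), 1L)
    m1 <- c(seq_len(k1), sample(seq_len(k1), n - k1, replace = TRUE))
    m2 <- c(seq_len(k2), sample(seq_len(k2), n - k2, replace = TRUE))
    a <- split(net$vertices, m1)
    b <- split(net$vertices, m2)
    ours <- nmi_disjoint(a, b)
    ref <- igraph::compare(m1, m2, method = "nmi")
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("overlapping NMI behaves like a similarity on covers", {
  a <- list(c("1", "2", "3"), c("3", "4", "5", "6"))
  expect_equal(nmi_overlapping(a, a), 1.0)
  d <- list(c("1", "2"), c("3", "4"))
  expect_equal(nmi_overlapping(d, d), 1.0)
  b <- list(c("1", "2", "4"), c("3", "5", "6"))
  v <- nmi_overlapping(a, b)
  expect_true(v >= 0 && v < 1)
  expect_equal(v, nmi_overlapping(b, a))
})

test_that("overlapping NMI matches a direct entropy-evaluation oracle", {
  toys <- list(
    list(a = list(c("1", "2", "3"), c("4", "5", "6")),
         b = list(c("1", "2"), c("3", "4", "5", "6"))),
    list(a = list(c("1", "2", "3", "4"), c("3", "4", "5", "6")),
         b = list(c("1", "2", "3"), c("4", "5", "6"))),
    list(a = list(c("1", "2", "5"), c("2", "3", "4"), c("4", "5", "6")),
         b = list(c("1", "2", "3"), c("3", "4", "5", "6"))))
  for (t in toys) {
    expect_equal(nmi_overlapping(t$a, t$b), lfk_nmi_ref(t$a, t$b),
                 tolerance = 1e-12)
  }
  # seeded random covers
  set.seed(77)
  for (rep in 1:20) {
    u <- as.character(1:8)
    a <- lapply(1:3, function(i) sample(u, sample(2:5, 1L)))
    b <- lapply(1:2, function(i) sample(u, sample(2:6, 1L)))
    expect_equal(nmi_overlapping(a, b), lfk_nmi_ref(a, b), tolerance = 1e-12)
  }
})

test_that("modularity matches closed forms and the igraph oracle", {
  twok3 <- elpa_network(rbind(complete_graph(1:3), complete_graph(4:6)))
  expect_equal(modularity_gn(twok3, list(as.character(1:3), as.character(4:6))),
               0.5)
  expect_equal(modularity_gn(twok3, list(as.character(1:6))), 0.0)

  karate <- load_fixture("karate")
  split2 <- karate_truth()
  ours <- modularity_gn(karate, split2)
  g <- as_igraph(karate)
  ref <- igraph::modularity(g, membership_of(karate, split2))
  expect_equal(ours, ref, tolerance = 1e-9)

  set.seed(53)
  for (rep in 1:15) {
    net <- random_graph(sample(6:12, 1L))
    k <- sample(2:4, 1L)
    mm <- sample(seq_len(k), net$n, replace = TRUE)
    cov <- split(net$vertices, mm)
    expect_equal(modularity_gn(net, cov),
                 igraph::modularity(as_igraph(net), mm), tolerance = 1e-9)
  }
})

test_that("overlap modularity reduces to G&N on disjoint covers", {
  set.seed(59)
  for (rep in 1:50) {
    net <- random_graph(sample(5:12, 1L))
    k <- sample(2:4, 1L)
    cov <- split(net$vertices, sample(seq_len(k), net$n, replace = TRUE))
    expect_equal(modularity_overlapping(net, cov), modularity_gn(net, cov),
                 tolerance = 1e-12)
  }
})

test_that("overlap modularity matches a hand-computed overlapping toy", {
  # two triangles sharing vertex c; c belongs to both communities
  net <- elpa_network(edge_mat("a", "b", "a", "c", "b", "c",
                               "c", "d", "c", "e", "d", "e"))
  cov <- list(c("a", "b", "c"), c("c", "d", "e"))
  # per community: W = 1 + 1/2 + 1/2 = 2, D = 2 + 2 + 4/2 = 6, m = 6
  # Q = 2 * (2/6 - (6/12)^2) = 1/6
  expect_equal(modularity_overlapping(net, cov), 1 / 6, tolerance = 1e-12)
  # a single community always scores 0
  expect_equal(modularity_overlapping(net, list(net$vertices)), 0.0)
})

test_that("partition density hits its closed forms", {
  # every community a clique spanning its vertices -> 1
  twok3 <- elpa_network(rbind(complete_graph(1:3), complete_graph(4:6)))
  lc <- list(complete_graph(1:3), complete_graph(4:6))
  expect_equal(partition_density(twok3, lc), 1.0)
  k4 <- elpa_network(complete_graph(1:4))
  expect_equal(partition_density(k4, list(complete_graph(1:4))), 1.0)

  # every community a tree -> 0
  tree <- elpa_network(path_graph(1:6))
  expect_equal(partition_density(tree, list(path_graph(1:3),
                                            path_graph(3:6))), 0.0)

  # mixed: K4 (6 edges) + a 3-edge path, M = 9:
  # D = (2/9) * (6*(6-3)/((4-2)(4-1)) + 0) = 2/3
  mixed <- elpa_network(rbind(complete_graph(1:4), path_graph(4:7)))
  expect_equal(partition_density(mixed, list(complete_graph(1:4),
                                             path_graph(4:7))), 2 / 3)

  # a two-vertex community contributes zero, not NaN
  pair <- elpa_network(rbind(complete_graph(1:3), edge_mat(4, 5, 3, 4)))
  d <- partition_density(pair, list(complete_graph(1:3), edge_mat(4, 5, 3, 4)))
  expect_true(is.finite(d))

  expect_error(partition_density(twok3, list(complete_graph(1:3))),
               "partition")
})

test_that("metrics are invariant under vertex and community relabeling", {
  set.seed(61)
  net <- random_graph(8)
  cov <- split(net$vertices, sample(1:3, net$n, replace = TRUE))
  q0 <- modularity_gn(net, cov)
  n0 <- nmi_overlapping(cov, cov[c(2, 3, 1)])
  # permute community order
  expect_equal(modularity_gn(net, cov[sample(length(cov))]), q0)
  expect_equal(n0, 1.0)
  # relabel vertices consistently in network and cover
  perm <- setNames(sample(net$vertices), net$vertices)
  net2 <- elpa_network(matrix(perm[net$vertices[net$edges]], ncol = 2L))
  cov2 <- lapply(cov, function(g) unname(perm[g]))
  expect_equal(modularity_gn(net2, cov2), q0, tolerance = 1e-12)
})

test_that("cover files round-trip", {
  cov <- list(c("1", "2", "3"), c("4", "5"))
  f <- withr::local_tempfile()
  write_cover(cov, f)
  expect_equal(read_cover(f), cov)
  expect_error(read_cover(tempfile()), "no such file")
})
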
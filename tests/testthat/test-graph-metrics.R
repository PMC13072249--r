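# Closed-form fixture values (K5, P4, S5, RC5) were derived by hand and
# cross-checked against the brute-force oracles in helper-oracles.R.

test_that("binarization and shared-support pairs agree", {
  expect_equal(binarize(K5(3.7)), K5(1))
  expect_equal(binarize(matrix(0, 4, 4)), matrix(0, 4, 4))
  gc_ <- generate_cohort(generator_config(n_patients = 1, n_nodes = 25,
                                          lesion_size = 3, seed = 2))
  pr <- gc_$cohort$matrices[[1]]
  expect_identical(binarize(pr$tract_count), binarize(pr$qa))
  expect_identical(node_degree(pr$tract_count), node_degree(pr$qa))
})

test_that("shortest paths: hops, inverse-weight lengths, unreachable pairs", {
  expect_equal(shortest_paths_matrix(P4(), "binary")[1, 4], 3)
  expect_equal(shortest_paths_matrix(P4(2), "weighted")[1, 4], 1.5)
  two_edges <- adj_from_edges(4, rbind(c(1, 2), c(3, 4)))
  D <- shortest_paths_matrix(two_edges, "binary")
  expect_true(is.infinite(D[1, 3]))
  expect_equal(D[1, 2], 1)
})

test_that("density matches edge counting", {
  expect_equal(graph_density(K5()), 1.0)
  expect_equal(graph_density(matrix(0, 5, 5)), 0.0)
  expect_equal(graph_density(P4()), 0.5)
  expect_error(graph_density(matrix(0, 1, 1)), "2 nodes")
})

test_that("clustering coefficients match triangle enumeration", {
  expect_equal(clustering_coefficients(K5(), "binary"), rep(1, 5))
  expect_equal(average_clustering(K5(), "binary"), 1)
  expect_equal(clustering_coefficients(S5(), "binary"), rep(0, 5))
  expect_equal(clustering_coefficients(RC5(), "binary"), c(0.5, 1, 1, 1, 0))
  expect_equal(average_clustering(RC5(), "binary"), 0.7)
})

test_that("transitivity counts triangles over connected triples", {
  expect_equal(graph_transitivity(K5(), "binary"), 1)
  expect_equal(graph_transitivity(S5(), "binary"), 0)
  # RC5: 4 triangles, 15 connected triples -> 12/15 (oracle-confirmed)
  expect_equal(graph_transitivity(RC5(), "binary"), 0.8)
  expect_equal(graph_transitivity(RC5(), "binary"), bf_transitivity(RC5()))
  expect_true(is.na(graph_transitivity(adj_from_edges(2, cbind(1, 2)), "binary")))
})

test_that("path length and efficiency handle disconnection by convention", {
  Dk <- shortest_paths_matrix(K5(), "binary")
  expect_equal(characteristic_path_length(Dk), 1)
  expect_equal(global_efficiency(Dk), 1)
  Dp <- shortest_paths_matrix(P4(), "binary")
  expect_equal(characteristic_path_length(Dp), 10 / 6)
  expect_equal(global_efficiency(Dp), (1 + 0.5 + 1 / 3 + 1 + 0.5 + 1) / 6)
  # two disjoint edges: CPL over reachable pairs only; E_glob = 4/12
  # (oracle: 4 reachable ordered pairs at distance 1 among 12)
  D2 <- shortest_paths_matrix(adj_from_edges(4, rbind(c(1, 2), c(3, 4))), "binary")
  expect_equal(characteristic_path_length(D2), 1)
  expect_equal(global_efficiency(D2), 1 / 3)
  expect_equal(global_efficiency(D2), bf_global_eff(D2))
})

test_that("eccentricity, radius and diameter", {
  Dp <- shortest_paths_matrix(P4(), "binary")
  expect_equal(node_eccentricity(Dp), c(3, 2, 2, 3))
  expect_equal(graph_radius(Dp), 2)
  expect_equal(graph_diameter(Dp), 3)
  Dk <- shortest_paths_matrix(K5(), "binary")
  expect_equal(node_eccentricity(Dk), rep(1, 5))
  Ds <- shortest_paths_matrix(S5(), "binary")
  expect_equal(node_eccentricity(Ds), c(1, 2, 2, 2, 2))
  expect_equal(graph_radius(Ds), 1)
  expect_equal(graph_diameter(Ds), 2)
  # isolated node flagged as 0
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(node_eccentricity(shortest_paths_matrix(iso, "binary"))[3], 0)
})

test_that("assortativity equals Pearson over edge-end pairs", {
  expect_equal(graph_assortativity(S5(), "binary"), -1)
  expect_true(is.na(graph_assortativity(K5(), "binary")))
  expect_equal(graph_assortativity(RC5(), "binary"), bf_assortativity(RC5()))
  W <- RC5(2); W[1, 5] <- W[5, 1] <- 7
  expect_equal(graph_assortativity(W, "weighted"),
               bf_assortativity(W, "weighted"))
})

test_that("rich-club coefficients", {
  expect_equal(rich_club(RC5(), "binary", 2), 1.0)
  expect_equal(rich_club(K5(), "binary", 3), 1.0)
  expect_true(is.na(rich_club(K5(), "binary", 10)))
  set.seed(7)
  W <- random_connected_graph(10, 0.5)
  for (k in c(2, 4)) {
    expect_equal(rich_club(W, "binary", k), bf_rich_club(W, "binary", k))
    expect_equal(rich_club(W, "weighted", k), bf_rich_club(W, "weighted", k))
  }
})

test_that("degree and strength", {
  expect_equal(node_degree(S5()), c(4, 1, 1, 1, 1))
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 2; W[1, 3] <- W[3, 1] <- 3
  expect_equal(node_strength(W), c(5, 2, 3))
})

test_that("local efficiency equals neighbor-subgraph efficiency", {
  expect_equal(local_efficiency(K5(), "binary"), rep(1, 5))
  expect_equal(local_efficiency(S5(), "binary"), rep(0, 5))
  expect_equal(local_efficiency(RC5(), "binary"), bf_local_eff(RC5()))
})

test_that("betweenness matches geodesic enumeration", {
  expect_equal(betweenness_centrality(S5(), "binary"), c(6, 0, 0, 0, 0))
  expect_equal(betweenness_centrality(P4(), "binary"), c(0, 2, 2, 0))
  expect_equal(betweenness_centrality(K5(), "binary"), rep(0, 5))
})

test_that("eigenvector centrality is norm-1 and matches eigendecomposition", {
  ec <- eigenvector_centrality(K5())
  expect_equal(ec, rep(1 / sqrt(5), 5), tolerance = 1e-8)
  ec_s <- eigenvector_centrality(S5())
  expect_gt(ec_s[1], max(ec_s[-1]))
  expect_equal(eigenvector_centrality(RC5()), bf_eigenvector(RC5()),
               tolerance = 1e-8)
})

test_that("pagerank is a probability vector with regular-graph uniformity", {
  pr <- pagerank_centrality(K5(), damping = 0.85)
  expect_equal(pr, rep(0.2, 5), tolerance = 1e-9)
  set.seed(11)
  W <- random_connected_graph(12, 0.4)
  expect_equal(sum(pagerank_centrality(W, "weighted")), 1, tolerance = 1e-9)
  expect_equal(pagerank_centrality(S5(), damping = 0.85),
               bf_pagerank(S5(), "binary", 0.85), tolerance = 1e-8)
})

test_that("small-worldness: complete graph is its own null; WS ring exceeds ER", {
  expect_equal(small_worldness(K5(), "binary", n_null = 3, seed = 1), 1)
  # ER random graph is (approximately) its own null -> sigma near 1
  A_er <- as.matrix(igraph::as_adjacency_matrix(
    withr::with_seed(31, igraph::sample_gnp(60, 0.2)), sparse = FALSE))
  sig_er <- small_worldness(A_er, "binary", n_null = 10, seed = 5)
  expect_gt(sig_er, 0.8); expect_lt(sig_er, 1.2)
  # Watts-Strogatz small-world regime -> sigma > 1
  A_ws <- as.matrix(igraph::as_adjacency_matrix(
    withr::with_seed(32, igraph::sample_smallworld(1, 60, 3, 0.1)),
    sparse = FALSE))
  A_ws[A_ws > 1] <- 1
  expect_gt(small_worldness(A_ws, "binary", n_null = 10, seed = 6), 1)
  # determinism
  expect_identical(small_worldness(A_er, "binary", n_null = 5, seed = 9),
                   small_worldness(A_er, "binary", n_null = 5, seed = 9))
})

test_that("global feature sets: 25 scalars, binary block scheme-invariant", {
  gc_ <- generate_cohort(generator_config(n_patients = 1, n_nodes = 30,
                                          lesion_size = 3, seed = 13))
  pr <- gc_$cohort$matrices[[1]]
  gf <- compute_global_features(pr$tract_count, pr$qa,
                                metric_config(n_null = 3))
  expect_length(gf$tract_count, 25)
  expect_length(gf$qa, 25)
  bin_names <- c("density", grep("_bin$", names(gf$tract_count), value = TRUE))
  expect_identical(gf$tract_count[bin_names], gf$qa[bin_names])
  # consistency with single-metric operations
  expect_equal(unname(gf$tract_count[["density"]]),
               graph_density(pr$tract_count))
  expect_equal(unname(gf$tract_count[["transitivity_bin"]]),
               graph_transitivity(pr$tract_count, "binary"))
})

test_that("local feature vectors have atlas length and roster is guarded", {
  pr <- generate_base_connectome(generator_config(n_patients = 1), seed = 17)
  W <- pr$tract_count
  expect_equal(igraph::components(
    igraph::graph_from_adjacency_matrix(binarize(W), mode = "undirected"))$no, 1)
  for (m in local_metric_names())
    expect_length(compute_local_features(W, m), 246)
  expect_error(compute_local_features(W, "modularity"), "unknown")
  # eccentricity positive on a connected graph (binary hops)
  expect_true(all(compute_local_features(W, "eccentricity", "binary") >= 1))
})

test_that("metric properties: scale invariance and permutation equivariance", {
  set.seed(23)
  for (rep_ in 1:5) {
    W <- random_connected_graph(9, 0.5)
    c_ <- runif(1, 0.5, 5)
    expect_equal(clustering_coefficients(W * c_, "weighted"),
                 clustering_coefficients(W, "weighted"), tolerance = 1e-10)
    expect_equal(eigenvector_centrality(W * c_, "weighted"),
                 eigenvector_centrality(W, "weighted"), tolerance = 1e-7)
    expect_equal(pagerank_centrality(W * c_, "weighted"),
                 pagerank_centrality(W, "weighted"), tolerance = 1e-9)
    expect_equal(node_strength(W * c_), c_ * node_strength(W))
    expect_equal(shortest_paths_matrix(W * c_, "weighted"),
                 shortest_paths_matrix(W, "weighted") / c_)
    # permutation equivariance
    p <- sample(9)
    Wp <- W[p, p]
    expect_equal(node_degree(Wp), node_degree(W)[p])
    expect_equal(betweenness_centrality(Wp, "weighted"),
                 betweenness_centrality(W, "weighted")[p], tolerance = 1e-9)
    expect_equal(graph_transitivity(Wp, "weighted"),
                 graph_transitivity(W, "weighted"))
    expect_equal(average_clustering(Wp, "binary"), average_clustering(W, "binary"))
    # monotonicity: adding an edge never decreases density/degree/efficiency
    A <- binarize(W)
    off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(off)) {
      e <- off[1, ]
      W2 <- W; W2[e[1], e[2]] <- W2[e[2], e[1]] <- 1
      expect_gte(graph_density(W2), graph_density(W))
      expect_true(all(node_degree(W2) >= node_degree(W)))
      expect_gte(global_efficiency(shortest_paths_matrix(W2, "binary")),
                 global_efficiency(shortest_paths_matrix(W, "binary")))
    }
  }
})
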
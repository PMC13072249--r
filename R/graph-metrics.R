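#' Graph-metric configuration
#'
#' @param damping PageRank damping factor.
#' @param n_null Number of degree-preserving surrogates for small-worldness.
#' @param null_swap_factor Double-edge-swap attempts per surrogate, as a
#'   multiple of the edge count.
#' @param tol Convergence tolerance for iterative centralities.
#' @param seed RNG seed for the small-worldness null ensemble.
#' @return A named list of settings.
#' @export
metric_config <- function(damping = 0.85, n_null = 20L, null_swap_factor = 10L,
                          tol = 1e-12, seed = 1L) {
  list(damping = damping, n_null = as.integer(n_null),
       null_swap_factor = as.integer(null_swap_factor), tol = tol,
       seed = as.integer(seed))
}

#' Binarize a weighted connectivity matrix
#' @param W A [connectivity_matrix()] or numeric matrix.
#' @return 0/1 adjacency matrix with `A[i,j] = 1` iff `W[i,j] > 0`.
#' @export
binarize <- function(W) {
  W <- as_weights(W)
  (W > 0) * 1
}

# Weight matrix in the requested mode: binary adjacency or raw weights.
mode_weights <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  W <- as_weights(W)
  if (mode == "binary") binarize(W) else W
}

graph_of <- function(M) {
  igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' All-pairs shortest-path distances
#'
#' Binary mode counts hops; weighted mode uses edge lengths `1/weight`
#' (stronger connections are closer). Unreachable pairs are `Inf`.
#'
#' @param W Connectivity matrix.
#' @param mode `"binary"` or `"weighted"`.
#' @return An n x n distance matrix with zero diagonal and `Inf` for
#'   unreachable pairs.
#' @export
shortest_paths_matrix <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  M <- as_weights(W)
  g <- graph_of(binarize(M))
  if (mode == "binary") {
    D <- igraph::distances(g, weights = NA)
  } else {
    w <- M[as.matrix(igraph::as_edgelist(g, names = FALSE))]
    D <- igraph::distances(g, weights = 1 / w)
  }
  dimnames(D) <- NULL
  D
}

#' Graph density
#' @param W Connectivity matrix (binarized internally).
#' @return `2 |E| / (n (n - 1))`.
#' @export
graph_density <- function(W) {
  A <- binarize(W)
  n <- nrow(A)
  if (n < 2) stop("density requires at least 2 nodes")
  sum(A) / (n * (n - 1))
}

#' Per-node clustering coefficients
#'
#' Binary mode is the triangle fraction (nodes of degree < 2 score 0).
#' Weighted mode is the Onnela geometric-mean triangle intensity with weights
#' normalized by the matrix maximum, over the binary-degree denominator.
#'
#' @inheritParams shortest_paths_matrix
#' @return Length-n numeric vector.
#' @export
clustering_coefficients <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  M <- as_weights(W)
  A <- binarize(M)
  deg <- rowSums(A)
  S <- if (mode == "binary") A else {
    mx <- max(M)
    if (mx == 0) A * 0 else (M / mx)^(1 / 3)
  }
  tri2 <- diag(S %*% S %*% S)  # 2 * triangle intensity per node
  cc <- ifelse(deg < 2, 0, tri2 / (deg * (deg - 1)))
  unname(cc)
}

#' Average clustering coefficient
#' @inheritParams shortest_paths_matrix
#' @return Unweighted mean of the per-node coefficients over all nodes.
#' @export
average_clustering <- function(W, mode = c("binary", "weighted")) {
  mean(clustering_coefficients(W, mode))
}

#' Graph transitivity
#'
#' Binary: `3 * triangles / connected triples`. Weighted: total Onnela
#' triangle intensity over the same triple count. Returns `NA` (undefined)
#' when the graph has no connected triples.
#'
#' @inheritParams shortest_paths_matrix
#' @return Scalar in `[0, 1]`, or `NA_real_`.
#' @export
graph_transitivity <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  M <- as_weights(W)
  A <- binarize(M)
  deg <- rowSums(A)
  triples2 <- sum(deg * (deg - 1))  # 2 * number of connected triples
  if (triples2 == 0) return(NA_real_)
  S <- if (mode == "binary") A else {
    mx <- max(M)
    if (mx == 0) A * 0 else (M / mx)^(1 / 3)
  }
  sum(diag(S %*% S %*% S)) / triples2
}

#' Characteristic path length
#' @param D Distance matrix from [shortest_paths_matrix()].
#' @return Mean of finite off-diagonal distances (reachable pairs only);
#'   `NA` when no pair is reachable.
#' @export
characteristic_path_length <- function(D) {
  d <- D[upper.tri(D) | lower.tri(D)]
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Global efficiency
#' @param D Distance matrix.
#' @return Mean over all ordered off-diagonal pairs of `1/d`, with
#'   unreachable pairs contributing 0.
#' @export
global_efficiency <- function(D) {
  n <- nrow(D)
  if (n < 2) stop("global efficiency requires at least 2 nodes")
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Node eccentricities, graph radius and diameter
#'
#' Eccentricity is the maximum finite distance from a node (i.e. within its
#' connected component); isolated nodes score 0. Radius and diameter are the
#' minimum and maximum eccentricity.
#'
#' @param D Distance matrix.
#' @return For [node_eccentricity()], a length-n vector; [graph_radius()] and
#'   [graph_diameter()] return scalars.
#' @export
node_eccentricity <- function(D) {
  apply(D, 1L, function(d) {
    d <- d[is.finite(d)]
    if (length(d) <= 1) 0 else max(d)
  })
}

#' @rdname node_eccentricity
#' @export
graph_radius <- function(D) min(node_eccentricity(D))

#' @rdname node_eccentricity
#' @export
graph_diameter <- function(D) max(node_eccentricity(D))

#' Degree assortativity
#'
#' Pearson correlation between the degrees (binary mode) or strengths
#' (weighted mode) of edge endpoints, counting both orientations of every
#' edge. Undefined (`NA`) for regular graphs (zero degree variance) or graphs
#' without edges.
#'
#' @inheritParams shortest_paths_matrix
#' @return Scalar in `[-1, 1]`, or `NA_real_`.
#' @export
graph_assortativity <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  M <- as_weights(W)
  A <- binarize(M)
  val <- if (mode == "binary") rowSums(A) else rowSums(M)
  ij <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  if (nrow(ij) == 0) return(NA_real_)
  x <- c(val[ij[, 1]], val[ij[, 2]])
  y <- c(val[ij[, 2]], val[ij[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Rich-club coefficient
#'
#' The rich set contains nodes of binary degree strictly greater than `k`.
#' Binary: density of edges within the rich set. Weighted (Opsahl): sum of
#' weights within the rich set divided by the sum of the equally many
#' globally strongest edge weights. `NA` when fewer than two rich nodes.
#'
#' @inheritParams shortest_paths_matrix
#' @param k Degree threshold (>= 1).
#' @return Scalar, or `NA_real_`.
#' @export
rich_club <- function(W, mode = c("binary", "weighted"), k) {
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  M <- as_weights(W)
  A <- binarize(M)
  deg <- rowSums(A)
  rich <- deg > k
  nk <- sum(rich)
  if (nk < 2) return(NA_real_)
  if (mode == "binary") {
    e_rich <- sum(A[rich, rich]) / 2
    return(2 * e_rich / (nk * (nk - 1)))
  }
  e_rich <- sum(A[rich, rich]) / 2
  if (e_rich == 0) return(0)
  w_rich <- sum(M[rich, rich]) / 2
  all_w <- sort(M[upper.tri(M)][A[upper.tri(A)] > 0], decreasing = TRUE)
  w_rich / sum(all_w[seq_len(e_rich)])
}

#' Node degree and strength
#' @param W Connectivity matrix.
#' @return [node_degree()]: neighbor counts; [node_strength()]: sums of
#'   incident edge weights.
#' @export
node_degree <- function(W) unname(rowSums(binarize(W)))

#' @rdname node_degree
#' @export
node_strength <- function(W) unname(rowSums(as_weights(W)))

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced on its neighbors
#' (the node itself excluded); nodes with fewer than two neighbors score 0.
#'
#' @inheritParams shortest_paths_matrix
#' @return Length-n numeric vector.
#' @export
local_efficiency <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  M <- as_weights(W)
  A <- binarize(M)
  n <- nrow(M)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- M[nb, nb, drop = FALSE]
    global_efficiency(shortest_paths_matrix(sub, mode))
  }, numeric(1))
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness; each unordered pair contributes
#' fractionally to every geodesic it is interior to. Weighted mode uses edge
#' lengths `1/weight`.
#'
#' @inheritParams shortest_paths_matrix
#' @return Length-n numeric vector.
#' @export
betweenness_centrality <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  M <- as_weights(W)
  g <- graph_of(binarize(M))
  if (igraph::ecount(g) == 0) return(rep(0, nrow(M)))
  w <- if (mode == "binary") NA else {
    1 / M[as.matrix(igraph::as_edgelist(g, names = FALSE))]
  }
  unname(igraph::betweenness(g, weights = w, normalized = FALSE))
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the (binary or weighted) adjacency matrix,
#' nonnegative with unit Euclidean norm, computed by power iteration on the
#' largest connected component; nodes outside it score 0.
#'
#' @inheritParams shortest_paths_matrix
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return Length-n numeric vector with `sqrt(sum(x^2)) = 1` on the largest
#'   component.
#' @export
eigenvector_centrality <- function(W, mode = c("binary", "weighted"),
                                   tol = 1e-12, max_iter = 100000L) {
  mode <- match.arg(mode)
  M <- mode_weights(W, mode)
  n <- nrow(M)
  comp <- igraph::components(graph_of(binarize(M)))
  main <- which(comp$membership == which.max(comp$csize))
  x <- rep(0, n)
  if (length(main) == 1) { x[main] <- 1; return(x) }
  S <- M[main, main, drop = FALSE]
  # diagonal shift: leaves eigenvectors unchanged, makes the dominant
  # eigenvalue strictly largest in modulus (kills bipartite oscillation)
  shift <- max(S)
  v <- rep(1 / sqrt(length(main)), length(main))
  for (it in seq_len(max_iter)) {
    v_new <- as.vector(S %*% v) + shift * v
    nv <- sqrt(sum(v_new^2))
    if (nv == 0) break
    v_new <- v_new / nv
    if (max(abs(v_new - v)) < tol) { v <- v_new; x[main] <- v; return(x) }
    v <- v_new
  }
  if (it >= max_iter) stop("eigenvector centrality did not converge")
  x[main] <- abs(v)
  x
}

#' PageRank centrality
#'
#' Stationary distribution of the damped random walk on the row-normalized
#' weight matrix (uniform teleportation); sums to 1.
#'
#' @inheritParams shortest_paths_matrix
#' @param damping Damping factor in (0, 1).
#' @return Length-n numeric vector summing to 1.
#' @export
pagerank_centrality <- function(W, mode = c("binary", "weighted"),
                                damping = 0.85) {
  mode <- match.arg(mode)
  stopifnot(damping > 0, damping < 1)
  M <- mode_weights(W, mode)
  g <- graph_of(M)
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else NULL
  unname(igraph::page_rank(g, damping = damping, weights = w)$vector)
}

# Degree-preserving surrogate: connected double-edge-swap rewiring of the
# binary topology; weighted mode redistributes the original weights at random
# onto the rewired edges.
rewired_surrogate <- function(M, mode, swap_factor) {
  A <- binarize(M)
  g <- graph_of(A)
  ne <- igraph::ecount(g)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = swap_factor * ne))
  A2 <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  dimnames(A2) <- NULL
  if (mode == "binary") return(A2)
  w <- M[upper.tri(M)][A[upper.tri(A)] > 0]
  w <- sample(w)
  M2 <- matrix(0, nrow(M), ncol(M))
  M2[upper.tri(M2)][A2[upper.tri(A2)] > 0] <- w
  M2 + t(M2)
}

#' Small-worldness
#'
#' `sigma = (C / C_rand) / (L / L_rand)` where `C` is the average clustering
#' coefficient, `L` the characteristic path length, and the null values are
#' means over `n_null` degree-preserving double-edge-swap surrogates
#' (weighted surrogates carry the original weights permuted over the rewired
#' topology). Reproducible under `seed`. `NA` when the ratio is undefined
#' (e.g. no clustering in the null ensemble or unreachable path lengths).
#'
#' @inheritParams shortest_paths_matrix
#' @param n_null Number of surrogates (>= 1).
#' @param seed RNG seed for the null ensemble.
#' @param swap_factor Swap attempts per surrogate as a multiple of |E|.
#' @return Scalar sigma, or `NA_real_`.
#' @export
small_worldness <- function(W, mode = c("binary", "weighted"), n_null = 20L,
                            seed = 1L, swap_factor = 10L) {
  mode <- match.arg(mode)
  stopifnot(n_null >= 1)
  M <- as_weights(W)
  C <- average_clustering(M, mode)
  L <- characteristic_path_length(shortest_paths_matrix(M, mode))
  if (is.na(L)) return(NA_real_)
  nulls <- withr::with_seed(seed, lapply(seq_len(n_null), function(b) {
    M2 <- rewired_surrogate(M, mode, swap_factor)
    c(C = average_clustering(M2, mode),
      L = characteristic_path_length(shortest_paths_matrix(M2, mode)))
  }))
  C_rand <- mean(vapply(nulls, `[[`, numeric(1), "C"))
  L_rand <- mean(vapply(nulls, `[[`, numeric(1), "L"))
  if (is.na(C_rand) || is.na(L_rand) || C_rand == 0 || L_rand == 0 || L == 0)
    return(NA_real_)
  (C / C_rand) / (L / L_rand)
}

# Roster of the 12 global metrics computed in both binary and weighted form
# (density is mode-free and computed once).
.global_metric_names <- c("avg_clustering", "transitivity", "char_path_length",
                          "small_worldness", "global_efficiency", "radius",
                          "diameter", "assortativity", "rich_club_k5",
                          "rich_club_k10", "rich_club_k15", "rich_club_k20")

global_metric_set_one <- function(M, mode, config) {
  D <- shortest_paths_matrix(M, mode)
  v <- c(
    avg_clustering = average_clustering(M, mode),
    transitivity = graph_transitivity(M, mode),
    char_path_length = characteristic_path_length(D),
    small_worldness = small_worldness(M, mode, n_null = config$n_null,
                                      seed = config$seed,
                                      swap_factor = config$null_swap_factor),
    global_efficiency = global_efficiency(D),
    radius = graph_radius(D),
    diameter = graph_diameter(D),
    assortativity = graph_assortativity(M, mode),
    rich_club_k5 = rich_club(M, mode, 5),
    rich_club_k10 = rich_club(M, mode, 10),
    rich_club_k15 = rich_club(M, mode, 15),
    rich_club_k20 = rich_club(M, mode, 20)
  )
  names(v) <- paste0(names(v), if (mode == "binary") "_bin" else "_wt")
  v
}

#' Global metric sets for a tract-count/QA matrix pair
#'
#' Computes density plus the 12 global metrics in binary and weighted form
#' (25 named scalars per scheme). The binary sub-vector is computed once from
#' the shared support and is identical across schemes.
#'
#' @param W_tc Tract-count [connectivity_matrix()].
#' @param W_qa QA [connectivity_matrix()] with identical binary support.
#' @param config A [metric_config()].
#' @return List with named 25-vectors `tract_count` and `qa`.
#' @export
compute_global_features <- function(W_tc, W_qa, config = metric_config()) {
  M_tc <- as_weights(W_tc); M_qa <- as_weights(W_qa)
  if (!identical(M_tc > 0, M_qa > 0))
    stop("matrix pair does not share binary support")
  dens <- c(density = graph_density(M_tc))
  bin <- global_metric_set_one(M_tc, "binary", config)
  list(tract_count = c(dens, bin, global_metric_set_one(M_tc, "weighted", config)),
       qa = c(dens, bin, global_metric_set_one(M_qa, "weighted", config)))
}

#' Names of the local metric roster
#' @return Character vector of the 8 local metrics.
#' @export
local_metric_names <- function() {
  c("degree", "strength", "clustering", "local_efficiency", "betweenness",
    "eigenvector", "pagerank", "eccentricity")
}

#' Compute one local metric vector
#'
#' `degree` is always binary; the seven remaining metrics honour `mode`
#' (weighted by default, matching the feature roster).
#'
#' @param W Connectivity matrix.
#' @param metric One of [local_metric_names()].
#' @param mode `"weighted"` or `"binary"`.
#' @param config A [metric_config()].
#' @return Numeric vector of length `n_nodes`.
#' @export
compute_local_features <- function(W, metric, mode = c("weighted", "binary"),
                                   config = metric_config()) {
  mode <- match.arg(mode)
  if (!metric %in% local_metric_names())
    stop("unknown local metric: ", metric)
  switch(metric,
    degree = node_degree(W),
    strength = node_strength(mode_weights(W, mode)),
    clustering = clustering_coefficients(W, mode),
    local_efficiency = local_efficiency(W, mode),
    betweenness = betweenness_centrality(W, mode),
    eigenvector = eigenvector_centrality(W, mode, tol = config$tol),
    pagerank = pagerank_centrality(W, mode, damping = config$damping),
    eccentricity = node_eccentricity(shortest_paths_matrix(W, mode))
  )
}

#' Long-format metric export
#'
#' @param cohort A `cohort`.
#' @param metrics Local metrics to include.
#' @param schemes Weighting schemes.
#' @param config A [metric_config()].
#' @return data.frame with columns patient, scheme, mode, metric, node, value.
#' @export
metrics_long <- function(cohort, metrics = local_metric_names(),
                         schemes = c("tract_count", "qa"),
                         config = metric_config()) {
  out <- list()
  for (id in cohort$patients$id) {
    for (sc in schemes) {
      W <- cohort$matrices[[id]][[sc]]
      for (m in metrics) {
        v <- compute_local_features(W, m, "weighted", config)
        out[[length(out) + 1L]] <- data.frame(
          patient = id, scheme = sc, mode = if (m == "degree") "binary" else "weighted",
          metric = m, node = seq_along(v) - 1L, value = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
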
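# Fixture graphs used across tests (adjacency matrices).
# K5: complete graph on 5 nodes; P4: path a-b-c-d; S5: star with hub 1;
# RC5: K4 (nodes 1-4) plus pendant node 5 attached to node 1.

adj_from_edges <- function(n, edges, w = 1) {
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    A[edges[e, 1], edges[e, 2]] <- w
    A[edges[e, 2], edges[e, 1]] <- w
  }
  A
}

K5 <- function(w = 1) {
  A <- matrix(w, 5, 5); diag(A) <- 0; A
}
P4 <- function(w = 1) adj_from_edges(4, cbind(1:3, 2:4), w)
S5 <- function(w = 1) adj_from_edges(5, cbind(1, 2:5), w)
RC5 <- function(w = 1) {
  e <- rbind(t(utils::combn(4, 2)), c(1, 5))
  adj_from_edges(5, e, w)
}

# All labeled connected graphs on n nodes (n <= 5 keeps this enumerable).
all_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (code in seq_len(2^m) - 1L) {
    bits <- bitwAnd(code, 2^(seq_len(m) - 1L)) > 0
    if (sum(bits) < n - 1) next
    A <- adj_from_edges(n, pairs[bits, , drop = FALSE])
    if (is_connected_bf(A)) out[[length(out) + 1L]] <- A
  }
  out
}

is_connected_bf <- function(A) {
  n <- nrow(A)
  seen <- c(1L)
  repeat {
    nb <- which(colSums(A[seen, , drop = FALSE] > 0) > 0)
    new <- setdiff(nb, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  length(seen) == n
}

# Random connected weighted graph on n nodes (continuous weights avoid
# shortest-path ties that would make tie-splitting comparisons fragile).
random_connected_graph <- function(n, p = 0.5, weighted = TRUE) {
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- (stats::runif(sum(up)) < p) *
      (if (weighted) stats::runif(sum(up), 0.5, 10) else 1)
    A <- A + t(A)
    if (is_connected_bf(A)) return(A)
  }
}
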
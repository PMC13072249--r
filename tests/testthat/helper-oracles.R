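# Brute-force oracle implementations, independent of the package's metric
# code paths: explicit path enumeration, triangle counting, dense
# eigendecomposition. Only feasible for small graphs.

bf_lengths <- function(W, mode) {
  if (mode == "binary") (W > 0) * 1 else ifelse(W > 0, 1 / W, 0)
}

# Floyd-Warshall all-pairs shortest paths.
bf_distances <- function(W, mode = "binary") {
  L <- bf_lengths(W, mode)
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[L > 0] <- L[L > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Enumerate all simple paths i -> j; return list of node sequences having
# minimal total length.
bf_geodesics <- function(W, i, j, mode) {
  L <- bf_lengths(W, mode)
  best <- list(len = Inf, paths = list())
  walk <- function(path, len) {
    tail_ <- path[length(path)]
    if (tail_ == j) {
      if (len < best$len - 1e-12) best <<- list(len = len, paths = list(path))
      else if (abs(len - best$len) <= 1e-12)
        best$paths[[length(best$paths) + 1L]] <<- path
      return()
    }
    for (k in which(L[tail_, ] > 0)) {
      if (k %in% path) next
      walk(c(path, k), len + L[tail_, k])
    }
  }
  walk(i, 0)
  best
}

bf_betweenness <- function(W, mode = "binary") {
  n <- nrow(W)
  b <- numeric(n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    g <- bf_geodesics(W, i, j, mode)
    if (!length(g$paths)) next
    for (p in g$paths) {
      interior <- setdiff(p, c(i, j))
      b[interior] <- b[interior] + 1 / length(g$paths)
    }
  }
  b
}

bf_clustering <- function(W, mode = "binary") {
  A <- (W > 0) * 1
  n <- nrow(W)
  S <- if (mode == "binary") A else if (max(W) > 0) (W / max(W))^(1 / 3) else A * 0
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    tot <- 0
    for (a in nb) for (b in nb) if (a != b)
      tot <- tot + S[i, a] * S[a, b] * S[b, i]
    tot / (length(nb) * (length(nb) - 1))
  }, numeric(1))
}

bf_transitivity <- function(W, mode = "binary") {
  A <- (W > 0) * 1
  deg <- rowSums(A)
  triples2 <- sum(deg * (deg - 1))
  if (triples2 == 0) return(NA_real_)
  S <- if (mode == "binary") A else if (max(W) > 0) (W / max(W))^(1 / 3) else A * 0
  tot <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n))
    if (i != a && a != b && b != i)
      tot <- tot + S[i, a] * S[a, b] * S[b, i]
  tot / triples2
}

bf_cpl <- function(D) {
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d)]
  if (!length(d)) NA_real_ else mean(d)
}

bf_global_eff <- function(D) {
  n <- nrow(D)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && is.finite(D[i, j]))
    tot <- tot + 1 / D[i, j]
  tot / (n * (n - 1))
}

bf_eccentricity <- function(D) {
  apply(D, 1, function(d) { d <- d[is.finite(d)]; if (length(d) <= 1) 0 else max(d) })
}

bf_local_eff <- function(W, mode = "binary") {
  A <- (W > 0) * 1
  vapply(seq_len(nrow(W)), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    bf_global_eff(bf_distances(W[nb, nb, drop = FALSE], mode))
  }, numeric(1))
}

bf_assortativity <- function(W, mode = "binary") {
  A <- (W > 0) * 1
  val <- if (mode == "binary") rowSums(A) else rowSums(W)
  x <- c(); y <- c()
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && A[i, j] > 0) {
    x <- c(x, val[i]); y <- c(y, val[j])
  }
  if (!length(x) || stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, y)
}

bf_rich_club <- function(W, mode, k) {
  A <- (W > 0) * 1
  deg <- rowSums(A)
  rich <- which(deg > k)
  if (length(rich) < 2) return(NA_real_)
  nk <- length(rich)
  er <- sum(A[rich, rich]) / 2
  if (mode == "binary") return(2 * er / (nk * (nk - 1)))
  if (er == 0) return(0)
  wr <- sum(W[rich, rich]) / 2
  allw <- sort(W[upper.tri(W)][W[upper.tri(W)] > 0], decreasing = TRUE)
  wr / sum(allw[seq_len(er)])
}

bf_eigenvector <- function(W, mode = "binary") {
  M <- if (mode == "binary") (W > 0) * 1 else W
  n <- nrow(M)
  comp <- bf_components(M)
  sizes <- table(comp)
  main <- which(comp == as.integer(names(sizes)[which.max(sizes)]))
  x <- numeric(n)
  if (length(main) == 1) { x[main] <- 1; return(x) }
  e <- eigen(M[main, main, drop = FALSE], symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- v * sign(sum(v) + 1e-300)
  x[main] <- abs(v) / sqrt(sum(v^2))
  x
}

bf_components <- function(M) {
  n <- nrow(M)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    seen <- s
    repeat {
      nb <- which(colSums(M[seen, , drop = FALSE] > 0) > 0)
      new <- setdiff(nb, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    comp[seen] <- cur
  }
  comp
}

bf_pagerank <- function(W, mode = "binary", damping = 0.85, iters = 200000,
                        tol = 1e-14) {
  M <- if (mode == "binary") (W > 0) * 1 else W
  n <- nrow(M)
  rs <- rowSums(M)
  P <- matrix(1 / n, n, n)
  ok <- rs > 0
  P[ok, ] <- M[ok, , drop = FALSE] / rs[ok]
  v <- rep(1 / n, n)
  for (i in seq_len(iters)) {
    v_new <- damping * as.vector(t(P) %*% v) + (1 - damping) / n
    if (max(abs(v_new - v)) < tol) return(v_new / sum(v_new))
    v <- v_new
  }
  v / sum(v)
}

bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
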
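#' Construct a feature table
#'
#' @param x Numeric matrix (patients x features) with column names.
#' @param y Binary labels (0/1), positive class = survival >= 1 year.
#' @param kind `"local"` or `"global"` feature-vector kind (drives the
#'   selection strategy: global tables skip the filter-consensus step).
#' @return List of class `feature_table` with elements `x`, `y`, `kind`.
#' @export
feature_table <- function(x, y, kind = "local") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)), !anyNA(x))
  structure(list(x = x, y = y, kind = kind), class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$x), " x ", ncol(x$x), " (", x$kind,
      "), prevalence = ", round(mean(x$y), 3), "\n", sep = "")
  invisible(x)
}

subset_rows <- function(table, idx) {
  feature_table(table$x[idx, , drop = FALSE], table$y[idx], table$kind)
}

# Rankings are data.frames (feature, score) sorted best-first; ties broken
# lexicographically by feature name so every ranking is deterministic.
make_ranking <- function(scores, filter) {
  stopifnot(!is.null(names(scores)))
  ord <- order(-scores, names(scores))
  structure(data.frame(feature = names(scores)[ord],
                       score = unname(scores[ord]),
                       stringsAsFactors = FALSE),
            filter = filter, class = c("feature_ranking", "data.frame"))
}

#' Correlation filter ranking
#'
#' Features ordered by absolute Pearson correlation with the 0/1 label;
#' zero-variance features score 0.
#'
#' @param table A [feature_table()].
#' @return A `feature_ranking` data.frame (feature, score), best first.
#' @export
rank_correlation <- function(table) {
  sc <- abs(suppressWarnings(stats::cor(table$x, table$y)))[, 1]
  sc[is.na(sc)] <- 0
  names(sc) <- colnames(table$x)
  make_ranking(sc, "correlation")
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Fayyad-Irani supervised MDL discretization: recursive binary splitting on
# class-boundary midpoints, accepted while information gain beats the MDL
# penalty. Returns cut points (possibly none).
mdl_discretize <- function(x, y) {
  cuts <- numeric(0)
  h2 <- function(a, b) {  # entropy in bits of a two-class count pair
    n <- a + b
    out <- numeric(length(n))
    ok <- n > 0
    p <- a[ok] / n[ok]
    q <- 1 - p
    t1 <- ifelse(p > 0, p * log2(p), 0)
    t2 <- ifelse(q > 0, q * log2(q), 0)
    out[ok] <- -(t1 + t2)
    out
  }
  recurse <- function(xs, ys) {
    n <- length(xs)
    if (n < 4) return()
    o <- order(xs)
    xs <- xs[o]; ys <- ys[o]
    # candidate cuts at boundaries between adjacent distinct values;
    # gains computed from cumulative class counts (vectorized)
    new_val <- which(diff(xs) > 0)
    if (!length(new_val)) return()
    c1 <- cumsum(ys)[new_val]           # class-1 count left of each cut
    c0 <- new_val - c1
    n1 <- sum(ys); n0 <- n - n1
    ent_s <- h2(n1, n0)
    e1 <- h2(c1, c0)
    e2 <- h2(n1 - c1, n0 - c0)
    nl <- new_val; nr <- n - new_val
    gain <- ent_s - (nl * e1 + nr * e2) / n
    at <- which.max(gain)
    # MDL acceptance criterion (class counts per side for the penalty)
    k <- (n1 > 0) + (n0 > 0)
    k1 <- (c1[at] > 0) + (c0[at] > 0)
    k2 <- (n1 - c1[at] > 0) + (n0 - c0[at] > 0)
    delta <- log2(3^k - 2) - (k * ent_s - k1 * e1[at] - k2 * e2[at])
    if (gain[at] <= (log2(n - 1) + delta) / n) return()
    cut <- (xs[new_val[at]] + xs[new_val[at] + 1L]) / 2
    cuts <<- c(cuts, cut)
    left <- xs <= cut
    recurse(xs[left], ys[left])
    recurse(xs[!left], ys[!left])
  }
  recurse(x, y)
  sort(cuts)
}

# All three entropy scores per feature from one shared MDL discretization.
info_scores_all <- function(table) {
  y <- table$y
  n <- length(y)
  hy <- entropy_bits(tabulate(y + 1L, 2L))
  sc <- vapply(seq_len(ncol(table$x)), function(j) {
    x <- table$x[, j]
    cuts <- mdl_discretize(x, y)
    if (!length(cuts))  # degenerate discretization
      return(c(info_gain = 0, gain_ratio = 0, sym_uncert = 0))
    bins <- findInterval(x, cuts)
    tab <- table(bins, y)
    hx <- entropy_bits(rowSums(tab))
    hyx <- sum(rowSums(tab) / n * apply(tab, 1L, entropy_bits))
    ig <- hy - hyx
    c(info_gain = ig,
      gain_ratio = if (hx > 0) ig / hx else 0,
      sym_uncert = if (hx + hy > 0) 2 * ig / (hx + hy) else 0)
  }, numeric(3))
  colnames(sc) <- colnames(table$x)
  sc
}

info_scores <- function(table, kind) {
  info_scores_all(table)[kind, ]
}

#' Entropy-based filter rankings
#'
#' Numeric features are discretized by supervised MDL binning
#' (Fayyad-Irani); scores use entropies in bits: information gain
#' `H(Y) - H(Y|X)`, gain ratio `IG / H(X)` and symmetrical uncertainty
#' `2 IG / (H(X) + H(Y))`. Features whose discretization is degenerate
#' (no accepted cut) score 0.
#'
#' @param table A [feature_table()].
#' @return A `feature_ranking`.
#' @export
rank_info_gain <- function(table) make_ranking(info_scores(table, "info_gain"), "info_gain")

#' @rdname rank_info_gain
#' @export
rank_gain_ratio <- function(table) make_ranking(info_scores(table, "gain_ratio"), "gain_ratio")

#' @rdname rank_info_gain
#' @export
rank_sym_uncert <- function(table) make_ranking(info_scores(table, "sym_uncert"), "sym_uncert")

#' OneR filter ranking
#'
#' For each feature a one-level rule is built from equal-frequency bins with
#' a minimum bucket size, predicting the majority class per bin; the score is
#' the rule's training accuracy.
#'
#' @param table A [feature_table()].
#' @param min_bucket Minimum bin occupancy (default 6).
#' @return A `feature_ranking`.
#' @export
rank_oner <- function(table, min_bucket = 6L) {
  y <- table$y
  n <- length(y)
  n_bins <- max(1L, n %/% min_bucket)
  sc <- vapply(seq_len(ncol(table$x)), function(j) {
    x <- table$x[, j]
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                          type = 1)
    cutpoints <- unique(qs[-c(1L, length(qs))])
    bins <- findInterval(x, cutpoints, left.open = TRUE)
    tab <- table(bins, y)
    sum(apply(tab, 1L, max)) / n
  }, numeric(1))
  names(sc) <- colnames(table$x)
  make_ranking(sc, "oner")
}

#' ReliefF filter ranking
#'
#' Instance-based weighting on min-max-scaled features: for each (sampled)
#' instance the k nearest hits and k nearest misses (Euclidean distance)
#' contribute the average per-feature miss-difference minus hit-difference.
#' With `n_samples = NULL` all instances are used and the ranking is
#' deterministic.
#'
#' @param table A [feature_table()].
#' @param k_neighbors Neighbors per class (default 10).
#' @param n_samples Number of sampled instances (`NULL` = all).
#' @param seed Seed used only when sampling instances.
#' @return A `feature_ranking`.
#' @export
rank_relieff <- function(table, k_neighbors = 10L, n_samples = NULL, seed = 1L) {
  stopifnot(k_neighbors >= 1)
  x <- table$x
  rng <- apply(x, 2L, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  xs <- sweep(sweep(x, 2L, apply(x, 2L, min)), 2L, rng, "/")
  n <- nrow(xs)
  D <- as.matrix(stats::dist(xs))
  idx <- if (is.null(n_samples) || n_samples >= n) seq_len(n)
         else withr::with_seed(seed, sort(sample.int(n, n_samples)))
  w <- numeric(ncol(x))
  for (i in idx) {
    same <- which(table$y == table$y[i]); same <- setdiff(same, i)
    diff_ <- which(table$y != table$y[i])
    if (!length(same) || !length(diff_)) next
    hits <- same[order(D[i, same])][seq_len(min(k_neighbors, length(same)))]
    miss <- diff_[order(D[i, diff_])][seq_len(min(k_neighbors, length(diff_)))]
    hd <- abs(sweep(xs[hits, , drop = FALSE], 2L, xs[i, ]))
    md <- abs(sweep(xs[miss, , drop = FALSE], 2L, xs[i, ]))
    w <- w + colMeans(md) - colMeans(hd)
  }
  w <- w / length(idx)
  names(w) <- colnames(x)
  make_ranking(w, "relieff")
}

#' Run the six-filter bank
#' @param table A [feature_table()].
#' @param relieff_k ReliefF neighbor count.
#' @return Named list of six `feature_ranking`s.
#' @export
filter_bank <- function(table, relieff_k = 10L) {
  ent <- info_scores_all(table)  # one MDL discretization for all three
  list(correlation = rank_correlation(table),
       gain_ratio = make_ranking(ent["gain_ratio", ], "gain_ratio"),
       info_gain = make_ranking(ent["info_gain", ], "info_gain"),
       oner = rank_oner(table),
       relieff = rank_relieff(table, k_neighbors = relieff_k),
       sym_uncert = make_ranking(ent["sym_uncert", ], "sym_uncert"))
}

#' Consensus selection over filter rankings
#'
#' Retains features ranked within the top `top_n` (ties at the boundary
#' included) in at least `min_votes` of the rankings; the result is ordered
#' by mean rank across all rankings.
#'
#' @param rankings List of `feature_ranking`s over the same feature set.
#' @param top_n Rank cutoff (default 50).
#' @param min_votes Minimum number of rankings voting for a feature
#'   (default 3).
#' @return Character vector of selected feature names (possibly empty).
#' @export
consensus_select <- function(rankings, top_n = 50L, min_votes = 3L) {
  feats <- sort(rankings[[1]]$feature)
  stopifnot(all(vapply(rankings, function(r) identical(sort(r$feature), feats),
                       logical(1))))
  rank_mat <- vapply(rankings, function(r) {
    rk <- rank(-r$score, ties.method = "min")
    rk[match(feats, r$feature)]
  }, numeric(length(feats)))
  score_mat <- vapply(rankings, function(r) r$score[match(feats, r$feature)],
                      numeric(length(feats)))
  # a zero score means the filter could not rank the feature at all; such
  # features never occupy a top slot (otherwise a mass tie of unscorable
  # features would flood the consensus)
  votes <- rowSums(rank_mat <= top_n & score_mat > 0)
  sel <- feats[votes >= min_votes]
  if (!length(sel)) {
    message("consensus selection returned no features")
    return(character(0))
  }
  mean_rank <- rowMeans(rank_mat)[votes >= min_votes]
  sel[order(mean_rank, sel)]
}

# Stratified k-fold assignment, deterministic under seed.
stratified_folds <- function(y, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      ix <- sample(which(y == cls))
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
    fold
  })
}

# Merit of a feature subset: pooled accuracy of the classifier under
# internal stratified CV; the empty set scores the majority-class rate.
subset_merit <- function(table, feats, classifier, fold, seed) {
  if (!length(feats)) return(max(mean(table$y), 1 - mean(table$y)))
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); va <- which(fold == f)
    m <- tryCatch(
      fit_classifier(classifier, table$x[tr, feats, drop = FALSE],
                     table$y[tr], seed = seed + f),
      error = function(e) NULL)
    if (is.null(m)) next  # classifier failure scores 0 for this fold
    p <- predict_prob(m, table$x[va, feats, drop = FALSE])
    correct <- correct + sum(as.integer(p >= 0.5) == table$y[va])
  }
  correct / nrow(table$x)
}

#' Wrapper feature selection (best-first forward search)
#'
#' Greedy best-first search over subsets of the candidate features, scored by
#' the target classifier's pooled accuracy under internal stratified
#' cross-validation. The search stops after `max_stale` consecutive
#' expansions without improvement (or at the expansion budget) and returns
#' the best subset found; deterministic given the seed.
#'
#' @param table A [feature_table()].
#' @param subset Candidate feature names (nonempty).
#' @param classifier A [classifier_spec()] used to score subsets.
#' @param seed Integer seed (fixes fold assignment and classifier fits).
#' @param n_folds Internal CV folds (default 5).
#' @param max_stale Consecutive non-improving expansions tolerated
#'   (default 5).
#' @param max_expansions Expansion budget of the search (default 12).
#' @return Character vector of selected features (possibly empty when no
#'   subset beats the empty-set merit).
#' @export
wrapper_select <- function(table, subset, classifier, seed = 1L, n_folds = 5L,
                           max_stale = 5L, max_expansions = 12L) {
  stopifnot(length(subset) >= 1)
  fold <- stratified_folds(table$y, n_folds, seed)
  cache <- new.env(parent = emptyenv())
  merit <- function(feats) {
    key <- paste0("s:", paste(sort(feats), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- subset_merit(table, feats, classifier, fold, seed)
    cache[[key]] <- m
    m
  }
  best_set <- character(0)
  best_merit <- merit(character(0))
  open <- list(list(feats = character(0), merit = best_merit))
  closed <- character(0)
  stale <- 0L
  expansions <- 0L
  while (length(open) && stale < max_stale && expansions < max_expansions) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    at <- which.max(merits)
    node <- open[[at]]
    open <- open[-at]
    key <- paste0("s:", paste(sort(node$feats), collapse = "|"))
    if (key %in% closed) next
    closed <- c(closed, key)
    expansions <- expansions + 1L
    improved <- FALSE
    for (f in setdiff(subset, node$feats)) {
      feats <- c(node$feats, f)
      m <- merit(feats)
      open[[length(open) + 1L]] <- list(feats = feats, merit = m)
      if (m > best_merit + 1e-9) {
        best_merit <- m
        best_set <- feats
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  sort(best_set)
}

#' SMOTE minority oversampling
#'
#' Synthesizes minority-class points by convex interpolation between a
#' minority point and one of its `k_neighbors` nearest minority neighbors
#' (`x_new = x_i + u (x_nn - x_i)`, `u ~ U(0, 1)`), until the class ratio
#' reaches `target_ratio` (minority : majority). Original rows are returned
#' unchanged, synthetics appended.
#'
#' @param table A [feature_table()].
#' @param k_neighbors Neighborhood size (default 5).
#' @param target_ratio Target minority/majority ratio (default 1).
#' @param seed Integer seed.
#' @return A balanced [feature_table()].
#' @export
smote <- function(table, k_neighbors = 5L, target_ratio = 1, seed = 1L) {
  y <- table$y
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(table)
  minority <- if (n1 < n0) 1L else 0L
  mi <- which(y == minority)
  n_min <- length(mi); n_maj <- length(y) - n_min
  if (n_min < 2) stop("SMOTE requires at least 2 minority samples")
  n_syn <- round(n_maj * target_ratio) - n_min
  if (n_syn <= 0) return(table)
  xm <- table$x[mi, , drop = FALSE]
  D <- as.matrix(stats::dist(xm))
  diag(D) <- Inf
  k <- min(k_neighbors, n_min - 1L)
  nn <- apply(D, 1L, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1L) matrix(nn, ncol = 1L) else t(nn)
  syn <- matrix(0, n_syn, ncol(xm))
  withr::with_seed(seed, {
    for (t_ in seq_len(n_syn)) {
      i <- ((t_ - 1L) %% n_min) + 1L
      j <- nn[i, sample.int(k, 1)]
      u <- stats::runif(1)
      syn[t_, ] <- xm[i, ] + u * (xm[j, ] - xm[i, ])
    }
  })
  colnames(syn) <- colnames(table$x)
  feature_table(rbind(table$x, syn), c(y, rep(minority, n_syn)), table$kind)
}
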
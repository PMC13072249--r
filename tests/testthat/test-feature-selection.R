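make_fake_ranking <- function(feats) {
  structure(data.frame(feature = feats,
                       score = seq(length(feats), 1) / length(feats),
                       stringsAsFactors = FALSE),
            filter = "fake", class = c("feature_ranking", "data.frame"))
}

# Small deterministic tables for filter oracles.
toy_table <- function() {
  y <- rep(c(0L, 1L), each = 6)
  set.seed(42)
  x <- cbind(
    exact = as.numeric(y),                       # identical to label
    good = y + rnorm(12, 0, 0.3),                # informative
    const = rep(1, 12),                          # zero variance
    noise = rnorm(12)                            # uninformative
  )
  feature_table(x, y)
}

test_that("correlation filter ranks by |r| with zero-variance scored 0", {
  tab <- toy_table()
  r <- rank_correlation(tab)
  expect_equal(r$feature[1], "exact")
  expect_equal(r$score[1], 1.0)
  expect_equal(r$score[r$feature == "const"], 0)
  # oracle: brute-force correlations agree
  for (f in colnames(tab$x)) {
    expected <- abs(suppressWarnings(cor(tab$x[, f], tab$y)))
    if (is.na(expected)) expected <- 0
    expect_equal(r$score[r$feature == f], expected)
  }
})

test_that("entropy filters: perfect binary predictor scores 1 bit", {
  y <- rep(c(0L, 1L), each = 4)
  x <- cbind(perfect = as.numeric(y), flat = rep(2, 8))
  tab <- feature_table(x, y)
  # H(Y) = 1, H(Y|X) = 0, H(X) = 1 by direct entropy arithmetic
  expect_equal(rank_info_gain(tab)$score[1], 1.0)
  expect_equal(rank_gain_ratio(tab)$score[1], 1.0)
  expect_equal(rank_sym_uncert(tab)$score[1], 1.0)
  expect_equal(rank_info_gain(tab)$score[2], 0)
  expect_equal(rank_sym_uncert(tab)$score[2], 0)
})

test_that("OneR scores rule training accuracy", {
  tab <- toy_table()
  r <- rank_oner(tab)
  expect_equal(r$score[r$feature == "exact"], 1.0)
  # constant feature: single bin, majority vote = prevalence
  expect_equal(r$score[r$feature == "const"], 0.5)
  # brute-force oracle on the "good" feature: split at the median
  # (two equal-frequency buckets of 6), majority class per bucket
  x <- tab$x[, "good"]; y <- tab$y
  low <- x <= quantile(x, 0.5, type = 1)
  acc <- (max(table(factor(y[low], levels = 0:1))) +
          max(table(factor(y[!low], levels = 0:1)))) / 12
  expect_equal(r$score[r$feature == "good"], unname(acc))
})

test_that("ReliefF separates signal from noise and respects duplicates", {
  set.seed(9)
  n <- 500
  y <- rep(c(0L, 1L), each = n / 2)
  signal <- y * 2 + rnorm(n, 0, 0.3)
  x <- cbind(signal = signal, twin = signal + rnorm(n, 0, 0.01),
             matrix(rnorm(n * 10), n, 10,
                    dimnames = list(NULL, sprintf("noise%02d", 1:10))))
  tab <- feature_table(x, y)
  r <- rank_relieff(tab, k_neighbors = 10)
  expect_true(all(r$feature[1:2] %in% c("signal", "twin")))
  w <- setNames(r$score, r$feature)
  expect_true(all(abs(w[grep("^noise", names(w))]) < 0.05))
  expect_lt(abs(w[["signal"]] - w[["twin"]]) / abs(w[["signal"]]), 0.1)
  # deterministic when all instances are used
  expect_identical(r, rank_relieff(tab, k_neighbors = 10))
})

test_that("rankings are permutations, column-order invariant", {
  tab <- toy_table()
  for (rk in filter_bank(tab)) {
    expect_setequal(rk$feature, colnames(tab$x))
    expect_equal(anyDuplicated(rk$feature), 0)
  }
  perm <- c(3, 1, 4, 2)
  tab2 <- feature_table(tab$x[, perm], tab$y)
  expect_equal(rank_correlation(tab2)$feature, rank_correlation(tab)$feature)
  expect_equal(rank_oner(tab2)$feature, rank_oner(tab)$feature)
})

test_that("consensus honours the top-n / min-votes rule and is monotone", {
  mk <- function(feats) make_fake_ranking(feats)
  feats <- sprintf("f%03d", 1:100)
  same <- mk(feats)
  sel <- consensus_select(rep(list(same), 6), top_n = 50, min_votes = 3)
  expect_setequal(sel, feats[1:50])
  # feature in top-50 of exactly 2 rankings -> excluded; exactly 3 -> included
  off <- mk(c(feats[51:100], feats[1:50]))  # reversed halves
  sel2 <- consensus_select(c(rep(list(same), 2), rep(list(off), 4)),
                           top_n = 50, min_votes = 3)
  expect_false(feats[1] %in% sel2)          # top-50 in only the 2 "same"
  sel3 <- consensus_select(c(rep(list(same), 3), rep(list(off), 3)),
                           top_n = 50, min_votes = 3)
  expect_true(feats[1] %in% sel3)           # now in exactly 3
  # monotone in top_n
  r6 <- c(rep(list(same), 3), rep(list(off), 3))
  s_small <- consensus_select(r6, top_n = 20, min_votes = 3)
  s_big <- consensus_select(r6, top_n = 60, min_votes = 3)
  expect_true(all(s_small %in% s_big))
})

test_that("wrapper search finds the predictive feature and never loses merit", {
  set.seed(15)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(hit = y + rnorm(n, 0, 0.2),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  tab <- feature_table(x, y)
  sel <- wrapper_select(tab, colnames(x), classifier_spec("knn"), seed = 2)
  expect_true("hit" %in% sel)
  # all-noise candidates: merit cannot beat prevalence by much
  tab_noise <- feature_table(x[, c("n1", "n2", "n3")], y)
  sel_n <- wrapper_select(tab_noise, c("n1", "n2", "n3"),
                          classifier_spec("knn"), seed = 2)
  fold <- connsurv:::stratified_folds(y, 5, 2)
  merit <- connsurv:::subset_merit(tab_noise, sel_n, classifier_spec("knn"),
                                   fold, 2)
  expect_lte(merit, 0.5 + 0.1 + 1e-9)
  # determinism
  expect_identical(sel, wrapper_select(tab, colnames(x),
                                       classifier_spec("knn"), seed = 2))
})

test_that("SMOTE balances classes on minority segments, originals unchanged", {
  set.seed(20)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(0L, 30), rep(1L, 10))
  tab <- feature_table(x, y)
  out <- smote(tab, k_neighbors = 5, seed = 3)
  expect_equal(sum(out$y == 1), 30)
  expect_equal(sum(out$y == 0), 30)
  expect_identical(out$x[1:40, ], tab$x)
  # every synthetic lies on a segment between two minority originals
  minority <- tab$x[y == 1, ]
  syn <- out$x[-(1:40), , drop = FALSE]
  on_segment <- apply(syn, 1, function(s) {
    any(apply(minority, 1, function(p) any(apply(minority, 1, function(q) {
      d <- q - p
      if (all(d == 0)) return(all(abs(s - p) < 1e-9))
      t_ <- sum((s - p) * d) / sum(d * d)
      t_ >= -1e-9 && t_ <= 1 + 1e-9 && all(abs(p + t_ * d - s) < 1e-9)
    }))))
  })
  expect_true(all(on_segment))
  # minority of two identical points -> synthetics equal that point
  x2 <- rbind(matrix(rnorm(20), 10, 2), matrix(1, 2, 2))
  colnames(x2) <- c("a", "b")
  tab2 <- feature_table(x2, c(rep(0L, 10), 1L, 1L))
  out2 <- smote(tab2, seed = 1)
  expect_true(all(out2$x[out2$y == 1, ] == 1))
  # singleton minority errors
  tab3 <- feature_table(x2[1:11, ], c(rep(0L, 10), 1L))
  expect_error(smote(tab3), "minority")
})
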
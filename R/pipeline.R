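#' Enumerate the 16 feature-vector specifications
#'
#' One global set (tract-count scheme; its binary half is scheme-invariant),
#' the unweighted degree vector (scheme-invariant, listed once), and the
#' seven weighted local metrics under both tract-count and QA weighting:
#' 1 + 1 + 7 x 2 = 16 specifications; crossed with the ten-classifier roster
#' this yields the 160-model grid.
#'
#' @return data.frame with columns `spec_id`, `kind`, `metric`, `scheme`.
#' @export
enumerate_feature_specs <- function() {
  weighted_local <- setdiff(local_metric_names(), "degree")
  specs <- rbind(
    data.frame(kind = "global", metric = "global", scheme = "tract_count"),
    data.frame(kind = "local", metric = "degree", scheme = "unweighted"),
    expand.grid(kind = "local", metric = weighted_local,
                scheme = c("tract_count", "qa"), stringsAsFactors = FALSE))
  specs$spec_id <- ifelse(
    specs$kind == "global", "global",
    ifelse(specs$metric == "degree", "local_degree",
           paste("local", specs$metric, specs$scheme, sep = "_")))
  rownames(specs) <- NULL
  specs[, c("spec_id", "kind", "metric", "scheme")]
}

#' Names of the clinical covariates
#' @return The five demographic/clinical covariates appended to every
#'   feature vector: age, sex, extent of resection, tumor hemisphere and
#'   tumor lobe.
#' @export
clinical_covariates <- function() {
  c("age", "sex", "extent_of_resection", "tumor_hemisphere", "tumor_lobe")
}

one_hot_clinical <- function(patients) {
  out <- list(age = patients$age)
  for (v in c("sex", "extent_of_resection", "tumor_hemisphere", "tumor_lobe")) {
    vals <- sort(unique(patients[[v]]))
    for (lv in vals)
      out[[paste0(v, "_", lv)]] <- as.numeric(patients[[v]] == lv)
  }
  m <- do.call(cbind, out)
  rownames(m) <- NULL
  m
}

#' Precompute all network features of a cohort
#'
#' Caches per-scheme local metric matrices (patients x nodes) and the global
#' 25-vectors so that the 16 feature tables can be assembled without
#' recomputing graph metrics.
#'
#' @param cohort A `cohort`.
#' @param config A [metric_config()].
#' @param include_global Compute the global sets too (the expensive
#'   small-worldness null ensemble runs per patient).
#' @param metrics Weighted local metrics to compute (default all seven).
#' @param schemes Weighting schemes to cover.
#' @return A cache list consumed by [assemble_features()].
#' @export
compute_cohort_features <- function(cohort, config = metric_config(),
                                    include_global = TRUE,
                                    metrics = setdiff(local_metric_names(),
                                                      "degree"),
                                    schemes = c("tract_count", "qa")) {
  ids <- cohort$patients$id
  local <- list()
  for (sc in schemes) {
    local[[sc]] <- lapply(metrics, function(m) {
      t(vapply(ids, function(id)
        compute_local_features(cohort$matrices[[id]][[sc]], m, "weighted",
                               config),
        numeric(cohort$n_nodes)))
    })
    names(local[[sc]]) <- metrics
  }
  degree <- t(vapply(ids, function(id)
    compute_local_features(cohort$matrices[[id]]$tract_count, "degree",
                           "binary", config),
    numeric(cohort$n_nodes)))
  global <- NULL
  if (include_global) {
    gl <- lapply(ids, function(id)
      compute_global_features(cohort$matrices[[id]]$tract_count,
                              cohort$matrices[[id]]$qa, config))
    global <- list(tract_count = t(vapply(gl, `[[`, numeric(25), "tract_count")),
                   qa = t(vapply(gl, `[[`, numeric(25), "qa")))
  }
  list(ids = ids, local = local, degree = degree, global = global)
}

#' Assemble the feature table for one specification
#'
#' Local specifications yield one column per node plus the one-hot-encoded
#' clinical covariates; the global specification yields the 25 global
#' metrics plus covariates. Undefined metric values (`NA` sentinels) are
#' mapped to 0 with a warning.
#'
#' @param cohort A `cohort`.
#' @param spec One row of [enumerate_feature_specs()].
#' @param cache Optional cache from [compute_cohort_features()].
#' @param config A [metric_config()] (used when `cache` is absent).
#' @return A [feature_table()] with labels `os_class`.
#' @export
assemble_features <- function(cohort, spec, cache = NULL,
                              config = metric_config()) {
  if (is.null(cache))
    cache <- compute_cohort_features(
      cohort, config, include_global = spec$kind == "global",
      metrics = if (spec$kind == "local" && spec$metric != "degree")
        spec$metric else character(0),
      schemes = if (spec$kind == "local" && spec$metric != "degree")
        spec$scheme else character(0))
  if (spec$kind == "global") {
    net <- cache$global[["tract_count"]]
    colnames(net) <- colnames(cache$global$tract_count) %||%
      paste0("g", seq_len(ncol(net)))
  } else if (spec$metric == "degree") {
    net <- cache$degree
    colnames(net) <- sprintf("degree_n%03d", seq_len(ncol(net)) - 1L)
  } else {
    net <- cache$local[[spec$scheme]][[spec$metric]]
    colnames(net) <- sprintf("%s_n%03d", spec$metric, seq_len(ncol(net)) - 1L)
  }
  if (anyNA(net)) {
    warning(sum(is.na(net)), " undefined metric values mapped to 0")
    net[is.na(net)] <- 0
  }
  clin <- one_hot_clinical(cohort$patients)
  feature_table(cbind(net, clin), cohort$patients$os_class,
                kind = spec$kind)
}

#' Selection-stage configuration
#'
#' @param top_n Filter-consensus rank cutoff.
#' @param min_votes Minimum filter votes for consensus retention.
#' @param wrapper Run the wrapper refinement step.
#' @param wrapper_folds,wrapper_max_stale,wrapper_max_expansions Wrapper
#'   search controls (see [wrapper_select()]).
#' @param relieff_k ReliefF neighborhood size.
#' @param smote Apply SMOTE rebalancing to training data.
#' @param smote_k SMOTE neighborhood size.
#' @return Named list of settings.
#' @export
selection_config <- function(top_n = 50L, min_votes = 3L, wrapper = TRUE,
                             wrapper_folds = 5L, wrapper_max_stale = 5L,
                             wrapper_max_expansions = 20L, relieff_k = 10L,
                             smote = TRUE, smote_k = 5L) {
  list(top_n = top_n, min_votes = min_votes, wrapper = wrapper,
       wrapper_folds = wrapper_folds, wrapper_max_stale = wrapper_max_stale,
       wrapper_max_expansions = wrapper_max_expansions, relieff_k = relieff_k,
       smote = smote, smote_k = smote_k)
}

# Two-step selection on a training table. Local tables: six-filter consensus
# then (optionally) wrapper refinement; global tables: wrapper only (the
# 25-feature set needs no filter triage). Falls back to the consensus set
# (or all features) when a step returns nothing.
select_features <- function(table, classifier, selection, seed) {
  all_feats <- colnames(table$x)
  candidates <- all_feats
  if (table$kind != "global") {
    rk <- filter_bank(table, relieff_k = selection$relieff_k)
    candidates <- consensus_select(rk, selection$top_n, selection$min_votes)
    if (!length(candidates)) candidates <- all_feats
  }
  selected <- candidates
  if (isTRUE(selection$wrapper)) {
    w <- wrapper_select(table, candidates, classifier, seed = seed,
                        n_folds = selection$wrapper_folds,
                        max_stale = selection$wrapper_max_stale,
                        max_expansions = selection$wrapper_max_expansions)
    if (length(w)) selected <- w
    else message("wrapper returned no features; keeping consensus set")
  }
  list(selected = selected, candidates = candidates)
}

#' Leakage-safe nested cross-validation
#'
#' Stratified k-fold cross-validation in which feature selection (filter
#' consensus + wrapper) and SMOTE oversampling are refit inside each
#' training fold; the fold's validation rows are only ever touched at
#' prediction time. Every row index handed to each stage is recorded in an
#' access log so leakage is assertable.
#'
#' @param table A [feature_table()].
#' @param classifier A [classifier_spec()].
#' @param n_folds Number of folds (default 10).
#' @param selection A [selection_config()].
#' @param seed Integer seed; fold assignment depends only on `seed`, so it
#'   is shared across classifiers run at the same seed.
#' @return List of class `cv_result`: pooled `report`, per-fold confusion
#'   matrices and selected-feature manifests, pooled `scores`/`labels`,
#'   fold assignment and `access_log`.
#' @export
nested_cv <- function(table, classifier, n_folds = 10L,
                      selection = selection_config(), seed = 1L) {
  fold <- stratified_folds(table$y, n_folds, seed)
  if (any(tabulate(fold) < 2) ||
      any(vapply(split(table$y, fold), function(yy) length(unique(yy)) < 2,
                 logical(1))))
    stop("a fold lost one of the classes; use fewer folds")
  scores <- numeric(length(table$y)); labels <- table$y
  fold_cms <- list(); manifests <- list(); access_log <- list()
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); va <- which(fold == f)
    train <- subset_rows(table, tr)
    sel <- select_features(train, classifier, selection, seed = seed + 1000L * f)
    train_sel <- feature_table(train$x[, sel$selected, drop = FALSE], train$y,
                               train$kind)
    smote_rows <- nrow(train_sel$x)
    if (isTRUE(selection$smote))
      train_sel <- smote(train_sel, k_neighbors = selection$smote_k,
                         seed = seed + 2000L * f)
    model <- fit_classifier(classifier, train_sel$x, train_sel$y,
                            seed = seed + 3000L * f)
    p <- predict_prob(model, table$x[va, sel$selected, drop = FALSE])
    scores[va] <- p
    fold_cms[[f]] <- confusion_counts(as.integer(p >= 0.5), table$y[va])
    manifests[[f]] <- sel$selected
    access_log[[f]] <- list(train_rows = tr, validation_rows = va,
                            selection_rows = tr, smote_input_rows = tr,
                            fit_rows = tr, smote_original_rows = smote_rows)
  }
  pooled <- performance_report(scores, labels)
  structure(list(classifier = classifier$name, n_folds = n_folds,
                 report = pooled, fold_confusions = fold_cms,
                 fold_features = manifests, scores = scores, labels = labels,
                 fold = fold, access_log = access_log, seed = seed),
            class = "cv_result")
}

#' Train a final model bundle on a development table
#'
#' Runs the two-step selection and SMOTE on the full development set, fits
#' the classifier, and returns a bundle persisting the selected features and
#' fitted state. An empty selection falls back to the full feature set.
#'
#' @inheritParams nested_cv
#' @return List of class `model_bundle` with the fitted model, selected
#'   features, candidate manifest and classifier spec.
#' @export
train_final <- function(table, classifier, selection = selection_config(),
                        seed = 1L) {
  sel <- select_features(table, classifier, selection, seed = seed)
  feats <- sel$selected
  if (!length(feats)) {
    message("empty selected set; falling back to all features")
    feats <- colnames(table$x)
  }
  dev <- feature_table(table$x[, feats, drop = FALSE], table$y, table$kind)
  if (isTRUE(selection$smote))
    dev <- smote(dev, k_neighbors = selection$smote_k, seed = seed + 7L)
  model <- fit_classifier(classifier, dev$x, dev$y, seed = seed + 11L)
  structure(list(model = model, features = feats,
                 candidates = sel$candidates, classifier = classifier,
                 seed = seed),
            class = "model_bundle")
}

#' Save/load a model bundle
#' @param bundle A `model_bundle`.
#' @param path File path.
#' @return [load_bundle()] returns the bundle.
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) readRDS(path)

#' Evaluate a trained bundle on held-out data
#'
#' @param bundle A `model_bundle` from [train_final()].
#' @param table Held-out [feature_table()] sharing the development feature
#'   space.
#' @return A [performance_report()].
#' @export
evaluate_heldout <- function(bundle, table) {
  miss <- setdiff(bundle$features, colnames(table$x))
  if (length(miss))
    stop("held-out table lacks features: ", paste(miss, collapse = ", "))
  p <- predict_prob(bundle$model, table$x[, bundle$features, drop = FALSE])
  performance_report(p, table$y)
}

#' Run the model grid
#'
#' Crosses feature-vector specifications with a classifier roster, runs
#' leakage-safe nested cross-validation for each pair, and ranks results by
#' descending Youden index, then ascending error count. Individual model
#' failures are recorded and the grid continues.
#'
#' @param cohort Development `cohort` (the held-out split is evaluated
#'   separately via [train_final()] / [evaluate_heldout()]).
#' @param roster Named list of [classifier_spec()]s
#'   (default [classifier_roster()]).
#' @param specs data.frame of feature specs
#'   (default [enumerate_feature_specs()]).
#' @param n_folds,selection,seed Passed to [nested_cv()]; the same seed gives
#'   every model the same fold assignment.
#' @param config A [metric_config()] for feature computation.
#' @return List with `results` (ranked data.frame, one row per model, with a
#'   `status` column recording failures) and `details` (the `cv_result`s).
#' @export
run_experiment <- function(cohort, roster = classifier_roster(),
                           specs = enumerate_feature_specs(), n_folds = 10L,
                           selection = selection_config(), seed = 1L,
                           config = metric_config()) {
  cache <- compute_cohort_features(cohort, config,
                                   include_global = "global" %in% specs$kind)
  rows <- list(); details <- list()
  for (si in seq_len(nrow(specs))) {
    spec <- specs[si, ]
    tab <- assemble_features(cohort, spec, cache = cache, config = config)
    for (cl in names(roster)) {
      key <- paste(spec$spec_id, cl, sep = ":")
      cv <- tryCatch(nested_cv(tab, roster[[cl]], n_folds = n_folds,
                               selection = selection, seed = seed),
                     error = function(e) e)
      if (inherits(cv, "error")) {
        rows[[key]] <- data.frame(spec_id = spec$spec_id, classifier = cl,
                                  accuracy = NA_real_, precision = NA_real_,
                                  sensitivity = NA_real_, specificity = NA_real_,
                                  f_score = NA_real_, youden = NA_real_,
                                  auroc = NA_real_, errors = NA_integer_,
                                  total = NA_integer_,
                                  status = paste("failed:", conditionMessage(cv)))
      } else {
        details[[key]] <- cv
        rows[[key]] <- cbind(data.frame(spec_id = spec$spec_id, classifier = cl),
                             report_row(cv$report),
                             data.frame(status = if (is.null(roster[[cl]]$note))
                               "ok" else roster[[cl]]$note))
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- !is.na(results$youden)
  results <- rbind(results[ok, ][order(-results$youden[ok], results$errors[ok]), ],
                   results[!ok, ])
  rownames(results) <- NULL
  list(results = results, details = details)
}
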
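#' Classifier specification
#'
#' The roster mirrors ten common classifier families: naive Bayes (`nb`),
#' logistic regression (`log`), multilayer perceptron (`mp`; one hidden
#' layer with features + classes neurons), support vector machine with
#' polynomial kernel (`svm`), k-nearest neighbors with k = 3 (`knn`),
#' adaptive boosting over decision trees (`ada`), a CART decision tree
#' (`j48`), random forest (`rf`), bootstrap-aggregated trees (`bag`) and
#' `kstar`. The entropic-distance KStar learner has no off-the-shelf R
#' equivalent; its slot is filled by a distance-weighted kNN and the
#' substitution is flagged in the spec (`note` field) and in reports.
#'
#' @param name One of `nb, log, mp, svm, knn, ada, j48, rf, bag, kstar`.
#' @param ... Hyperparameter overrides (e.g. `ntree` for `rf`).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(name, ...) {
  name <- match.arg(name, c("nb", "log", "mp", "svm", "knn", "ada", "j48",
                            "rf", "bag", "kstar"))
  defaults <- switch(name,
    nb = list(),
    log = list(),
    mp = list(decay = 0.1, maxit = 200L),
    svm = list(degree = 3L),
    knn = list(k = 3L),
    ada = list(rounds = 30L),
    j48 = list(cp = 0.01),
    rf = list(ntree = 100L),
    bag = list(n_bags = 25L),
    kstar = list(k = 10L))
  hp <- utils::modifyList(defaults, list(...))
  note <- if (name == "kstar")
    "KStar substituted by distance-weighted kNN" else NULL
  structure(list(name = name, hyper = hp, note = note),
            class = "classifier_spec")
}

#' The full ten-classifier roster
#' @param ... Per-classifier overrides passed as named lists, e.g.
#'   `rf = list(ntree = 100)`.
#' @return Named list of ten [classifier_spec()]s.
#' @export
classifier_roster <- function(...) {
  ov <- list(...)
  names_ <- c("nb", "log", "mp", "svm", "knn", "ada", "j48", "rf", "bag", "kstar")
  specs <- lapply(names_, function(nm)
    do.call(classifier_spec, c(list(name = nm), ov[[nm]])))
  names(specs) <- names_
  specs
}

drop_constant <- function(x) {
  keep <- apply(x, 2L, function(v) stats::sd(v) > 0)
  if (!any(keep)) keep[1] <- TRUE
  x[, keep, drop = FALSE]
}

clip01 <- function(p) pmin(pmax(ifelse(is.finite(p), p, 0.5), 0), 1)

#' Fit a classifier
#'
#' All classifiers share a fit/predict-probability interface; the positive
#' class is survival >= 1 year (`y == 1`). Stochastic learners are seeded
#' for reproducibility.
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param seed Integer seed.
#' @return A fitted model bundle of class `connsurv_model`.
#' @export
fit_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required to fit")
  yf <- factor(y, levels = c(0L, 1L))
  hp <- spec$hyper
  fit <- withr::with_seed(seed, switch(spec$name,
    nb = {
      xd <- drop_constant(x)
      list(kept = colnames(xd),
           m = e1071::naiveBayes(as.data.frame(xd), yf))
    },
    log = {
      df <- as.data.frame(x)
      suppressWarnings(list(m = stats::glm(yf ~ ., data = cbind(df, yf = yf),
                                           family = stats::binomial())))
    },
    mp = {
      size <- ncol(x) + 2L
      list(m = nnet::nnet(x, as.numeric(y), size = size, decay = hp$decay,
                          maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                          MaxNWts = (ncol(x) + 2L) * size + size + 1L + 10000L))
    },
    svm = {
      xd <- drop_constant(x)
      list(kept = colnames(xd),
           m = e1071::svm(xd, yf, kernel = "polynomial", degree = hp$degree,
                          probability = TRUE))
    },
    knn = list(x = x, y = y, k = hp$k,
               ctr = colMeans(x), scl = pmax(apply(x, 2L, stats::sd), 1e-12)),
    ada = fit_adaboost(x, yf, hp$rounds),
    j48 = list(m = rpart::rpart(yf ~ ., data = cbind(as.data.frame(x), yf = yf),
                                method = "class",
                                control = rpart::rpart.control(cp = hp$cp))),
    rf = list(m = ranger::ranger(x = x, y = yf, num.trees = hp$ntree,
                                 probability = TRUE, num.threads = 1L,
                                 seed = seed)),
    bag = fit_bagging(x, yf, hp$n_bags),
    kstar = {
      ctr <- colMeans(x)
      scl <- pmax(apply(x, 2L, stats::sd), 1e-12)
      list(x = sweep(sweep(x, 2L, ctr), 2L, scl, "/"), y = y, k = hp$k,
           ctr = ctr, scl = scl)
    }
  ))
  structure(list(spec = spec, fit = fit, features = colnames(x)),
            class = "connsurv_model")
}

fit_adaboost <- function(x, yf, rounds) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  df <- cbind(as.data.frame(x), yf = yf)
  for (t_ in seq_len(rounds)) {
    m <- rpart::rpart(yf ~ ., data = df, weights = w, method = "class",
                      control = rpart::rpart.control(cp = 0.01))
    pred <- stats::predict(m, df, type = "class")
    err <- sum(w * (pred != yf))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    trees[[t_]] <- m; alphas[t_] <- alpha
    w <- w * exp(alpha * ifelse(pred != yf, 1, -1))
    w <- w / sum(w)
    if (err < 1e-8) break
  }
  list(trees = trees, alphas = alphas)
}

fit_bagging <- function(x, yf, n_bags) {
  n <- nrow(x)
  df <- cbind(as.data.frame(x), yf = yf)
  trees <- lapply(seq_len(n_bags), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(yf[idx])) < 2) idx <- seq_len(n)
    rpart::rpart(yf ~ ., data = df[idx, , drop = FALSE], method = "class",
                 control = rpart::rpart.control(cp = 0, minsplit = 5L))
  })
  list(trees = trees)
}

#' Predict positive-class probabilities
#' @param model A fitted `connsurv_model`.
#' @param x Feature matrix with the training feature columns.
#' @return Numeric vector of probabilities of survival >= 1 year.
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "connsurv_model"))
  x <- as.matrix(x)[, model$features, drop = FALSE]
  fit <- model$fit
  p <- switch(model$spec$name,
    nb = stats::predict(fit$m, as.data.frame(x[, fit$kept, drop = FALSE]),
                        type = "raw")[, "1"],
    log = {
      pr <- stats::predict(fit$m, newdata = as.data.frame(x), type = "response")
      as.numeric(pr)
    },
    mp = as.numeric(stats::predict(fit$m, x)),
    svm = {
      pr <- stats::predict(fit$m, x[, fit$kept, drop = FALSE], probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    knn = {
      xs_tr <- sweep(sweep(fit$x, 2L, fit$ctr), 2L, fit$scl, "/")
      xs_te <- sweep(sweep(x, 2L, fit$ctr), 2L, fit$scl, "/")
      pr <- class::knn(xs_tr, xs_te, factor(fit$y, levels = c(0L, 1L)),
                       k = min(fit$k, nrow(fit$x)), prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    ada = {
      df <- as.data.frame(x)
      num <- Reduce(`+`, Map(function(m, a)
        a * (stats::predict(m, df, type = "class") == "1"),
        fit$trees, as.list(fit$alphas)))
      num / sum(fit$alphas)
    },
    j48 = stats::predict(fit$m, as.data.frame(x), type = "prob")[, "1"],
    rf = stats::predict(fit$m, x, num.threads = 1L)$predictions[, "1"],
    bag = {
      df <- as.data.frame(x)
      pl <- lapply(fit$trees, function(m)
        stats::predict(m, df, type = "prob")[, "1"])
      Reduce(`+`, pl) / length(pl)
    },
    kstar = {
      xs_te <- sweep(sweep(x, 2L, fit$ctr), 2L, fit$scl, "/")
      D <- as.matrix(stats::dist(rbind(xs_te, fit$x)))
      D <- D[seq_len(nrow(xs_te)), nrow(xs_te) + seq_len(nrow(fit$x)),
             drop = FALSE]
      k <- min(fit$k, ncol(D))
      apply(D, 1L, function(d) {
        o <- order(d)[seq_len(k)]
        w <- 1 / (d[o] + 1e-6)
        sum(w * fit$y[o]) / sum(w)
      })
    })
  clip01(as.numeric(p))
}
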
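#' Construct a validated connectivity matrix
#'
#' A structural connectome is stored as a symmetric, nonnegative, zero-diagonal
#' weighted adjacency matrix over a fixed parcellation. Two weighting schemes
#' are supported: `"tract_count"` (integer streamline counts) and `"qa"`
#' (quantitative anisotropy, continuous in (0, 1]).
#'
#' @param weights Square numeric matrix of edge weights.
#' @param scheme Weighting scheme, `"tract_count"` or `"qa"`.
#' @param sym_tol Maximum tolerated asymmetry `max(|W - t(W)|)`; inputs within
#'   tolerance are symmetrized by averaging, larger asymmetries are an error.
#' @return An object of class `connectivity_matrix`: a list with elements
#'   `weights`, `scheme` and `n_nodes`.
#' @export
connectivity_matrix <- function(weights, scheme = c("tract_count", "qa"),
                                sym_tol = 1e-9) {
  scheme <- match.arg(scheme)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectivity matrix must be square, got ", nrow(weights), "x", ncol(weights))
  if (anyNA(weights)) stop("connectivity matrix contains NA/NaN entries")
  if (!is.numeric(weights)) stop("connectivity matrix must be numeric")
  if (any(weights < 0)) stop("connectivity matrix contains negative entries")
  asym <- max(abs(weights - t(weights)))
  if (asym > sym_tol)
    stop("asymmetric connectivity matrix (max |W - t(W)| = ", format(asym), ")")
  weights <- (weights + t(weights)) / 2
  if (max(abs(diag(weights))) > sym_tol)
    stop("connectivity matrix has nonzero diagonal")
  diag(weights) <- 0
  dimnames(weights) <- NULL
  structure(list(weights = weights, scheme = scheme, n_nodes = nrow(weights)),
            class = "connectivity_matrix")
}

#' @exportS3Method base::print
print.connectivity_matrix <- function(x, ...) {
  e <- sum(x$weights > 0) / 2
  cat("<connectivity_matrix> ", x$n_nodes, " nodes, ", e, " edges, scheme = ",
      x$scheme, "\n", sep = "")
  invisible(x)
}

# Accept either a connectivity_matrix or a bare numeric matrix.
as_weights <- function(W) {
  if (inherits(W, "connectivity_matrix")) W$weights else as.matrix(W)
}

#' Read a connectivity matrix from CSV/TSV or MatrixMarket file
#'
#' Dense CSV/TSV files may carry a one-line comment header of the form
#' `# scheme: tract_count`, in which case `scheme` can be omitted.
#' MatrixMarket (`.mtx`) files are read with [Matrix::readMM()] and require an
#' explicit `scheme`.
#'
#' @param path File path.
#' @param scheme Weighting scheme; overrides any header tag if given.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity_matrix <- function(path, scheme = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(scheme)) stop("scheme must be given for MatrixMarket input")
    W <- as.matrix(Matrix::readMM(path))
    return(connectivity_matrix(W, scheme))
  }
  first <- readLines(path, n = 1L)
  if (is.null(scheme)) {
    m <- regmatches(first, regexec("^#\\s*scheme:\\s*(\\w+)", first))[[1]]
    if (length(m) == 2L) scheme <- m[2]
    else stop("no scheme header in ", path, " and no scheme argument given")
  }
  sep <- if (grepl("\t", readLines(path, n = 2L)[2] %||% first)) "\t" else ","
  W <- as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                   comment.char = "#"))
  connectivity_matrix(W, scheme)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Write a connectivity matrix to CSV or MatrixMarket
#'
#' CSV output carries a `# scheme:` header line and full-precision entries so
#' that tract counts round-trip bit-exactly and QA weights round-trip to
#' better than 1e-12.
#'
#' @param x A [connectivity_matrix()].
#' @param path Output path; a `.mtx` extension selects MatrixMarket.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(x, path) {
  stopifnot(inherits(x, "connectivity_matrix"))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(x$weights, sparse = TRUE),
                                "generalMatrix"), path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scheme: ", x$scheme), con)
  rows <- apply(x$weights, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

#' Dichotomize overall survival at one year
#'
#' @param os_days Vector of overall survival times in days (positive).
#' @return Integer vector: 1 if `os_days >= 365` (survival of at least one
#'   year, the positive class), else 0.
#' @export
dichotomize_os <- function(os_days) {
  if (any(is.na(os_days)) || any(os_days < 1))
    stop("os_days must be positive")
  as.integer(os_days >= 365)
}

# Canonical cortical lobe sizes for the 246-region parcellation
# (210 cortical + 36 subcortical).
.lobe_sizes_246 <- c(frontal = 56, temporal = 48, parietal = 42,
                     occipital = 28, insular = 12, limbic = 24,
                     subcortical = 36)

#' Default node metadata table
#'
#' Builds the node table for an `n_nodes`-region parcellation with lobe,
#' hemisphere and cortical/subcortical tier labels. At the default
#' `n_nodes = 246` the table has exactly 210 cortical regions (across six
#' lobes) and 36 subcortical regions; for other sizes lobe blocks are
#' allocated proportionally (largest-remainder rounding). Hemispheres
#' alternate L/R within each lobe.
#'
#' @param n_nodes Number of regions (default 246).
#' @return A data.frame with columns `index` (0-based), `region`, `lobe`,
#'   `hemisphere`, `tier`.
#' @export
default_node_table <- function(n_nodes = 246L) {
  stopifnot(n_nodes >= length(.lobe_sizes_246))
  frac <- .lobe_sizes_246 / sum(.lobe_sizes_246)
  sz <- floor(frac * n_nodes)
  rem <- n_nodes - sum(sz)
  if (rem > 0) {
    o <- order(frac * n_nodes - sz, decreasing = TRUE)
    sz[o[seq_len(rem)]] <- sz[o[seq_len(rem)]] + 1L
  }
  lobe <- rep(names(sz), sz)
  hemi <- unlist(lapply(sz, function(k) rep_len(c("L", "R"), k)),
                 use.names = FALSE)
  within <- unlist(lapply(sz, seq_len), use.names = FALSE)
  data.frame(
    index = seq_len(n_nodes) - 1L,
    region = sprintf("%s_%s_%03d", lobe, hemi, within),
    lobe = lobe,
    hemisphere = hemi,
    tier = ifelse(lobe == "subcortical", "subcortical", "cortical"),
    stringsAsFactors = FALSE
  )
}

#' Assemble a cohort dataset
#'
#' Bundles a patient table, per-patient matrix pairs and the node table, and
#' checks the shared-support invariant: the tract-count and QA matrices of
#' each patient must have identical binary support (so binary metrics agree
#' between schemes).
#'
#' @param patients data.frame with columns `id`, `age`, `sex`,
#'   `extent_of_resection`, `tumor_hemisphere`, `tumor_lobe`, `os_days`;
#'   `os_class` is derived if absent.
#' @param matrices Named list (by patient id) of lists with elements
#'   `tract_count` and `qa`, each a [connectivity_matrix()].
#' @param nodes Node table; default [default_node_table()] at the matrix size.
#' @return An object of class `cohort`.
#' @export
cohort_dataset <- function(patients, matrices, nodes = NULL) {
  stopifnot(is.data.frame(patients), all(c("id", "os_days") %in% names(patients)))
  patients$id <- as.character(patients$id)
  if (is.null(patients$os_class)) patients$os_class <- dichotomize_os(patients$os_days)
  stopifnot(all(patients$os_class == dichotomize_os(patients$os_days)))
  miss <- setdiff(patients$id, names(matrices))
  if (length(miss)) stop("missing matrices for patients: ", paste(miss, collapse = ", "))
  n_nodes <- matrices[[patients$id[1]]]$tract_count$n_nodes
  for (id in patients$id) {
    pr <- matrices[[id]]
    stopifnot(inherits(pr$tract_count, "connectivity_matrix"),
              inherits(pr$qa, "connectivity_matrix"))
    if (!identical(pr$tract_count$weights > 0, pr$qa$weights > 0))
      stop("tract-count and QA matrices of patient ", id,
           " do not share binary support")
  }
  if (is.null(nodes)) nodes <- default_node_table(n_nodes)
  stopifnot(nrow(nodes) == n_nodes)
  structure(list(patients = patients, matrices = matrices[patients$id],
                 nodes = nodes, n_nodes = n_nodes),
            class = "cohort")
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$patients), " patients, ", x$n_nodes,
      "-node parcellation, prevalence(OS >= 1y) = ",
      round(mean(x$patients$os_class), 3), "\n", sep = "")
  invisible(x)
}

#' Subset a cohort by patient position
#' @param cohort A `cohort`.
#' @param idx Integer positions into the patient table.
#' @return A `cohort` restricted to those patients.
#' @export
subset_cohort <- function(cohort, idx) {
  p <- cohort$patients[idx, , drop = FALSE]
  rownames(p) <- NULL
  structure(list(patients = p, matrices = cohort$matrices[p$id],
                 nodes = cohort$nodes, n_nodes = cohort$n_nodes),
            class = "cohort")
}

#' Randomly split a cohort into development and held-out sets
#'
#' The held-out size is `round(n * test_fraction)` with round-half-up, so a
#' cohort of 871 at `test_fraction = 0.10` yields 784 development and 87
#' held-out patients. The partition is disjoint, exhaustive and reproducible
#' under a fixed seed.
#'
#' @param cohort A `cohort`.
#' @param test_fraction Fraction held out, in (0, 1).
#' @param seed Integer RNG seed.
#' @return List with elements `development` and `heldout`, both `cohort`s.
#' @export
split_cohort <- function(cohort, test_fraction = 0.1, seed = 1L) {
  n <- nrow(cohort$patients)
  if (n < 2) stop("cohort must contain at least 2 patients")
  stopifnot(test_fraction > 0, test_fraction < 1)
  n_test <- as.integer(floor(n * test_fraction + 0.5))
  n_test <- max(1L, min(n - 1L, n_test))
  idx_test <- withr::with_seed(seed, sort(sample.int(n, n_test)))
  list(development = subset_cohort(cohort, setdiff(seq_len(n), idx_test)),
       heldout = subset_cohort(cohort, idx_test))
}

#' Write a cohort's matrices and tables to a directory
#'
#' Emits one CSV per patient per scheme plus `patients.csv` and `nodes.csv`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(cohort$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  for (id in cohort$patients$id) {
    write_connectivity_matrix(cohort$matrices[[id]]$tract_count,
                              file.path(dir, paste0(id, "_tract_count.csv")))
    write_connectivity_matrix(cohort$matrices[[id]]$qa,
                              file.path(dir, paste0(id, "_qa.csv")))
  }
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#' @param dir Directory containing `patients.csv`, `nodes.csv` and matrices.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              colClasses = c(id = "character"))
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"))
  matrices <- lapply(patients$id, function(id) list(
    tract_count = read_connectivity_matrix(file.path(dir, paste0(id, "_tract_count.csv"))),
    qa = read_connectivity_matrix(file.path(dir, paste0(id, "_qa.csv")))))
  names(matrices) <- patients$id
  cohort_dataset(patients, matrices, nodes)
}
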
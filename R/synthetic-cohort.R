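#' Synthetic cohort generator configuration
#'
#' Defaults emulate the study conditions of a pooled glioblastoma cohort on a
#' 246-region parcellation: age ~ Normal(62.9, 11.8) truncated to \[21, 94\]
#' years, 40.8% female, extent of resection GTR/STR/NA at 57.3/38.3/4.4%,
#' a hub-targeted temporal-lobe lesion whose severity (with age) drives the
#' one-year survival label through a logistic model, and paired tract-count /
#' QA matrices sharing binary support.
#'
#' @param n_patients Number of patients.
#' @param n_nodes Parcellation size (default 246).
#' @param hub_fraction Fraction of nodes designated as cross-module hubs.
#' @param p_in,p_out Within-/between-module edge probabilities.
#' @param p_hub Edge probability between a hub and any other module.
#' @param tract_meanlog,tract_sdlog Log-normal law for tract counts
#'   (rounded to integers >= 1 on present edges).
#' @param qa_jitter_sd Gaussian jitter added to the monotone tract->QA map
#'   `qa = w / (w + median(w))`, clipped to (0, 1].
#' @param lesion_lobe Lobe label hosting the lesion block.
#' @param lesion_size Number of lesioned nodes.
#' @param severity_shape1,severity_shape2 Beta law for lesion severity
#'   (default Beta(1, 1): uniform — disruption spans the full range).
#' @param beta0,beta_sev,beta_age Logistic label model coefficients:
#'   `p = plogis(beta0 - beta_sev * s - beta_age * (age - 62.9)/11.8)`.
#' @param prevalence_target Optional target prevalence of the positive class,
#'   enforced by per-patient rejection; `NULL` leaves the natural rate.
#' @param tract_floor Attenuated tract weight below which a lesioned edge is
#'   removed from both supports.
#' @param seed Integer RNG seed fixing the whole cohort.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 100L, n_nodes = 246L,
                             hub_fraction = 0.10, p_in = 0.35, p_out = 0.05,
                             p_hub = 0.25, tract_meanlog = 3, tract_sdlog = 1,
                             qa_jitter_sd = 0.02, lesion_lobe = "temporal",
                             lesion_size = 12L, severity_shape1 = 1,
                             severity_shape2 = 1, beta0 = 2, beta_sev = 4,
                             beta_age = 0.8, prevalence_target = NULL,
                             tract_floor = 1, seed = 1L) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1, p_hub >= 0,
            p_hub <= 1, hub_fraction >= 0, hub_fraction <= 1,
            lesion_size < n_nodes, n_patients >= 1)
  structure(as.list(environment()), class = "generator_config")
}

# Hubs: spread over modules, taking the first ceil(hub_fraction * size)
# nodes of each lobe block (deterministic given the node table).
designate_hubs <- function(nodes, hub_fraction) {
  unlist(lapply(split(nodes$index, nodes$lobe), function(ix) {
    k <- ceiling(hub_fraction * length(ix))
    sort(ix)[seq_len(k)]
  }), use.names = FALSE) + 1L  # 1-based
}

#' Generate one paired tract-count/QA base connectome
#'
#' Block-structured binary support (dense within lobe modules, sparse
#' between, hubs wired across modules), log-normal integer tract counts, and
#' QA derived from tract count by the bounded monotone map
#' `qa = w / (w + median(w))` plus clipped Gaussian jitter. The two matrices
#' share binary support by construction.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed for this matrix pair.
#' @param nodes Optional node table (defaults to the config's parcellation).
#' @return List with elements `tract_count` and `qa`.
#' @export
generate_base_connectome <- function(config, seed = config$seed,
                                     nodes = default_node_table(config$n_nodes)) {
  withr::with_seed(seed, {
    n <- config$n_nodes
    module <- match(nodes$lobe, unique(nodes$lobe))
    hubs <- designate_hubs(nodes, config$hub_fraction)
    same <- outer(module, module, "==")
    P <- ifelse(same, config$p_in, config$p_out)
    is_hub <- seq_len(n) %in% hubs
    hub_pair <- outer(is_hub, rep(TRUE, n), "&") | outer(rep(TRUE, n), is_hub, "&")
    P[hub_pair & !same] <- pmax(P[hub_pair & !same], config$p_hub)
    up <- upper.tri(P)
    supp <- matrix(FALSE, n, n)
    supp[up] <- stats::runif(sum(up)) < P[up]
    ne <- sum(supp)
    w <- pmax(1, round(stats::rlnorm(ne, config$tract_meanlog, config$tract_sdlog)))
    Wtc <- matrix(0, n, n)
    Wtc[up][supp[up]] <- w
    Wtc <- Wtc + t(Wtc)
    med <- stats::median(w)
    qa <- w / (w + med) + stats::rnorm(ne, 0, config$qa_jitter_sd)
    qa <- pmin(pmax(qa, 1e-4), 1)
    Wqa <- matrix(0, n, n)
    Wqa[up][supp[up]] <- qa
    Wqa <- Wqa + t(Wqa)
    list(tract_count = connectivity_matrix(Wtc, "tract_count"),
         qa = connectivity_matrix(Wqa, "qa"))
  })
}

#' Attenuate edges incident to a lesion
#'
#' Every edge touching a lesion node has both its tract-count and QA weights
#' multiplied by `(1 - s * u)` with `u ~ Uniform(0.5, 1)` drawn once per
#' edge; edges whose attenuated tract weight falls below `floor` are removed
#' from both supports jointly. Edges not incident to the lesion are
#' untouched.
#'
#' @param pair List with `tract_count` and `qa` matrices.
#' @param lesion_nodes 1-based node indices of the lesion.
#' @param severity Severity `s` in \[0, 1\].
#' @param floor Removal threshold on the attenuated tract weight.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return The attenuated pair.
#' @export
apply_tumor_disruption <- function(pair, lesion_nodes, severity, floor = 1,
                                   seed = NULL) {
  stopifnot(severity >= 0, severity <= 1)
  run <- function() {
    Wtc <- pair$tract_count$weights
    Wqa <- pair$qa$weights
    n <- nrow(Wtc)
    if (any(lesion_nodes < 1 | lesion_nodes > n))
      stop("lesion node out of range")
    if (severity == 0) return(pair)
    hit <- matrix(FALSE, n, n)
    hit[lesion_nodes, ] <- TRUE
    hit[, lesion_nodes] <- TRUE
    idx <- which(hit & upper.tri(Wtc) & Wtc > 0)
    if (length(idx)) {
      u <- stats::runif(length(idx), 0.5, 1)
      f <- 1 - severity * u
      tc_new <- Wtc[idx] * f
      drop <- tc_new < floor
      Wtc[idx] <- ifelse(drop, 0, pmax(1, round(tc_new)))
      Wqa[idx] <- ifelse(drop, 0, pmin(pmax(Wqa[idx] * f, 1e-4), 1))
      Wtc[lower.tri(Wtc)] <- t(Wtc)[lower.tri(Wtc)]
      Wqa[lower.tri(Wqa)] <- t(Wqa)[lower.tri(Wqa)]
    }
    list(tract_count = connectivity_matrix(Wtc, "tract_count"),
         qa = connectivity_matrix(Wqa, "qa"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# os_days coherent with the class label around the 365-day threshold:
# 365 * exp(z), z ~ N(+/- 0.5, 0.4) signed by class, resampled on crossing.
draw_os_days <- function(os_class) {
  repeat {
    z <- stats::rnorm(1, if (os_class == 1) 0.5 else -0.5, 0.4)
    d <- max(1L, as.integer(round(365 * exp(z))))
    if (dichotomize_os(d) == os_class) return(d)
  }
}

#' Generate a synthetic cohort with ground truth
#'
#' Per patient: draws age and lesion severity, builds a base connectome,
#' applies hub-targeted disruption in the configured lobe, and samples the
#' one-year survival class from
#' `p = plogis(beta0 - beta_sev * s - beta_age * (age - 62.9)/11.8)`, with
#' overall-survival days drawn coherently with the class. Sex, extent of
#' resection and tumor laterality follow the configured cohort frequencies.
#' An optional prevalence target is enforced by per-patient rejection.
#'
#' @param config A [generator_config()].
#' @return List with elements `cohort` (a `cohort`) and `truth` (data.frame
#'   with per-patient lesion nodes, severity, linear predictor and class
#'   probability — never consumed by the pipeline).
#' @export
generate_cohort <- function(config) {
  nodes <- default_node_table(config$n_nodes)
  lobe_nodes <- nodes$index[nodes$lobe == config$lesion_lobe] + 1L
  if (length(lobe_nodes) < config$lesion_size)
    stop("lesion_size exceeds the size of the lesion lobe")
  hubs <- designate_hubs(nodes, config$hub_fraction)
  target <- config$prevalence_target
  quota <- if (!is.null(target))
    c(`1` = round(config$n_patients * target),
      `0` = config$n_patients - round(config$n_patients * target))
  withr::with_seed(config$seed, {
    patients <- vector("list", config$n_patients)
    matrices <- vector("list", config$n_patients)
    truth <- vector("list", config$n_patients)
    taken <- c(`1` = 0L, `0` = 0L)
    tries <- 0L
    i <- 1L
    while (i <= config$n_patients) {
      tries <- tries + 1L
      if (tries > 200L * config$n_patients)
        stop("unattainable prevalence target")
      age <- rtrunc_norm(1, 62.9, 11.8, 21, 94)
      s <- stats::rbeta(1, config$severity_shape1, config$severity_shape2)
      eta <- config$beta0 - config$beta_sev * s -
        config$beta_age * (age - 62.9) / 11.8
      p <- stats::plogis(eta)
      cls <- stats::rbinom(1, 1, p)
      if (!is.null(target) && taken[as.character(cls)] >= quota[as.character(cls)])
        next
      pair <- generate_base_connectome(config,
                                       seed = sample.int(.Machine$integer.max, 1),
                                       nodes = nodes)
      wts <- 1 + 4 * (lobe_nodes %in% hubs)  # hub-targeted lesion sampling
      lesion <- sort(sample(lobe_nodes, config$lesion_size, prob = wts))
      pair <- apply_tumor_disruption(pair, lesion, s, floor = config$tract_floor)
      os <- draw_os_days(cls)
      id <- sprintf("SYN-%04d", i)
      patients[[i]] <- data.frame(
        id = id, age = age,
        sex = sample(c("F", "M"), 1, prob = c(0.408, 0.592)),
        extent_of_resection = sample(c("GTR", "STR", "NA"), 1,
                                     prob = c(0.573, 0.383, 0.044)),
        tumor_hemisphere = sample(c("L", "R"), 1),
        tumor_lobe = config$lesion_lobe,
        os_days = os, os_class = cls, stringsAsFactors = FALSE)
      matrices[[i]] <- pair
      truth[[i]] <- data.frame(
        id = id, severity = s, eta = eta, prob = p,
        lesion_nodes = paste(lesion - 1L, collapse = ";"),
        stringsAsFactors = FALSE)
      taken[as.character(cls)] <- taken[as.character(cls)] + 1L
      i <- i + 1L
    }
    patients <- do.call(rbind, patients)
    names(matrices) <- patients$id
    list(cohort = cohort_dataset(patients, matrices, nodes),
         truth = do.call(rbind, truth))
  })
}
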
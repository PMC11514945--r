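#' Simulate an annotated single-cell reference with planted markers
#'
#' Generates negative-binomial UMI counts for a configurable number of
#' fetal and adult cell states. Each state owns a disjoint block of marker
#' genes whose mean is multiplied by `marker_fc`; all other genes share a
#' log-normal baseline mean profile scaled so the expected per-cell total
#' is `target_total` UMIs. The returned truth record makes every fixture
#' reproducible.
#'
#' @param n_fetal_states,n_adult_states number of fetal/adult states.
#' @param n_genes total genes.
#' @param n_cells_per_state cells per state.
#' @param n_markers_per_state planted exclusive markers per state
#'   (disjoint blocks; total must not exceed `n_genes`).
#' @param marker_fc fold change of marker means in their own state.
#' @param nb_dispersion negative-binomial dispersion (variance = mean +
#'   mean^2 * dispersion).
#' @param target_total expected UMI total per cell.
#' @param tissue tissue label used in annotations.
#' @param seed integer seed.
#' @return `list(reference = SingleCellReference, truth = list(...))`;
#'   `truth` carries the state mean profiles, marker blocks, parameters
#'   and seed.
#' @export
simulateReference <- function(n_fetal_states = 4, n_adult_states = 4,
                              n_genes = 2000, n_cells_per_state = 200,
                              n_markers_per_state = 25, marker_fc = 8,
                              nb_dispersion = 0.5, target_total = 3000,
                              tissue = "synthetic", seed = 1) {
  K <- n_fetal_states + n_adult_states
  if (n_markers_per_state * K > n_genes)
    stop("marker blocks exceed the gene count")
  genes <- sprintf("G%05d", seq_len(n_genes))
  states <- c(sprintf("fetal_state%02d", seq_len(n_fetal_states)),
              sprintf("adult_state%02d", seq_len(n_adult_states)))
  stage <- rep(c("fetal", "adult"), c(n_fetal_states, n_adult_states))
  base_mu <- .withSeed(splitSeed(seed, "base_mu"),
                       rlnorm(n_genes, meanlog = 0, sdlog = 1))
  markers <- lapply(seq_len(K), function(k)
    genes[((k - 1L) * n_markers_per_state + 1L):(k * n_markers_per_state)])
  names(markers) <- states
  # per-state expected mean profile, scaled to the target library size
  mu <- vapply(seq_len(K), function(k) {
    m <- base_mu
    m[genes %in% markers[[k]]] <- m[genes %in% markers[[k]]] * marker_fc
    m / sum(m) * target_total
  }, numeric(n_genes))
  dimnames(mu) <- list(genes, states)
  counts <- matrix(0L, n_genes, K * n_cells_per_state)
  cell_ids <- character(ncol(counts))
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * n_cells_per_state + 1L):(k * n_cells_per_state)
    counts[, idx] <- .withSeed(
      splitSeed(seed, paste0("counts|", states[k])),
      matrix(rnbinom(n_genes * n_cells_per_state, mu = mu[, k],
                     size = 1 / nb_dispersion),
             n_genes, n_cells_per_state))
    cell_ids[idx] <- sprintf("%s_c%04d", states[k], seq_len(n_cells_per_state))
  }
  dimnames(counts) <- list(genes, cell_ids)
  ann <- data.frame(
    cell_id = cell_ids,
    tissue = tissue,
    cell_type = rep(states, each = n_cells_per_state),
    stage = rep(stage, each = n_cells_per_state),
    donor = rep(c("d1", "d2"), length.out = ncol(counts)),
    stringsAsFactors = FALSE)
  truth <- list(states = states, stage = setNames(stage, states),
                markers = markers, mean_profiles = mu,
                params = list(n_fetal_states = n_fetal_states,
                              n_adult_states = n_adult_states,
                              n_genes = n_genes,
                              n_cells_per_state = n_cells_per_state,
                              n_markers_per_state = n_markers_per_state,
                              marker_fc = marker_fc,
                              nb_dispersion = nb_dispersion,
                              target_total = target_total),
                seed = seed)
  list(reference = SingleCellReference(counts, ann), truth = truth)
}

#' Simulate bulk mixtures with known cell-state fractions
#'
#' Draws per-sample fraction vectors from a symmetric Dirichlet, mixes the
#' supplied state profiles accordingly, applies optional multiplicative
#' log-normal noise per gene and sample, and renormalizes every sample to
#' TPM.
#'
#' @param profiles genes x states matrix of state mean profiles (e.g. from
#'   [stateMeanCPM()] or a simulated truth).
#' @param n_samples number of bulk samples.
#' @param dirichlet_alpha symmetric Dirichlet concentration (> 0).
#' @param noise_sigma standard deviation of the log-normal noise
#'   (`exp(N(0, sigma^2))`); 0 for noiseless mixtures.
#' @param seed integer seed.
#' @return `list(bulk = BulkExpression (TPM), fractions = samples x states
#'   true fraction matrix)`.
#' @export
simulateMixtures <- function(profiles, n_samples = 200, dirichlet_alpha = 1,
                             noise_sigma = 0, seed = 1) {
  stopifnot(dirichlet_alpha > 0, n_samples >= 1)
  profiles <- as.matrix(profiles)
  K <- ncol(profiles)
  f <- .withSeed(splitSeed(seed, "fractions"), {
    g <- matrix(rgamma(n_samples * K, shape = dirichlet_alpha), n_samples, K)
    g / rowSums(g)
  })
  colnames(f) <- colnames(profiles)
  rownames(f) <- sprintf("sample%04d", seq_len(n_samples))
  mix <- profiles %*% base::t(f)
  if (noise_sigma > 0) {
    noise <- .withSeed(splitSeed(seed, "noise"),
                       matrix(exp(rnorm(length(mix), 0, noise_sigma)),
                              nrow(mix), ncol(mix)))
    mix <- mix * noise
  }
  mix <- sweep(mix, 2L, colSums(mix), "/") * 1e6
  colnames(mix) <- rownames(f)
  list(bulk = BulkExpression(mix, unit = "TPM"), fractions = f)
}

#' Simulate a survival cohort driven by the fetalness index
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(beta * fetalness)`; independent exponential
#' censoring is calibrated so the expected censored fraction equals
#' `censor_rate` (solved from the closed-form per-sample censoring
#' probability `c / (c + rate_i)`).
#'
#' @param fetalness named numeric vector of per-sample index values.
#' @param beta log-hazard ratio per unit of fetalness.
#' @param baseline_hazard baseline exponential event rate.
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return A `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
simulateSurvivalCohort <- function(fetalness, beta = 0,
                                   baseline_hazard = 0.01, censor_rate = 0.3,
                                   seed = 1) {
  stopifnot(censor_rate >= 0, censor_rate < 1)
  rate <- baseline_hazard * exp(beta * fetalness)
  cens_rate <- if (censor_rate == 0) 0 else
    stats::uniroot(function(cc) mean(cc / (cc + rate)) - censor_rate,
                   interval = c(1e-12, 1e6 * max(rate)), tol = 1e-12)$root
  .withSeed(splitSeed(seed, "survival"), {
    t_event <- rexp(length(rate), rate = rate)
    t_cens <- if (cens_rate > 0) rexp(length(rate), rate = cens_rate) else
      rep(Inf, length(rate))
    data.frame(
      sample_id = names(fetalness) %||% sprintf("s%04d", seq_along(rate)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE)
  })
}

#' Simulate an expression/index design with one planted enriched set
#'
#' The index is uniform over samples; the genes of the `COUPLED` set have
#' expression `exp(coupling * index + N(0, noise_sd))`, all other genes are
#' index-independent log-normal noise. Decoy sets of the same size are
#' drawn from the non-coupled genes. Samples are TPM-normalized.
#'
#' @param n_genes,n_samples problem size.
#' @param coupled_set_size genes in the planted set.
#' @param coupling linear coupling strength on the log scale (0 = null).
#' @param noise_sd log-scale noise standard deviation.
#' @param n_decoy_sets number of random decoy sets.
#' @param seed integer seed.
#' @return `list(expr = BulkExpression (TPM), index, collection, truth)`.
#' @export
simulateEnrichmentDesign <- function(n_genes = 1500, n_samples = 100,
                                     coupled_set_size = 50, coupling = 2,
                                     noise_sd = 1, n_decoy_sets = 20,
                                     seed = 1) {
  stopifnot(coupled_set_size < n_genes)
  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- sprintf("s%04d", seq_len(n_samples))
  index <- .withSeed(splitSeed(seed, "index"),
                     setNames(runif(n_samples), samples))
  expr <- .withSeed(splitSeed(seed, "expr"), {
    e <- matrix(exp(rnorm(n_genes * n_samples, 0, noise_sd)),
                n_genes, n_samples)
    e[seq_len(coupled_set_size), ] <- e[seq_len(coupled_set_size), ] *
      exp(coupling * matrix(index, coupled_set_size, n_samples, byrow = TRUE))
    e
  })
  dimnames(expr) <- list(genes, samples)
  expr <- sweep(expr, 2L, colSums(expr), "/") * 1e6
  coupled <- genes[seq_len(coupled_set_size)]
  decoys <- .withSeed(splitSeed(seed, "decoys"), {
    lapply(seq_len(n_decoy_sets), function(i)
      sample(setdiff(genes, coupled), coupled_set_size))
  })
  names(decoys) <- sprintf("DECOY%02d", seq_len(n_decoy_sets))
  collection <- c(list(COUPLED = coupled), decoys)
  list(expr = BulkExpression(expr, unit = "TPM"), index = index,
       collection = collection,
       truth = list(coupled = coupled, coupling = coupling,
                    noise_sd = noise_sd, seed = seed))
}
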
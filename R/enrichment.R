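#' Spearman correlation of every gene with the fetalness index
#'
#' Computes the Spearman rank correlation between each gene's TPM
#' expression and the per-sample fetalness index (average ranks for ties).
#' Constant genes have no defined correlation; they are excluded and
#' logged.
#'
#' @param expr a [BulkExpression-class] object (TPM) or genes x samples
#'   matrix.
#' @param index named fetalness vector covering the expression samples.
#' @return Named numeric vector of Spearman rho per gene.
#' @export
correlateWithIndex <- function(expr, index) {
  v <- if (methods::is(expr, "BulkExpression")) assay(expr, "exprs") else
    as.matrix(expr)
  if (!is.null(names(index))) {
    shared <- intersect(colnames(v), names(index))
    if (length(shared) < ncol(v))
      .log("correlateWithIndex: %d sample(s) without index dropped",
           ncol(v) - length(shared))
    v <- v[, shared, drop = FALSE]
    index <- index[shared]
  }
  if (ncol(v) < 3L) stop("need >= 3 samples")
  rho <- suppressWarnings(
    as.vector(cor(base::t(v), index, method = "spearman")))
  names(rho) <- rownames(v)
  bad <- is.na(rho)
  if (any(bad))
    .log("correlateWithIndex: %d constant gene(s) excluded", sum(bad))
  rho[!bad]
}

#' Rank genes by correlation and split into equal bins
#'
#' Genes are sorted ascending by rho (ties broken by gene id) and divided
#' into `n_bins` contiguous equal-size bins; any remainder is distributed
#' to the last bins. Bin 1 holds the most negatively correlated genes, bin
#' `n_bins` the most positively correlated.
#'
#' @param rho named vector of per-gene correlations.
#' @param n_bins number of bins (default 15).
#' @return `list(genes, rho, bin, n_bins)` with elements ordered by rank;
#'   class `correlation_ranking`.
#' @export
binGeneRanks <- function(rho, n_bins = 15) {
  n <- length(rho)
  if (n < n_bins) stop("fewer genes (", n, ") than bins (", n_bins, ")")
  ord <- order(rho, names(rho))
  base_size <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base_size, n_bins)
  if (rem > 0)
    sizes[(n_bins - rem + 1L):n_bins] <- base_size + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  structure(list(genes = names(rho)[ord], rho = unname(rho[ord]), bin = bin,
                 n_bins = n_bins),
            class = "correlation_ranking")
}

# member counts per bin for a gene set (dropping genes outside the universe)
.binMemberCounts <- function(ranking, geneset) {
  member <- ranking$genes %in% geneset
  if (!any(member))
    stop("gene set has no overlap with the ranked gene universe")
  tabulate(ranking$bin[member], nbins = ranking$n_bins)
}

# plug-in MI (bits) from per-bin member counts k, bin sizes nb, total n
.miFromCounts <- function(k, nb) {
  n <- sum(nb)
  m <- sum(k)
  mi <- 0
  for (cell in list(cbind(k, nb * (m / n)),
                    cbind(nb - k, nb * ((n - m) / n)))) {
    obs <- cell[, 1L] / n
    expd <- cell[, 2L] / n
    nz <- obs > 0
    mi <- mi + sum(obs[nz] * log2(obs[nz] / expd[nz]))
  }
  mi
}

#' Mutual information between gene bins and set membership
#'
#' Plug-in discrete mutual information (in bits) between the bin variable
#' and the membership indicator over the ranked gene universe:
#' `MI = sum_bm p(b,m) log2(p(b,m) / (p(b) p(m)))` with `0 log 0 = 0`.
#' Genes of the set outside the universe are ignored.
#'
#' @param ranking a `correlation_ranking` from [binGeneRanks()].
#' @param geneset character vector of gene ids.
#' @return MI in bits (>= 0).
#' @export
genesetMI <- function(ranking, geneset) {
  stopifnot(inherits(ranking, "correlation_ranking"))
  k <- .binMemberCounts(ranking, geneset)
  nb <- tabulate(ranking$bin, nbins = ranking$n_bins)
  .miFromCounts(k, nb)
}

#' Permutation p-value for a gene set's MI
#'
#' Null MI values are generated by shuffling the gene-to-bin assignment
#' with the membership size fixed (equivalently: drawing the same number of
#' member genes uniformly without replacement). The p-value uses the
#' add-one estimator `p = (1 + #{MI_null >= MI_obs}) / (1 + n_perm)`.
#'
#' @param ranking a `correlation_ranking`.
#' @param geneset character vector of gene ids.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return `list(p, mi, n_perm)`.
#' @export
miPermutationPvalue <- function(ranking, geneset, n_perm = 10000, seed = 1) {
  stopifnot(n_perm >= 100)
  k <- .binMemberCounts(ranking, geneset)
  nb <- tabulate(ranking$bin, nbins = ranking$n_bins)
  mi_obs <- .miFromCounts(k, nb)
  m <- sum(k)
  n <- sum(nb)
  hits <- .withSeed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, m)
      mi0 <- .miFromCounts(tabulate(ranking$bin[idx], nbins = ranking$n_bins),
                           nb)
      if (mi0 >= mi_obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(p = (1 + hits) / (1 + n_perm), mi = mi_obs, n_perm = n_perm)
}

#' Direction of an enrichment and its per-bin profile
#'
#' The per-bin profile is `log2((observed members + 0.5) / (expected +
#' 0.5))`; the sign is the sign of the Spearman correlation between the bin
#' index and the profile: +1 when the set concentrates among genes
#' positively correlated with the index, -1 for the negative side, 0 for a
#' flat profile.
#'
#' @param ranking a `correlation_ranking`.
#' @param geneset character vector of gene ids.
#' @return `list(sign, profile)`.
#' @export
enrichmentSign <- function(ranking, geneset) {
  k <- .binMemberCounts(ranking, geneset)
  nb <- tabulate(ranking$bin, nbins = ranking$n_bins)
  expd <- nb * (sum(k) / sum(nb))
  profile <- log2((k + 0.5) / (expd + 0.5))
  if (max(abs(profile)) < 1e-9 || sd(profile) == 0)
    return(list(sign = 0L, profile = profile))
  rho <- cor(seq_along(profile), profile, method = "spearman")
  list(sign = as.integer(sign(rho)), profile = profile)
}

#' MI enrichment of a gene-set collection against the fetalness index
#'
#' Runs the full information-theoretic enrichment for every set in the
#' collection: Spearman correlation of each gene with the index, rank
#' binning, plug-in MI, permutation p-value, per-bin profile and sign.
#' P-values are Benjamini-Hochberg adjusted across sets. Per-set seeds are
#' derived from `seed` and the set name, so results are deterministic and
#' independent of collection order.
#'
#' @param expr a [BulkExpression-class] object (TPM) or genes x samples
#'   matrix.
#' @param index named fetalness vector.
#' @param collection named list of gene sets (e.g. from [readGmt()]).
#' @param n_bins number of rank bins.
#' @param n_perm permutations per set.
#' @param seed master seed.
#' @param fdr_alpha significance level applied to the BH-adjusted p-values
#'   for the `significant` flag.
#' @return A `data.frame` with one row per set: `set`, `n_genes_used`,
#'   `mi_bits`, `pvalue`, `fdr`, `sign`, `significant`, `profile`
#'   (semicolon-joined per-bin log2 ratios).
#' @export
enrichCollection <- function(expr, index, collection, n_bins = 15,
                             n_perm = 10000, seed = 1, fdr_alpha = 0.05) {
  rho <- correlateWithIndex(expr, index)
  ranking <- binGeneRanks(rho, n_bins = n_bins)
  rows <- lapply(names(collection), function(nm) {
    gs <- intersect(collection[[nm]], ranking$genes)
    if (!length(gs)) {
      .log("enrichCollection: set '%s' has no gene in the universe; skipped",
           nm)
      return(NULL)
    }
    pv <- miPermutationPvalue(ranking, gs, n_perm = n_perm,
                              seed = splitSeed(seed, nm))
    sg <- enrichmentSign(ranking, gs)
    data.frame(set = nm, n_genes_used = length(gs), mi_bits = pv$mi,
               pvalue = pv$p, sign = sg$sign,
               profile = paste(.fmtNum(sg$profile), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) stop("no gene set overlaps the ranked universe")
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  out$significant <- out$fdr < fdr_alpha
  out[, c("set", "n_genes_used", "mi_bits", "pvalue", "fdr", "sign",
          "significant", "profile")]
}
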
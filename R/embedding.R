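#' Embedding pipeline parameters
#'
#' Bundles the preprocessing and embedding knobs: the dispersion-based
#' highly-variable-gene window (`hvg_min_mean`, `hvg_max_mean`,
#' `hvg_min_dispersion` on the log1p scale), the scaling clip value, the
#' number of principal components computed (`n_pcs`) and used for
#' neighbor distances (`n_pcs_distance`), UMAP settings and the
#' mitochondrial gene prefix used for the covariate.
#'
#' @param hvg_max_mean,hvg_min_mean mean-expression window for HVG selection.
#' @param hvg_min_dispersion lower cutoff on the bin-normalized dispersion.
#' @param scale_clip upper clip applied after unit-variance scaling.
#' @param n_pcs number of principal components.
#' @param n_pcs_distance components used for Euclidean neighbor distances.
#' @param umap_seed seed for the UMAP layout.
#' @param umap_neighbors,umap_min_dist UMAP hyperparameters.
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @return A validated list of class `embedding_params`.
#' @export
embeddingParams <- function(hvg_max_mean = 3, hvg_min_mean = 0.0125,
                            hvg_min_dispersion = 0.5, scale_clip = 10,
                            n_pcs = 50, n_pcs_distance = 10, umap_seed = 42,
                            umap_neighbors = 15, umap_min_dist = 0.1,
                            mito_prefix = "MT-") {
  stopifnot(hvg_min_mean < hvg_max_mean, n_pcs_distance <= n_pcs,
            scale_clip > 0, n_pcs >= 2)
  structure(list(hvg_max_mean = hvg_max_mean, hvg_min_mean = hvg_min_mean,
                 hvg_min_dispersion = hvg_min_dispersion,
                 scale_clip = scale_clip, n_pcs = n_pcs,
                 n_pcs_distance = n_pcs_distance, umap_seed = umap_seed,
                 umap_neighbors = umap_neighbors,
                 umap_min_dist = umap_min_dist, mito_prefix = mito_prefix),
            class = "embedding_params")
}

#' CP10K normalization, replicate averaging and log1p transform
#'
#' Normalizes raw counts to counts-per-10K per cell, optionally averages the
#' normalized profiles within (cell type x replicate/donor) groups when
#' annotations are supplied, and applies `log1p`. The total-count and
#' mitochondrial-percentage covariates are computed on the raw counts
#' before normalization (and averaged within groups alongside).
#'
#' @param counts genes x units raw count matrix (or a
#'   [SingleCellReference-class]).
#' @param annotations optional annotation source; when given, profiles are
#'   averaged within `cell_type` x `donor` x `stage` groups.
#' @param params an [embeddingParams()] list.
#' @return `list(matrix = log1p CP10K matrix, covariates = data.frame(
#'   total_count, mito_pct))`.
#' @export
preprocessEmbedding <- function(counts, annotations = NULL,
                                params = embeddingParams()) {
  if (methods::is(counts, "SingleCellReference")) {
    if (missing(annotations)) annotations <- .annotationFrame(counts)
    counts <- assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("unit(s) with zero total count: ",
         paste(head(colnames(counts)[tot == 0], 5L), collapse = ", "))
  mito <- startsWith(rownames(counts), params$mito_prefix)
  mito_pct <- 100 * colSums(counts[mito, , drop = FALSE]) / tot
  cp10k <- sweep(counts, 2L, tot, "/") * 1e4
  covar <- data.frame(total_count = tot, mito_pct = mito_pct,
                      row.names = colnames(counts))
  if (!is.null(annotations)) {
    ann <- .annotationFrame(annotations)
    ann <- ann[match(colnames(counts), ann$cell_id), , drop = FALSE]
    grp <- paste(ann$tissue, ann$cell_type, ann$stage, ann$donor, sep = ":")
    levels_ <- unique(grp)
    cp10k <- vapply(levels_, function(g)
      rowMeans(cp10k[, grp == g, drop = FALSE]), numeric(nrow(cp10k)))
    covar <- data.frame(
      total_count = vapply(levels_, function(g) mean(tot[grp == g]), 0),
      mito_pct = vapply(levels_, function(g) mean(mito_pct[grp == g]), 0),
      row.names = levels_)
    colnames(cp10k) <- levels_
  }
  list(matrix = log1p(cp10k), covariates = covar)
}

#' Dispersion-based highly-variable-gene selection
#'
#' Keeps genes whose mean (log1p scale) lies strictly inside
#' `(hvg_min_mean, hvg_max_mean)` and whose normalized dispersion
#' (variance/mean, z-scored within 20 equal-frequency mean bins) exceeds
#' `hvg_min_dispersion`.
#'
#' @param mat log1p-scale genes x units matrix from [preprocessEmbedding()].
#' @param params an [embeddingParams()] list.
#' @param n_bins number of equal-frequency mean bins.
#' @return Character vector of selected gene ids.
#' @export
selectHVG <- function(mat, params = embeddingParams(), n_bins = 20) {
  if (ncol(mat) < 2L) stop("need >= 2 units to estimate dispersion")
  mu <- rowMeans(mat)
  v <- apply(mat, 1L, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency mean bins; z-score dispersion within each bin
  qs <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(mu, breaks = qs, include.lowest = TRUE, labels = FALSE)
  norm_disp <- disp
  for (b in unique(bin)) {
    i <- bin == b
    s <- sd(disp[i])
    norm_disp[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  keep <- mu > params$hvg_min_mean & mu < params$hvg_max_mean &
    norm_disp > params$hvg_min_dispersion
  if (!any(keep))
    stop("no gene passes the HVG window/dispersion cutoffs")
  .log("selectHVG: %d of %d genes selected", sum(keep), length(keep))
  rownames(mat)[keep]
}

#' Regress out covariates, scale to unit variance, clip
#'
#' Per gene: ordinary-least-squares residual against
#' `[1, total_count, mito_pct]`, then centering to mean 0 and scaling to
#' variance 1, then clipping values above `scale_clip` to `scale_clip`.
#' Genes constant after regression are set to all-zero (logged).
#'
#' @param mat genes x units matrix (typically restricted to HVGs).
#' @param covariates `data.frame` with `total_count` and `mito_pct` rows
#'   matching the matrix columns.
#' @param params an [embeddingParams()] list.
#' @return The regressed, scaled, clipped matrix.
#' @export
regressAndScale <- function(mat, covariates, params = embeddingParams()) {
  stopifnot(nrow(covariates) == ncol(mat))
  D <- cbind(1, covariates$total_count, covariates$mito_pct)
  if (anyNA(D) || any(!is.finite(D))) stop("covariates must be finite")
  qr_d <- qr(D)
  res <- base::t(qr.resid(qr_d, base::t(mat)))
  sds <- apply(res, 1L, sd)
  # residuals of a constant gene are zero up to rounding noise
  flat <- is.na(sds) | sds < 1e-10 * pmax(1, apply(abs(mat), 1L, max))
  if (any(flat))
    .log("regressAndScale: %d constant gene(s) set to zero", sum(flat))
  sds[flat] <- 1
  out <- res / sds
  out[flat, ] <- 0
  out[out > params$scale_clip] <- params$scale_clip
  dimnames(out) <- dimnames(mat)
  out
}

#' PCA and UMAP embedding
#'
#' Computes the first `n_pcs` principal components of the scaled matrix
#' (units as observations; centered, not re-scaled) and a seeded 2-D UMAP
#' of the PC scores. With a fixed `umap_seed` the layout is deterministic.
#'
#' @param scaled genes x units scaled matrix from [regressAndScale()].
#' @param params an [embeddingParams()] list.
#' @return `list(pc_scores = units x n_pcs, umap = units x 2,
#'   var_explained, params)`.
#' @export
pcaUmap <- function(scaled, params = embeddingParams()) {
  n_units <- ncol(scaled)
  if (n_units < 3L) stop("need >= 3 units to embed")
  n_pcs <- params$n_pcs
  if (n_units <= n_pcs) {
    n_pcs <- n_units - 1L
    warning("reducing n_pcs to ", n_pcs, " (only ", n_units, " units)")
  }
  pc <- prcomp(base::t(scaled), center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  nb <- min(params$umap_neighbors, n_units - 1L)
  um <- .withSeed(params$umap_seed,
                  uwot::umap(scores, n_neighbors = nb,
                             min_dist = params$umap_min_dist,
                             metric = "euclidean", n_threads = 1,
                             n_sgd_threads = 0))
  rownames(um) <- rownames(scores)
  colnames(um) <- c("UMAP1", "UMAP2")
  list(pc_scores = scores, umap = um,
       var_explained = pc$sdev^2 / sum(pc$sdev^2), params = params)
}

#' Fetal-centroid nearest-neighbor enrichment
#'
#' The fetal centroid is the mean of the fetal samples' first
#' `n_pcs_distance` principal components. For each requested `k`, the `k`
#' nearest non-fetal samples by Euclidean distance are taken and, per class
#' (tumor, NAT, normal, ...), the fraction of that class's samples captured
#' in the subset is reported. Distance ties are broken by lexicographic
#' sample id.
#'
#' @param pc_scores units x PCs score matrix (rownames = sample ids).
#' @param class_labels named character vector per sample; the value
#'   `"fetal"` marks the centroid samples, all other values are classes.
#' @param ks integer vector of neighborhood sizes.
#' @param params an [embeddingParams()] list (uses `n_pcs_distance`).
#' @return A `data.frame` with column `k` and one proportion column per
#'   class.
#' @export
fetalNeighborEnrichment <- function(pc_scores, class_labels, ks,
                                    params = embeddingParams()) {
  stopifnot(!is.null(rownames(pc_scores)))
  labs <- class_labels[rownames(pc_scores)]
  if (anyNA(labs)) stop("class_labels must cover every embedded sample")
  d <- min(params$n_pcs_distance, ncol(pc_scores))
  fetal <- labs == "fetal"
  if (!any(fetal)) stop("no fetal samples to define the centroid")
  pool <- which(!fetal)
  if (any(ks > length(pool)))
    stop("k exceeds the number of non-fetal samples (", length(pool), ")")
  if (any(ks < 1)) stop("k must be >= 1")
  centroid <- colMeans(pc_scores[fetal, seq_len(d), drop = FALSE])
  dist2 <- rowSums(sweep(pc_scores[pool, seq_len(d), drop = FALSE],
                         2L, centroid)^2)
  ord <- pool[order(dist2, rownames(pc_scores)[pool])]
  classes <- sort(unique(labs[!fetal]))
  totals <- table(factor(labs[!fetal], levels = classes))
  out <- data.frame(k = sort(unique(as.integer(ks))))
  for (cl in classes) out[[cl]] <- NA_real_
  for (i in seq_len(nrow(out))) {
    sub <- labs[ord[seq_len(out$k[i])]]
    cnt <- table(factor(sub, levels = classes))
    out[i, classes] <- as.numeric(cnt) / as.numeric(totals)
  }
  out
}
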
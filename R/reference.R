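#' Remove low-quality cells by total UMI count
#'
#' Cells with fewer than `min_umi` total UMIs are treated as low-quality and
#' dropped (default 500).
#'
#' @param x a [SingleCellReference-class] or a genes x cells count matrix.
#' @param min_umi minimum total UMI count for a cell to be retained.
#' @return The input with low-quality cells removed.
#' @export
filterCells <- function(x, min_umi = 500) {
  stopifnot(min_umi >= 1)
  counts <- if (methods::is(x, "SingleCellReference")) assay(x, "counts") else x
  tot <- Matrix::colSums(counts)
  keep <- tot >= min_umi
  if (!any(keep))
    stop("all cells fall below min_umi = ", min_umi,
         "; review the threshold or the input")
  .log("filterCells: removed %d of %d cells (< %d UMIs)",
       sum(!keep), length(keep), min_umi)
  x[, keep]
}

#' Normalize counts to CPM
#'
#' Scales every cell's counts to counts-per-million so each column sums to
#' 10^6, removing library-size variation.
#'
#' @param x a [SingleCellReference-class] or genes x cells count matrix.
#' @return A genes x cells dense matrix of CPM values.
#' @export
normalizeCPM <- function(x) {
  counts <- if (methods::is(x, "SingleCellReference")) assay(x, "counts") else x
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stop("cell(s) with zero total count: ",
         paste(head(colnames(counts)[tot == 0], 5L), collapse = ", "),
         " (filter cells first)")
  m <- as.matrix(counts)
  sweep(m, 2L, tot, "/") * 1e6
}

#' Tabulate cell states and drop under-supported ones
#'
#' A cell state is a (tissue, cell_type, stage) combination. States backed
#' by fewer than `min_cells` high-quality cells are removed (default 20).
#'
#' @param annotations annotation `data.frame` (or a
#'   [SingleCellReference-class], whose colData is used) covering exactly
#'   the high-quality cells.
#' @param min_cells minimum number of cells per retained state.
#' @return A `data.frame` with columns `cell_state`, `tissue`, `cell_type`,
#'   `stage`, `n_cells` for the retained states.
#' @export
filterCellTypes <- function(annotations, min_cells = 20) {
  ann <- .annotationFrame(annotations)
  ann$cell_state <- .stateId(ann$tissue, ann$cell_type, ann$stage)
  tab <- ann[!duplicated(ann$cell_state),
             c("cell_state", "tissue", "cell_type", "stage")]
  tab$n_cells <- as.integer(table(ann$cell_state)[tab$cell_state])
  keep <- tab$n_cells >= min_cells
  .log("filterCellTypes: %d of %d states retained (>= %d cells)",
       sum(keep), nrow(tab), min_cells)
  if (!any(keep))
    stop("no cell state has >= ", min_cells, " cells")
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$cell_state), , drop = FALSE]
}

# coerce a SingleCellReference or data.frame into an annotation frame with
# cell_id column
.annotationFrame <- function(annotations) {
  if (methods::is(annotations, "SingleCellReference")) {
    cd <- colData(annotations)
    data.frame(cell_id = colnames(annotations), tissue = cd$tissue,
               cell_type = cd$cell_type, stage = cd$stage, donor = cd$donor,
               stringsAsFactors = FALSE)
  } else {
    .normalizeAnnotations(as.data.frame(annotations))
  }
}

#' Build mega-cell replicate profiles
#'
#' For every retained cell state, a fraction (default half) of its cells is
#' drawn without replacement and their CPM profiles averaged into a "mega
#' cell"; this is repeated `n_replicates` times (default 10) to produce the
#' replicate set used for signature-gene selection. Per-state, per-replicate
#' seeds are derived with [splitSeed()], so draws are reproducible and
#' independent across states.
#'
#' @param cpm genes x cells CPM matrix (from [normalizeCPM()]).
#' @param annotations annotation source covering the CPM cells.
#' @param states optional retained-state table from [filterCellTypes()];
#'   defaults to all states present.
#' @param n_replicates replicates per state.
#' @param fraction fraction of cells per draw (0 < fraction <= 1); the draw
#'   size is `floor(fraction * n)`.
#' @param seed master seed.
#' @return A [MegaReplicates-class] object.
#' @export
makeMegaReplicates <- function(cpm, annotations, states = NULL,
                               n_replicates = 10, fraction = 0.5, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1, n_replicates >= 1)
  ann <- .annotationFrame(annotations)
  ann <- ann[match(colnames(cpm), ann$cell_id), , drop = FALSE]
  if (anyNA(ann$cell_id)) stop("annotations do not cover all CPM cells")
  ann$cell_state <- .stateId(ann$tissue, ann$cell_type, ann$stage)
  if (is.null(states)) states <- filterCellTypes(ann, min_cells = 1)
  profiles <- matrix(0, nrow(cpm), nrow(states) * n_replicates,
                     dimnames = list(rownames(cpm), NULL))
  cn <- character(ncol(profiles))
  members <- vector("list", ncol(profiles))
  cd <- data.frame(cell_state = character(), stage = character(),
                   replicate = integer(), stringsAsFactors = FALSE)
  j <- 0L
  for (i in seq_len(nrow(states))) {
    st <- states$cell_state[i]
    cells <- ann$cell_id[ann$cell_state == st]
    take <- floor(fraction * length(cells))
    if (take < 1)
      stop("state '", st, "': fraction * n < 1 (n = ", length(cells), ")")
    for (r in seq_len(n_replicates)) {
      j <- j + 1L
      picked <- .withSeed(splitSeed(seed, paste0(st, "|rep", r)),
                          sample(cells, take))
      profiles[, j] <- rowMeans(cpm[, picked, drop = FALSE])
      cn[j] <- paste0(st, "|rep", r)
      members[[j]] <- picked
      cd <- rbind(cd, data.frame(cell_state = st, stage = states$stage[i],
                                 replicate = r, stringsAsFactors = FALSE))
    }
  }
  colnames(profiles) <- cn
  names(members) <- cn
  se <- SummarizedExperiment(assays = list(meanCPM = profiles),
                             colData = DataFrame(cd, row.names = cn))
  metadata(se)$members <- members
  metadata(se)$seed <- seed
  methods::new("MegaReplicates", se)
}

# ---------------------------------------------------------------------------
# Mann-Whitney machinery (vectorized across genes)
# ---------------------------------------------------------------------------

# one-sided (greater) Mann-Whitney U test of rows of `values[, focal]` vs the
# remaining columns; exact null when both groups <= `exact_max` and the gene
# has no ties, normal approximation with tie correction and continuity
# correction otherwise. Cross-checked against stats::wilcox.test in the
# test suite.
.rowMannWhitney <- function(values, focal, exact_max = 12L) {
  n1 <- sum(focal)
  n2 <- sum(!focal)
  N <- n1 + n2
  R <- base::t(apply(values, 1L, rank))
  U <- rowSums(R[, focal, drop = FALSE]) - n1 * (n1 + 1) / 2
  # tie correction term per gene: sum(t^3 - t) over tied groups
  tiecor <- apply(values, 1L, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  has_ties <- tiecor > 0
  p <- numeric(length(U))
  use_exact <- (max(n1, n2) <= exact_max) & !has_ties
  if (any(use_exact))
    p[use_exact] <- pwilcox(U[use_exact] - 1, n1, n2, lower.tail = FALSE)
  if (any(!use_exact)) {
    mu <- n1 * n2 / 2
    s2 <- n1 * n2 / 12 * ((N + 1) - tiecor[!use_exact] / (N * (N - 1)))
    z <- (U[!use_exact] - mu - 0.5) / sqrt(s2)
    p[!use_exact] <- pnorm(z, lower.tail = FALSE)
  }
  list(U = U, p = p)
}

#' Select per-state signature genes by one-vs-rest Mann-Whitney tests
#'
#' Every cell state's mega-cell replicates are compared against the pooled
#' replicates of all other states with a one-sided (greater) Mann-Whitney U
#' test per gene. P-values are Benjamini-Hochberg adjusted across genes
#' within each state; genes with adjusted p below `alpha_adj` are ranked by
#' descending log2 fold change (pseudocount 1 on mean CPM) and the top
#' `top_n` flagged as signature genes. Ties in the ranking are broken by
#' ascending adjusted p, then lexicographic gene id.
#'
#' @param replicates a [MegaReplicates-class] object with at least 2 states
#'   and at least 2 replicates per state.
#' @param top_n maximum signature genes per state.
#' @param alpha_adj adjusted-p cutoff.
#' @return A `data.frame` (class `signature_gene_table`) with one row per
#'   (cell_state, gene): `U`, `p`, `p_adj`, `log2fc`, `eligible`,
#'   `selected`, `rank`. Selection parameters are kept as attributes so
#'   [applyExclusions()] can re-truncate.
#' @export
selectSignatureGenes <- function(replicates, top_n = 200, alpha_adj = 0.01) {
  stopifnot(methods::is(replicates, "MegaReplicates"))
  cd <- colData(replicates)
  states <- unique(cd$cell_state)
  if (length(states) < 2L)
    stop("need >= 2 cell states for one-vs-rest testing")
  reps_per_state <- table(cd$cell_state)
  if (any(reps_per_state < 2L))
    stop("state(s) with < 2 replicates: ",
         paste(names(reps_per_state)[reps_per_state < 2L], collapse = ", "))
  V <- assay(replicates, "meanCPM")
  genes <- rownames(V)
  out <- vector("list", length(states))
  for (i in seq_along(states)) {
    focal <- cd$cell_state == states[i]
    mw <- .rowMannWhitney(V, focal)
    p_adj <- p.adjust(mw$p, method = "BH")
    l2fc <- log2((rowMeans(V[, focal, drop = FALSE]) + 1) /
                 (rowMeans(V[, !focal, drop = FALSE]) + 1))
    out[[i]] <- data.frame(cell_state = states[i], gene = genes,
                           U = mw$U, p = mw$p, p_adj = p_adj, log2fc = l2fc,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, out)
  tab <- .truncateSelection(tab, top_n = top_n, alpha_adj = alpha_adj)
  attr(tab, "top_n") <- top_n
  attr(tab, "alpha_adj") <- alpha_adj
  attr(tab, "stages") <- stageLabels(replicates)
  class(tab) <- c("signature_gene_table", "data.frame")
  tab
}

# (re)compute eligible/selected/rank columns for a signature gene table
.truncateSelection <- function(tab, top_n, alpha_adj) {
  tab$eligible <- tab$p_adj < alpha_adj
  tab$selected <- FALSE
  tab$rank <- NA_integer_
  for (st in unique(tab$cell_state)) {
    idx <- which(tab$cell_state == st & tab$eligible)
    if (!length(idx)) next
    ord <- idx[order(-tab$log2fc[idx], tab$p_adj[idx], tab$gene[idx])]
    sel <- head(ord, top_n)
    tab$rank[ord] <- seq_along(ord)
    tab$selected[sel] <- TRUE
  }
  tab
}

#' Remove excluded genes from signature candidacy
#'
#' Genes in any catalog category (cell cycle, ribosome biogenesis,
#' apoptosis, mitochondrial, ...) are removed from the candidate table
#' BEFORE the top-N truncation, so each state can still fill its quota from
#' the remaining eligible genes. An empty catalog is the identity.
#'
#' @param table a `signature_gene_table` from [selectSignatureGenes()].
#' @param catalog named list of gene-id vectors (e.g. from [readGmt()]), or
#'   `NULL`.
#' @return The filtered, re-truncated table.
#' @export
applyExclusions <- function(table, catalog = NULL) {
  stopifnot(inherits(table, "signature_gene_table"))
  if (is.null(catalog) || !length(catalog)) return(table)
  for (nm in names(catalog)) {
    n_hit <- length(intersect(unique(table$gene), catalog[[nm]]))
    .log("applyExclusions: %s removes %d gene(s) from candidacy", nm, n_hit)
  }
  drop <- unique(unlist(catalog, use.names = FALSE))
  out <- table[!table$gene %in% drop, , drop = FALSE]
  out <- .truncateSelection(out, top_n = attr(table, "top_n"),
                            alpha_adj = attr(table, "alpha_adj"))
  attributes(out)[c("top_n", "alpha_adj", "stages")] <-
    attributes(table)[c("top_n", "alpha_adj", "stages")]
  class(out) <- class(table)
  out
}

#' Per-state mean CPM profiles
#'
#' Mean CPM of every gene over all (high-quality) cells of each cell state.
#'
#' @param cpm genes x cells CPM matrix.
#' @param annotations annotation source covering the CPM cells.
#' @return genes x states matrix with an attached `stage` attribute.
#' @export
stateMeanCPM <- function(cpm, annotations) {
  ann <- .annotationFrame(annotations)
  ann <- ann[match(colnames(cpm), ann$cell_id), , drop = FALSE]
  if (anyNA(ann$cell_id)) stop("annotations do not cover all CPM cells")
  st <- .stateId(ann$tissue, ann$cell_type, ann$stage)
  states <- sort(unique(st))
  prof <- vapply(states, function(s)
    rowMeans(cpm[, st == s, drop = FALSE]), numeric(nrow(cpm)))
  dimnames(prof) <- list(rownames(cpm), states)
  attr(prof, "stage") <- setNames(
    ann$stage[match(states, st)], states)
  prof
}

#' Assemble the final signature matrix
#'
#' Pools the union of per-state selected genes and fills each (gene, state)
#' entry with the mean CPM of that gene over all high-quality cells of the
#' state, carrying the fetal/adult stage label per state.
#'
#' @param cpm genes x cells CPM matrix.
#' @param annotations annotation source covering the CPM cells.
#' @param table selected-gene table from [selectSignatureGenes()] /
#'   [applyExclusions()].
#' @param provenance optional provenance list stored in the result.
#' @return A [SignatureMatrix-class] object.
#' @export
buildSignatureMatrix <- function(cpm, annotations, table, provenance = list()) {
  stopifnot(inherits(table, "signature_gene_table"))
  genes <- sort(unique(table$gene[table$selected]))
  if (!length(genes)) stop("no selected signature genes")
  missing <- setdiff(genes, rownames(cpm))
  if (length(missing))
    stop("selected gene(s) absent from the CPM matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  prof <- stateMeanCPM(cpm, annotations)
  states <- intersect(colnames(prof), unique(table$cell_state))
  if (!length(states)) stop("no overlap between table states and CPM states")
  SignatureMatrix(prof[genes, states, drop = FALSE],
                  stage = attr(prof, "stage")[states],
                  provenance = provenance)
}

#' Full signature-building pipeline
#'
#' Chains [filterCells()], [normalizeCPM()], [filterCellTypes()],
#' [makeMegaReplicates()], [selectSignatureGenes()], [applyExclusions()] and
#' [buildSignatureMatrix()] with the recipe's default parameters (500-UMI
#' cell filter, 20-cell state filter, 10 half-sampled mega replicates,
#' top 200 genes at adjusted p < 0.01).
#'
#' @param reference a [SingleCellReference-class] object.
#' @param exclusions optional exclusion catalog (named list of gene sets).
#' @param min_umi,min_cells,n_replicates,fraction,top_n,alpha_adj recipe
#'   parameters; see the chained functions.
#' @param seed master seed for the mega-replicate draws.
#' @return A [SignatureMatrix-class] object with full provenance.
#' @export
buildSignature <- function(reference, exclusions = NULL, min_umi = 500,
                           min_cells = 20, n_replicates = 10, fraction = 0.5,
                           top_n = 200, alpha_adj = 0.01, seed = 1) {
  stopifnot(methods::is(reference, "SingleCellReference"))
  hq <- filterCells(reference, min_umi = min_umi)
  states <- filterCellTypes(hq, min_cells = min_cells)
  ann <- .annotationFrame(hq)
  ann$cell_state <- .stateId(ann$tissue, ann$cell_type, ann$stage)
  keep <- ann$cell_state %in% states$cell_state
  .log("buildSignature: %d cells in %d retained states", sum(keep),
       nrow(states))
  hq <- hq[, keep]
  cpm <- normalizeCPM(hq)
  reps <- makeMegaReplicates(cpm, hq, states = states,
                             n_replicates = n_replicates,
                             fraction = fraction, seed = seed)
  tab <- selectSignatureGenes(reps, top_n = top_n, alpha_adj = alpha_adj)
  tab <- applyExclusions(tab, exclusions)
  buildSignatureMatrix(cpm, hq, tab, provenance = list(
    seed = seed, min_umi = min_umi, min_cells = min_cells,
    n_replicates = n_replicates, fraction = fraction, top_n = top_n,
    alpha_adj = alpha_adj,
    exclusions = names(exclusions) %||% character()))
}

# ---------------------------------------------------------------------------
# ortholog mapping
# ---------------------------------------------------------------------------

.mapGeneRows <- function(m, map) {
  .validateOrthologMap(map)
  hit <- map[map$source %in% rownames(m), , drop = FALSE]
  if (!nrow(hit)) stop("no gene of the matrix is covered by the ortholog map")
  .log("mapOrthologs: %d of %d genes mapped; %d dropped",
       nrow(hit), nrow(m), nrow(m) - nrow(hit))
  out <- m[hit$source, , drop = FALSE]
  rownames(out) <- hit$target
  out
}

#' Rename gene rows through a one-to-one ortholog map
#'
#' Rows are renamed from the source to the target namespace in map order;
#' genes without a one-to-one ortholog are dropped (logged). The map must be
#' bijective.
#'
#' @param x a genes-indexed `matrix`, [SignatureMatrix-class] or
#'   [BulkExpression-class] object.
#' @param map `data.frame` with columns `source`, `target` (see
#'   [readOrthologMap()]).
#' @return The same class as `x`, restricted to mapped genes.
#' @rdname mapOrthologs
#' @export
setMethod("mapOrthologs", "matrix", function(x, map) .mapGeneRows(x, map))

#' @rdname mapOrthologs
#' @export
setMethod("mapOrthologs", "SignatureMatrix", function(x, map) {
  SignatureMatrix(.mapGeneRows(assay(x, "meanCPM"), map),
                  stage = stageLabels(x),
                  provenance = metadata(x)$provenance)
})

#' @rdname mapOrthologs
#' @export
setMethod("mapOrthologs", "BulkExpression", function(x, map) {
  v <- .mapGeneRows(assay(x, "exprs"), map)
  se <- SummarizedExperiment(assays = list(exprs = v))
  metadata(se)$unit <- expressionUnit(x)
  # a TPM matrix no longer sums to 1e6 after dropping rows; renormalize
  if (expressionUnit(x) == "TPM") {
    assay(se, "exprs") <- sweep(v, 2L, colSums(v), "/") * 1e6
  }
  methods::new("BulkExpression", se)
})
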
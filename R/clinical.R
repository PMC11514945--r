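#' @importFrom survival coxph Surv survdiff
NULL

# merge index with a clinical table on sample ids
.mergeIndex <- function(index, df, id_col = "sample_id") {
  if (is.null(names(index))) stop("index must be a named vector")
  if (anyDuplicated(df[[id_col]])) stop("duplicated samples in the table")
  shared <- intersect(names(index), df[[id_col]])
  if (!length(shared)) stop("no overlap between index and table samples")
  df <- df[match(shared, df[[id_col]]), , drop = FALSE]
  df$index <- unname(index[shared])
  df
}

#' Cox proportional-hazards association of the fetalness index
#'
#' Fits a Cox model (Efron tie handling) of survival on the fetalness
#' index, optionally adjusted for age at diagnosis and tumor stage. The
#' index is standardized to unit standard deviation before fitting, so the
#' hazard ratio is per SD of fetalness. A hazard ratio > 1 means higher
#' fetalness associates with worse outcome.
#'
#' @param index named fetalness vector.
#' @param surv `data.frame` with columns `sample_id`, `time` (> 0), `event`
#'   (0/1) and, if requested as covariates, `age` and `stage` (ordinal
#'   integer I=1..IV=4 or numeric).
#' @param covariates character subset of `c("age", "stage")`.
#' @param min_events minimum number of events required.
#' @return A one-row `data.frame`: `hr`, `ci_lo`, `ci_hi`, `loghr`, `se`,
#'   `p`, `n`, `events`, `covariates`.
#' @export
coxAssociation <- function(index, surv, covariates = character(),
                           min_events = 10) {
  stopifnot(all(covariates %in% c("age", "stage")))
  df <- .mergeIndex(index, surv)
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(df$event) < min_events)
    stop("fewer than ", min_events, " events (", sum(df$event), ")")
  if (sd(df$index) == 0) stop("zero-variance index")
  df$index_std <- df$index / sd(df$index)
  fml <- stats::reformulate(c("index_std", covariates),
                            response = "Surv(time, event)")
  fit <- tryCatch(coxph(fml, data = df, ties = "efron"),
                  warning = function(w) {
                    if (grepl("converge|infinite", conditionMessage(w)))
                      stop("Cox fit did not converge: ", conditionMessage(w))
                    suppressWarnings(coxph(fml, data = df, ties = "efron"))
                  })
  s <- summary(fit)
  co <- s$coefficients["index_std", , drop = TRUE]
  ci <- s$conf.int["index_std", c("lower .95", "upper .95")]
  data.frame(hr = unname(co["exp(coef)"]), ci_lo = unname(ci[1L]),
             ci_hi = unname(ci[2L]), loghr = unname(co["coef"]),
             se = unname(co["se(coef)"]), p = unname(co["Pr(>|z|)"]),
             n = nrow(df), events = sum(df$event),
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Median split of the index into low/high groups
#'
#' Samples with index below the median form the `low` group, samples at or
#' above it the `high` group (so for odd n the high group gets the extra
#' member).
#'
#' @param index named fetalness vector (>= 4 samples, not all identical).
#' @return Named character vector of `"low"`/`"high"` labels.
#' @export
kmGroups <- function(index) {
  if (length(index) < 4L) stop("need >= 4 samples for a median split")
  if (max(index) == min(index)) stop("all index values identical")
  med <- median(index)
  setNames(ifelse(index < med, "low", "high"), names(index))
}

#' Log-rank test between median-split groups
#'
#' Convenience wrapper pairing [kmGroups()] with a log-rank test, the
#' statistic behind the Kaplan-Meier comparison of the two equal-sized
#' groups.
#'
#' @param index named fetalness vector.
#' @param surv survival `data.frame` as in [coxAssociation()].
#' @return `list(chisq, p, groups)`.
#' @export
kmLogrank <- function(index, surv) {
  df <- .mergeIndex(index, surv)
  df$group <- kmGroups(setNames(df$index, df$sample_id))[df$sample_id]
  sd_ <- survdiff(Surv(time, event) ~ group, data = df)
  list(chisq = sd_$chisq,
       p = stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE),
       groups = table(df$group))
}

#' Stem-cell-marker correlation shift test
#'
#' Pearson correlation of each marker gene's expression with the fetalness
#' index, compared to the correlations of all non-marker genes (the
#' baseline distribution) with a two-sided Mann-Whitney U test.
#'
#' @param expr a [BulkExpression-class] object (TPM) or genes x samples
#'   matrix.
#' @param index named fetalness vector.
#' @param markers character vector of marker gene ids; every marker must be
#'   present in the expression matrix.
#' @return `list(marker_r, baseline_r, U, p, direction)` where `direction`
#'   is `"above"`/`"below"` baseline by median difference.
#' @export
markerCorrelationShift <- function(expr, index, markers) {
  v <- if (methods::is(expr, "BulkExpression")) assay(expr, "exprs") else
    as.matrix(expr)
  missing <- setdiff(markers, rownames(v))
  if (length(missing))
    stop("marker(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(markers) < 2L) stop("need >= 2 markers")
  if (!is.null(names(index))) {
    shared <- intersect(colnames(v), names(index))
    v <- v[, shared, drop = FALSE]
    index <- index[shared]
  }
  if (ncol(v) < 3L) stop("need >= 3 samples")
  r <- suppressWarnings(as.vector(cor(base::t(v), index, method = "pearson")))
  names(r) <- rownames(v)
  r <- r[!is.na(r)]
  mk <- intersect(markers, names(r))
  bl <- setdiff(names(r), markers)
  if (!length(bl)) stop("no baseline genes left")
  wt <- wilcox.test(r[mk], r[bl], alternative = "two.sided")
  list(marker_r = r[mk], baseline_r = r[bl],
       U = unname(wt$statistic), p = wt$p.value,
       direction = if (median(r[mk]) >= median(r[bl])) "above" else "below")
}

#' Dependency enrichment of index-correlated genes
#'
#' Classifies genes as essential (CERES score strictly below
#' `essential_threshold`, default -0.5) or non-essential, crosses that with
#' the sign of each gene's correlation with the fetalness index (genes with
#' rho exactly 0 are excluded), and tests the 2x2 table with a two-sided
#' Fisher exact test. The odds ratio reported is the cross-product ratio.
#'
#' @param dep named numeric vector of CERES scores per gene.
#' @param rho named numeric vector of per-gene correlations with the index.
#' @param essential_threshold CERES cutoff (strict `<`).
#' @return `list(table, odds_ratio, p, degenerate)`; `odds_ratio` is `NA`
#'   with `degenerate = TRUE` when a marginal of the table is zero.
#' @export
dependencyEnrichment <- function(dep, rho, essential_threshold = -0.5) {
  shared <- intersect(names(dep), names(rho))
  rho <- rho[shared][rho[shared] != 0]
  if (!length(rho)) stop("no genes with non-zero correlation")
  pos <- names(rho)[rho > 0]
  neg <- names(rho)[rho < 0]
  if (!length(pos) || !length(neg))
    stop("need genes in both correlation-sign groups")
  ess <- function(g) sum(dep[g] < essential_threshold)
  tab <- matrix(c(ess(pos), length(pos) - ess(pos),
                  ess(neg), length(neg) - ess(neg)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("pos", "neg"),
                                c("essential", "non_essential")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- if (degenerate) NA_real_ else
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, odds_ratio = or, p = p, degenerate = degenerate)
}

#' Drug-response correlation with the fetalness index
#'
#' Per drug, the Spearman correlation between the cell-line fetalness index
#' and the drug's area-under-dose-response-curve values across overlapping
#' cell lines (higher AUC = more resistant), with Benjamini-Hochberg FDR
#' across drugs. Drugs with fewer than `min_overlap` overlapping lines are
#' skipped (logged).
#'
#' @param index named fetalness vector over cell lines.
#' @param auc named list (or column-named `data.frame`/matrix) of per-line
#'   AUC vectors per drug.
#' @param min_overlap minimum overlapping lines per drug.
#' @return A `data.frame` with one row per tested drug: `drug`, `n`, `rho`,
#'   `p`, `fdr`.
#' @export
drugResponseCorrelation <- function(index, auc, min_overlap = 5) {
  if (is.matrix(auc) || is.data.frame(auc)) {
    auc <- lapply(stats::setNames(seq_len(ncol(auc)), colnames(auc)),
                  function(j) stats::setNames(auc[, j], rownames(auc)))
  }
  rows <- lapply(names(auc), function(drug) {
    a <- auc[[drug]]
    a <- a[!is.na(a)]
    shared <- intersect(names(index), names(a))
    if (length(shared) < min_overlap) {
      .log("drugResponseCorrelation: drug '%s' skipped (%d overlapping lines)",
           drug, length(shared))
      return(NULL)
    }
    ct <- suppressWarnings(
      cor.test(index[shared], a[shared], method = "spearman"))
    data.frame(drug = drug, n = length(shared),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) stop("no drug has enough overlapping cell lines")
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
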
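#' Convert FPKM to TPM
#'
#' Per sample k and gene i: `TPM_ik = FPKM_ik / sum_j FPKM_jk * 10^6`, i.e.
#' within-sample ratios are preserved and every sample is rescaled to a
#' 10^6 total.
#'
#' @param bulk a [BulkExpression-class] object tagged `FPKM`.
#' @return A [BulkExpression-class] object tagged `TPM`.
#' @export
fpkmToTpm <- function(bulk) {
  stopifnot(methods::is(bulk, "BulkExpression"))
  if (expressionUnit(bulk) != "FPKM")
    stop("input is tagged '", expressionUnit(bulk), "', expected 'FPKM'")
  v <- assay(bulk, "exprs")
  tot <- colSums(v)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(head(colnames(v)[tot == 0], 5L), collapse = ", "))
  BulkExpression(sweep(v, 2L, tot, "/") * 1e6, unit = "TPM")
}

#' Align bulk expression and signature on shared genes
#'
#' Restricts both objects to the intersection of their gene sets in the
#' signature's gene order. Warns when fewer than half of the signature
#' genes are found in the bulk matrix.
#'
#' @param bulk a [BulkExpression-class] object (TPM).
#' @param signature a [SignatureMatrix-class] object.
#' @return `list(bulk = , signature = )`, both restricted to the shared
#'   genes in identical order.
#' @export
alignGenes <- function(bulk, signature) {
  stopifnot(methods::is(bulk, "BulkExpression"),
            methods::is(signature, "SignatureMatrix"))
  shared <- intersect(rownames(signature), rownames(bulk))
  if (!length(shared))
    stop("no overlap between bulk and signature gene sets")
  frac <- length(shared) / nrow(signature)
  .log("alignGenes: %d of %d signature genes found in bulk (%.1f%%)",
       length(shared), nrow(signature), 100 * frac)
  if (frac < 0.5)
    warning(sprintf("only %.1f%% of signature genes found in the bulk matrix",
                    100 * frac))
  sig <- signature[shared, ]
  se <- SummarizedExperiment(
    assays = list(exprs = assay(bulk, "exprs")[shared, , drop = FALSE]))
  metadata(se)$unit <- expressionUnit(bulk)
  metadata(se)$aligned <- TRUE
  b <- methods::new("BulkExpression", se)
  list(bulk = b, signature = sig)
}

# ---------------------------------------------------------------------------
# mixture solvers
# ---------------------------------------------------------------------------

# nu-SVR mixture regression: z-score X and y jointly (X by its global
# mean/sd, y by its own), fit a linear nu-SVR for each nu in `nus`, score
# each fit by the RMSE between X %*% w (w clipped at 0 and renormalized) and
# y on the z-scale, keep the best
.solveNuSvr <- function(X, y, nus = c(0.25, 0.5, 0.75)) {
  Xs <- (X - mean(X)) / sd(as.vector(X))
  ys <- (y - mean(y)) / sd(y)
  best <- NULL
  for (nu in nus) {
    fit <- e1071::svm(Xs, ys, type = "nu-regression", kernel = "linear",
                      nu = nu, scale = FALSE)
    w <- as.vector(base::t(fit$coefs) %*% fit$SV)
    w[w < 0] <- 0
    if (sum(w) == 0) next
    wn <- w / sum(w)
    yhat <- as.vector(Xs %*% wn)
    rmse <- sqrt(mean((yhat - ys)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(w = wn, rmse = rmse, r = cor(yhat, ys), nu = nu)
  }
  if (is.null(best))
    stop("nu-SVR produced no non-negative solution for any nu")
  best
}

# non-negative least squares, renormalized. When the unconstrained OLS
# solution is already feasible it IS the NNLS solution (and the active-set
# iteration can cycle on such exact-fit inputs), so it is returned directly;
# otherwise Lawson-Hanson via pracma::lsqnonneg.
.solveNnls <- function(X, y) {
  ols <- qr.coef(qr(X), y)
  w <- if (!anyNA(ols) && all(ols >= -1e-10)) pmax(ols, 0) else
    pracma::lsqnonneg(X, y)$x
  if (sum(w) == 0) stop("NNLS solution is identically zero")
  wn <- w / sum(w)
  yhat <- as.vector(X %*% (w))
  list(w = wn, rmse = sqrt(mean((yhat - y)^2)),
       r = suppressWarnings(cor(yhat, y)), nu = NA_real_)
}

# snap near-zero fractions to 0 and renormalize
.snapFractions <- function(w, eps = 1e-8) {
  w[w < eps] <- 0
  w / sum(w)
}

#' Decompose one mixture into relative cell-state fractions
#'
#' With `solver = "nu_svr"` the mixture and the signature are z-scored,
#' linear nu-support-vector regressions are fitted for nu in {0.25, 0.5,
#' 0.75}, and the solution with the lowest root-mean-square reconstruction
#' error is kept; negative coefficients are set to 0 and the rest
#' renormalized to sum to 1. With `solver = "nnls"` a non-negative
#' least-squares fit is renormalized instead. Fractions below 10^-8 are
#' snapped to 0 (and the vector renormalized).
#'
#' @param mixture named per-gene expression vector (TPM), aligned to the
#'   signature genes.
#' @param signature a [SignatureMatrix-class] object (or plain genes x
#'   states matrix) on the same genes in the same order.
#' @param solver `"nu_svr"` or `"nnls"`.
#' @return `list(fractions = named vector summing to 1, rmse, r, nu)`.
#' @export
deconvolveSample <- function(mixture, signature, solver = c("nu_svr", "nnls")) {
  solver <- match.arg(solver)
  X <- if (methods::is(signature, "SignatureMatrix"))
    assay(signature, "meanCPM") else as.matrix(signature)
  if (ncol(X) < 2L) stop("need >= 2 cell states")
  if (length(mixture) != nrow(X))
    stop("mixture and signature are not aligned")
  if (!is.null(names(mixture)) && !is.null(rownames(X)) &&
      !identical(names(mixture), rownames(X)))
    stop("mixture and signature gene orders differ; run alignGenes() first")
  if (any(apply(X, 2L, sd) == 0))
    stop("degenerate signature: zero-variance column after alignment")
  y <- as.numeric(mixture)
  sol <- if (solver == "nu_svr") .solveNuSvr(X, y) else .solveNnls(X, y)
  f <- .snapFractions(sol$w)
  names(f) <- colnames(X)
  list(fractions = f, rmse = sol$rmse, r = sol$r, nu = sol$nu)
}

#' Decompose a cohort of bulk samples
#'
#' Converts nothing: the bulk matrix must already be TPM-tagged (convert
#' FPKM input with [fpkmToTpm()]). Genes are aligned with [alignGenes()],
#' each sample is decomposed with [deconvolveSample()], and per-sample
#' diagnostics are retained. A failing sample is recorded as a failed row
#' (fractions NA) and the run continues unless `strict = TRUE`.
#'
#' @param bulk a [BulkExpression-class] object tagged `TPM`.
#' @param signature a [SignatureMatrix-class] object.
#' @param solver `"nu_svr"` or `"nnls"`.
#' @param strict abort on the first failing sample?
#' @return A [CellStateFractions-class] object.
#' @export
decomposeCohort <- function(bulk, signature, solver = c("nu_svr", "nnls"),
                            strict = FALSE) {
  solver <- match.arg(solver)
  stopifnot(methods::is(bulk, "BulkExpression"),
            methods::is(signature, "SignatureMatrix"))
  if (expressionUnit(bulk) != "TPM")
    stop("bulk matrix is tagged '", expressionUnit(bulk),
         "'; convert with fpkmToTpm() before deconvolution")
  al <- alignGenes(bulk, signature)
  V <- assay(al$bulk, "exprs")
  X <- assay(al$signature, "meanCPM")
  states <- colnames(X)
  n <- ncol(V)
  fr <- matrix(NA_real_, length(states), n,
               dimnames = list(states, colnames(V)))
  diag_df <- data.frame(rmse = rep(NA_real_, n), r = NA_real_, nu = NA_real_,
                        status = "failed", reason = NA_character_,
                        row.names = colnames(V), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    res <- tryCatch(
      deconvolveSample(setNames(V[, k], rownames(V)), X, solver = solver),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop("sample '", colnames(V)[k], "': ", conditionMessage(res))
      diag_df$reason[k] <- conditionMessage(res)
      .log("decomposeCohort: sample '%s' failed: %s", colnames(V)[k],
           conditionMessage(res))
    } else {
      fr[, k] <- res$fractions
      diag_df[k, c("rmse", "r", "nu")] <- list(res$rmse, res$r, res$nu)
      diag_df$status[k] <- "ok"
      diag_df$reason[k] <- ""
    }
  }
  out <- .CellStateFractions(fr, stage = stageLabels(al$signature),
                             diagnostics = DataFrame(diag_df))
  metadata(out)$solver <- solver
  out
}

#' Fetalness index
#'
#' Per sample, the sum of decomposed relative fractions over the
#' fetal-labelled cell states: the aggregated fetal cell program of the
#' sample, in `[0, 1]`.
#'
#' @param result a [CellStateFractions-class] object.
#' @return Named numeric vector of fetalness values per sample (NA for
#'   failed samples).
#' @export
fetalnessIndex <- function(result) {
  stopifnot(methods::is(result, "CellStateFractions"))
  st <- stageLabels(result)
  if (anyNA(st) || !all(st %in% .STAGES))
    stop("every cell state needs a fetal/adult stage label")
  f <- assay(result, "fractions")
  colSums(f[st == "fetal", , drop = FALSE])
}
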
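#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.STAGES <- c("fetal", "adult")

# ---------------------------------------------------------------------------
# SingleCellReference
# ---------------------------------------------------------------------------

#' Annotated single-cell reference
#'
#' A [SingleCellExperiment::SingleCellExperiment] holding a genes x cells UMI
#' count matrix (assay `"counts"`) together with the per-cell annotations the
#' signature-building recipe needs: `tissue`, `cell_type`, developmental
#' `stage` (`"fetal"` or `"adult"`) and `donor`.
#'
#' @slot .. inherited from `SingleCellExperiment`; no extra slots.
#' @name SingleCellReference-class
#' @aliases SingleCellReference-class
#' @exportClass SingleCellReference
setClass("SingleCellReference", contains = "SingleCellExperiment")

.validSingleCellReference <- function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  need <- c("tissue", "cell_type", "stage", "donor")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing colData column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(msg)) {
    st <- colData(object)$stage
    bad <- !st %in% .STAGES
    if (any(bad))
      msg <- c(msg, paste0("stage must be one of {fetal, adult}; offending cell(s): ",
                           paste(head(colnames(object)[bad], 5L), collapse = ", ")))
    cts <- assay(object, "counts")
    v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.vector(as.matrix(cts))
    if (length(v) && (anyNA(v) || min(v) < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
    if (length(v) && max(abs(v - round(v))) > 1e-8)
      msg <- c(msg, "counts must be integral (UMI counts)")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate cell identifiers")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SingleCellReference", .validSingleCellReference)

#' Construct a SingleCellReference
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of UMI
#'   counts with gene ids as rownames and cell ids as colnames.
#' @param annotations `data.frame` with columns `cell_id`, `tissue`,
#'   `cell_type`, `stage` and optionally `donor` (defaults to `"d1"`); one
#'   row per cell of `counts`.
#' @return A validated [SingleCellReference-class] object.
#' @examples
#' m <- matrix(c(1L, 0L, 2L, 5L, 0L, 3L), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), c("c1", "c2")))
#' ann <- data.frame(cell_id = c("c1", "c2"), tissue = "liver",
#'                   cell_type = "Hepatocyte", stage = c("fetal", "adult"))
#' ref <- SingleCellReference(m, ann)
#' @export
SingleCellReference <- function(counts, annotations) {
  annotations <- .normalizeAnnotations(annotations)
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  missing_cells <- setdiff(colnames(counts), annotations$cell_id)
  if (length(missing_cells))
    stop("cells without annotation: ",
         paste(head(missing_cells, 5L), collapse = ", "))
  ann <- annotations[match(colnames(counts), annotations$cell_id), , drop = FALSE]
  cd <- DataFrame(tissue = ann$tissue, cell_type = ann$cell_type,
                  stage = ann$stage, donor = ann$donor,
                  row.names = colnames(counts))
  methods::new("SingleCellReference",
               SingleCellExperiment(assays = list(counts = counts),
                                    colData = cd))
}

# normalize/validate an annotation data.frame (stage lowercased, donor filled)
.normalizeAnnotations <- function(annotations) {
  need <- c("cell_id", "tissue", "cell_type", "stage")
  miss <- setdiff(need, colnames(annotations))
  if (length(miss))
    stop("missing annotation column(s): ", paste(miss, collapse = ", "))
  annotations$stage <- tolower(as.character(annotations$stage))
  bad <- !annotations$stage %in% .STAGES
  if (any(bad))
    stop("unknown stage value(s) in row(s) ",
         paste(head(which(bad), 5L), collapse = ", "), ": ",
         paste(head(unique(annotations$stage[bad]), 5L), collapse = ", "))
  if (is.null(annotations$donor)) annotations$donor <- "d1"
  if (anyDuplicated(annotations$cell_id))
    stop("duplicate cell_id in annotations")
  annotations
}

# ---------------------------------------------------------------------------
# BulkExpression
# ---------------------------------------------------------------------------

#' Bulk expression matrix with a declared unit
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"exprs"`
#' (genes x samples, non-negative) and a unit tag (`"FPKM"` or `"TPM"`) in
#' its metadata. TPM-tagged objects must have per-sample column sums of 10^6
#' (relative tolerance 10^-6); FPKM-tagged objects must be converted with
#' [fpkmToTpm()] before deconvolution.
#'
#' @name BulkExpression-class
#' @aliases BulkExpression-class
#' @exportClass BulkExpression
setClass("BulkExpression", contains = "SummarizedExperiment")

.validBulkExpression <- function(object) {
  msg <- character()
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  unit <- metadata(object)$unit
  if (is.null(unit) || !unit %in% c("FPKM", "TPM"))
    msg <- c(msg, "metadata 'unit' must be 'FPKM' or 'TPM'")
  if (!length(msg)) {
    v <- assay(object, "exprs")
    if (anyNA(v)) msg <- c(msg, "expression values must not be NA/NaN")
    else if (min(v) < 0) msg <- c(msg, "expression values must be non-negative")
    else if (identical(unit, "TPM") && ncol(v) &&
             !isTRUE(metadata(object)$aligned)) {
      cs <- colSums(v)
      off <- abs(cs - 1e6) / 1e6
      if (max(off) > 1e-6)
        msg <- c(msg, sprintf(
          "TPM sample sums must be 10^6 (max relative deviation %.3g)", max(off)))
    }
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate sample identifiers")
  }
  if (length(msg)) msg else TRUE
}
setValidity("BulkExpression", .validBulkExpression)

#' Construct a BulkExpression object
#'
#' @param values genes x samples numeric matrix with gene rownames and sample
#'   colnames. Note the Bioconductor orientation: on disk the package reads
#'   and writes samples x genes tables ([readExpressionTable()]) and
#'   transposes on load.
#' @param unit `"FPKM"` or `"TPM"`.
#' @return A validated [BulkExpression-class] object.
#' @examples
#' v <- matrix(c(2.5e5, 7.5e5, 5e5, 5e5), nrow = 2,
#'             dimnames = list(c("G1", "G2"), c("s1", "s2")))
#' be <- BulkExpression(v, unit = "TPM")
#' expressionUnit(be)
#' @export
BulkExpression <- function(values, unit = c("TPM", "FPKM")) {
  unit <- match.arg(unit)
  se <- SummarizedExperiment(assays = list(exprs = as.matrix(values)))
  metadata(se)$unit <- unit
  methods::new("BulkExpression", se)
}

#' Unit tag of a BulkExpression object
#'
#' @param x a [BulkExpression-class] object.
#' @return `"FPKM"` or `"TPM"`.
#' @rdname expressionUnit
#' @export
setMethod("expressionUnit", "BulkExpression",
          function(x) metadata(x)$unit)

# ---------------------------------------------------------------------------
# SignatureMatrix
# ---------------------------------------------------------------------------

#' Cell-state signature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the genes x
#' cell-states reference used for deconvolution: assay `"meanCPM"` carries
#' the mean CPM of each pooled signature gene in each cell state, and
#' `colData(x)$stage` labels every state `"fetal"` or `"adult"`. Build
#' provenance (seed and recipe parameters) is stored in `metadata(x)$provenance`.
#'
#' @name SignatureMatrix-class
#' @aliases SignatureMatrix-class
#' @exportClass SignatureMatrix
setClass("SignatureMatrix", contains = "SummarizedExperiment")

.validSignatureMatrix <- function(object) {
  msg <- character()
  if (!"meanCPM" %in% assayNames(object))
    msg <- c(msg, "assay 'meanCPM' is required")
  if (!"stage" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'stage' is required")
  else if (!all(colData(object)$stage %in% .STAGES))
    msg <- c(msg, "every cell state needs a stage label in {fetal, adult}")
  if (!length(msg)) {
    v <- assay(object, "meanCPM")
    if (anyNA(v) || min(v) < 0)
      msg <- c(msg, "signature values must be non-negative and non-missing")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicate signature gene identifiers")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate cell-state identifiers")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SignatureMatrix", .validSignatureMatrix)

#' Construct a SignatureMatrix
#'
#' @param values genes x cell-states matrix of mean CPM values.
#' @param stage character vector of stage labels (`"fetal"`/`"adult"`), one
#'   per column of `values`.
#' @param provenance optional list recording the build parameters and seed.
#' @return A validated [SignatureMatrix-class] object.
#' @export
SignatureMatrix <- function(values, stage, provenance = list()) {
  se <- SummarizedExperiment(
    assays = list(meanCPM = as.matrix(values)),
    colData = DataFrame(stage = as.character(stage),
                        row.names = colnames(values)))
  metadata(se)$provenance <- provenance
  methods::new("SignatureMatrix", se)
}

#' Stage labels of cell states
#'
#' @param x a [SignatureMatrix-class], [MegaReplicates-class] or
#'   [CellStateFractions-class] object.
#' @return Named character vector of `"fetal"`/`"adult"` labels per state.
#' @rdname stageLabels
#' @export
setMethod("stageLabels", "SignatureMatrix", function(x)
  setNames(colData(x)$stage, colnames(x)))

#' Cell-state identifiers
#'
#' @param x an object holding cell states.
#' @return Character vector of state ids.
#' @rdname cellStates
#' @export
setMethod("cellStates", "SignatureMatrix", function(x) colnames(x))

# ---------------------------------------------------------------------------
# MegaReplicates
# ---------------------------------------------------------------------------

#' Mega-cell replicate profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] of genes x (state x
#' replicate) mean-CPM profiles. Each column is a "mega cell": the average
#' CPM vector of a random half of one cell state's cells, drawn without
#' replacement. `colData` records `cell_state`, `stage` and
#' `replicate`; `metadata(x)$members` keeps the sampled cell ids per column
#' and `metadata(x)$seed` the master seed.
#'
#' @name MegaReplicates-class
#' @aliases MegaReplicates-class
#' @exportClass MegaReplicates
setClass("MegaReplicates", contains = "SummarizedExperiment")

#' Construct a MegaReplicates object from precomputed profiles
#'
#' Mainly useful for toy cases and tests; [makeMegaReplicates()] is the
#' standard route from a CPM matrix.
#'
#' @param profiles genes x replicate-profiles matrix of mean CPM values.
#' @param cell_state character vector, state id per column.
#' @param stage character vector of `"fetal"`/`"adult"` per column.
#' @param replicate integer replicate index per column.
#' @return A [MegaReplicates-class] object.
#' @export
MegaReplicates <- function(profiles, cell_state, stage, replicate) {
  cn <- paste0(cell_state, "|rep", replicate)
  colnames(profiles) <- cn
  se <- SummarizedExperiment(
    assays = list(meanCPM = as.matrix(profiles)),
    colData = DataFrame(cell_state = cell_state, stage = stage,
                        replicate = as.integer(replicate), row.names = cn))
  methods::new("MegaReplicates", se)
}

.validMegaReplicates <- function(object) {
  msg <- character()
  need <- c("cell_state", "stage", "replicate")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing colData column(s): ",
                         paste(miss, collapse = ", ")))
  if (!"meanCPM" %in% assayNames(object))
    msg <- c(msg, "assay 'meanCPM' is required")
  if (length(msg)) msg else TRUE
}
setValidity("MegaReplicates", .validMegaReplicates)

#' @rdname stageLabels
#' @export
setMethod("stageLabels", "MegaReplicates", function(x) {
  cd <- colData(x)
  st <- cd$stage[!duplicated(cd$cell_state)]
  setNames(st, cd$cell_state[!duplicated(cd$cell_state)])
})

#' @rdname cellStates
#' @export
setMethod("cellStates", "MegaReplicates",
          function(x) unique(colData(x)$cell_state))

# ---------------------------------------------------------------------------
# CellStateFractions
# ---------------------------------------------------------------------------

#' Decomposition result: relative cell-state fractions per sample
#'
#' A [SummarizedExperiment::SummarizedExperiment] with cell states as rows
#' (stage label in `rowData`) and bulk samples as columns. Assay
#' `"fractions"` holds the non-negative relative fractions, which sum to 1
#' per successfully decomposed sample. Per-sample solver diagnostics live in
#' `colData`: `rmse` and `r` of the mixture reconstruction, the chosen `nu`
#' (NA for the NNLS solver), `status` (`"ok"`/`"failed"`) and `reason`.
#'
#' @name CellStateFractions-class
#' @aliases CellStateFractions-class
#' @exportClass CellStateFractions
setClass("CellStateFractions", contains = "SummarizedExperiment")

.validCellStateFractions <- function(object) {
  msg <- character()
  if (!"fractions" %in% assayNames(object))
    msg <- c(msg, "assay 'fractions' is required")
  if (!"stage" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'stage' is required")
  need <- c("rmse", "r", "nu", "status")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing diagnostic column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(msg)) {
    ok <- colData(object)$status == "ok"
    f <- assay(object, "fractions")[, ok, drop = FALSE]
    if (length(f)) {
      if (anyNA(f) || min(f) < 0)
        msg <- c(msg, "fractions of decomposed samples must be non-negative")
      else if (ncol(f) && max(abs(colSums(f) - 1)) > 1e-6)
        msg <- c(msg, "fractions must sum to 1 per sample (tolerance 1e-6)")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("CellStateFractions", .validCellStateFractions)

# internal constructor
.CellStateFractions <- function(fractions, stage, diagnostics) {
  se <- SummarizedExperiment(
    assays = list(fractions = fractions),
    rowData = DataFrame(stage = stage, row.names = rownames(fractions)),
    colData = diagnostics)
  methods::new("CellStateFractions", se)
}

#' Extract the fraction matrix
#'
#' @param x a [CellStateFractions-class] object.
#' @return samples x cell-states numeric matrix.
#' @rdname fractions
#' @export
setMethod("fractions", "CellStateFractions",
          function(x) t(assay(x, "fractions")))

#' @rdname stageLabels
#' @export
setMethod("stageLabels", "CellStateFractions", function(x)
  setNames(rowData(x)$stage, rownames(x)))

#' @rdname cellStates
#' @export
setMethod("cellStates", "CellStateFractions", function(x) rownames(x))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SingleCellReference", function(object) {
  cd <- colData(object)
  states <- unique(.stateId(cd$tissue, cd$cell_type, cd$stage))
  cat("SingleCellReference:", nrow(object), "genes x", ncol(object), "cells\n")
  cat("  cell states:", length(states),
      sprintf("(%d fetal, %d adult cells)\n",
              sum(cd$stage == "fetal"), sum(cd$stage == "adult")))
  cat("  tissues:", paste(unique(cd$tissue), collapse = ", "), "\n")
})

setMethod("show", "BulkExpression", function(object) {
  cat("BulkExpression:", nrow(object), "genes x", ncol(object), "samples,",
      "unit =", expressionUnit(object), "\n")
})

setMethod("show", "SignatureMatrix", function(object) {
  st <- stageLabels(object)
  cat("SignatureMatrix:", nrow(object), "signature genes x", ncol(object),
      "cell states\n")
  cat(sprintf("  %d fetal / %d adult states\n",
              sum(st == "fetal"), sum(st == "adult")))
})

setMethod("show", "MegaReplicates", function(object) {
  cat("MegaReplicates:", nrow(object), "genes,",
      length(cellStates(object)), "states x",
      max(colData(object)$replicate), "replicates\n")
})

setMethod("show", "CellStateFractions", function(object) {
  ok <- sum(colData(object)$status == "ok")
  cat("CellStateFractions:", ncol(object), "samples x", nrow(object),
      "cell states (", ok, "decomposed )\n")
  st <- stageLabels(object)
  cat(sprintf("  %d fetal / %d adult states; solver: %s\n",
              sum(st == "fetal"), sum(st == "adult"),
              metadata(object)$solver %||% "unknown"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
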
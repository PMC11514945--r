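#' @importFrom Matrix readMM writeMM sparseMatrix rowSums colSums t
NULL

# read a canonical TSV (comment '#', UTF-8, '.' decimal) into a data.frame
.readTsv <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

# collapse duplicate gene rows of a counts matrix by summation (logged)
.collapseDuplicateGenes <- function(m) {
  dup <- anyDuplicated(rownames(m))
  if (!dup) return(m)
  ids <- rownames(m)
  ndup <- sum(duplicated(ids))
  grp <- factor(ids, levels = unique(ids))
  # rowsum works for both dense and Matrix sparse inputs
  m <- rowsum(m, grp)
  rownames(m) <- levels(grp)
  .log("collapsed %d duplicate gene row(s) by summation", ndup)
  m
}

.checkCountValues <- function(v, what = "counts") {
  if (anyNA(v)) stop(what, ": missing values are not allowed")
  if (length(v) && min(v) < 0) stop(what, ": negative entries are not allowed")
  if (length(v) && max(abs(v - round(v))) > 1e-8)
    stop(what, ": non-integer entries are not allowed in a count matrix")
}

#' Read a single-cell count matrix
#'
#' Supports the MatrixMarket triplet layout (`matrix.mtx` plus sidecar
#' `features.tsv` and `barcodes.tsv` in the same directory, or explicit
#' paths) and a dense TSV (first column gene ids, header cell ids). Entries
#' must be non-negative integers; duplicate gene rows are collapsed by
#' summation with a log message.
#'
#' @param path path to the `.mtx` file or the dense TSV.
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @param features,barcodes optional sidecar paths for the MTX layout;
#'   default to `features.tsv` / `barcodes.tsv` next to `path`.
#' @return A genes x cells count matrix (sparse `dgCMatrix` for MTX input,
#'   dense base matrix for TSV input) with gene/cell dimnames.
#' @seealso [writeCountMatrix()] for the inverse operation.
#' @export
readCountMatrix <- function(path, format = c("mtx_triplet", "dense_tsv"),
                            features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "mtx_triplet") {
    dir <- dirname(path)
    features <- features %||% file.path(dir, "features.tsv")
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    if (!file.exists(features)) stop("missing sidecar: ", features)
    if (!file.exists(barcodes)) stop("missing sidecar: ", barcodes)
    m <- Matrix::readMM(path)
    g <- .readTsv(features, header = FALSE)[[1L]]
    b <- .readTsv(barcodes, header = FALSE)[[1L]]
    if (nrow(m) != length(g))
      stop(sprintf("matrix has %d rows but features.tsv lists %d genes",
                   nrow(m), length(g)))
    if (ncol(m) != length(b))
      stop(sprintf("matrix has %d columns but barcodes.tsv lists %d cells",
                   ncol(m), length(b)))
    .checkCountValues(m@x)
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(as.character(g), as.character(b))
  } else {
    df <- .readTsv(path)
    g <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    .checkCountValues(m)
    rownames(m) <- g
  }
  if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers")
  .collapseDuplicateGenes(m)
}

#' Write a count matrix
#'
#' Inverse of [readCountMatrix()]: MTX triplet (with `features.tsv` /
#' `barcodes.tsv` sidecars) or dense TSV.
#'
#' @param m genes x cells count matrix with dimnames.
#' @param path output `.mtx` path (its directory receives the sidecars) or
#'   TSV path.
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @return Invisibly, `path`.
#' @export
writeCountMatrix <- function(m, path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    Matrix::writeMM(methods::as(methods::as(m, "dMatrix"), "TsparseMatrix"), path)
    dir <- dirname(path)
    writeLines(rownames(m), file.path(dir, "features.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  } else {
    df <- data.frame(gene = rownames(m), as.matrix(m), check.names = FALSE)
    .writeTsv(df, path)
  }
  invisible(path)
}

#' Read per-cell annotations
#'
#' Requires columns `cell_id`, `tissue`, `cell_type`, `stage` (plus optional
#' `donor`). Stage strings are normalized to lowercase and must be `fetal`
#' or `adult`; anything else raises an error naming the offending row.
#'
#' @param path TSV path.
#' @return A `data.frame` of validated annotations.
#' @export
readCellMetadata <- function(path) {
  .normalizeAnnotations(.readTsv(path))
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then one gene id per field. Gene ids
#' are deduplicated within a set; empty sets and duplicate set names are
#' errors.
#'
#' @param path GMT path.
#' @return Named list of character vectors; per-set descriptions in
#'   `attr(, "description")`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(head(which(short), 5L), collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    stop("empty gene set(s): ", paste(nm[empty], collapse = ", "))
  names(sets) <- nm
  attr(sets, "description") <- setNames(desc, nm)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute as produced by [readGmt()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a bulk expression table
#'
#' The on-disk layout is samples x genes (first column sample ids, header
#' gene ids); the returned object follows the Bioconductor genes x samples
#' orientation. Values must be numeric, finite and non-negative.
#'
#' @param path TSV path.
#' @param unit `"FPKM"` or `"TPM"`. FPKM-tagged matrices must pass through
#'   [fpkmToTpm()] before deconvolution.
#' @return A [BulkExpression-class] object.
#' @export
readExpressionTable <- function(path, unit = c("TPM", "FPKM")) {
  unit <- match.arg(unit)
  df <- .readTsv(path)
  samples <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/NaN value at sample '%s', gene '%s'",
                 samples[bad[1L]], colnames(m)[bad[2L]]))
  }
  if (min(m) < 0) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at sample '%s', gene '%s'",
                 samples[bad[1L]], colnames(m)[bad[2L]]))
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicate gene identifiers in expression table")
  v <- base::t(m)
  colnames(v) <- samples
  BulkExpression(v, unit = unit)
}

#' Read a two-column ortholog map
#'
#' Columns: source gene id, target gene id. The map must be bijective
#' (one-to-one in both directions).
#'
#' @param path TSV path (header optional columns `source`, `target`).
#' @return A `data.frame` with columns `source` and `target`.
#' @export
readOrthologMap <- function(path) {
  df <- .readTsv(path)
  if (ncol(df) < 2L) stop("ortholog map needs two columns")
  map <- data.frame(source = as.character(df[[1L]]),
                    target = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  .validateOrthologMap(map)
  map
}

.validateOrthologMap <- function(map) {
  if (anyDuplicated(map$source))
    stop("ortholog map is not one-to-one: duplicated source gene(s): ",
         paste(head(unique(map$source[duplicated(map$source)]), 5L),
               collapse = ", "))
  if (anyDuplicated(map$target))
    stop("ortholog map is not one-to-one: duplicated target gene(s): ",
         paste(head(unique(map$target[duplicated(map$target)]), 5L),
               collapse = ", "))
  invisible(map)
}

#' Write a signature matrix as TSV
#'
#' Layout: a comment line per provenance entry, a header row of cell-state
#' ids, a second header row of stage labels (marked with a leading
#' `#stage`), then one row per signature gene.
#'
#' @param x a [SignatureMatrix-class] object.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
writeSignatureMatrix <- function(x, path) {
  stopifnot(methods::is(x, "SignatureMatrix"))
  v <- assay(x, "meanCPM")
  hdr1 <- paste(c("gene", colnames(v)), collapse = "\t")
  hdr2 <- paste(c("#stage", stageLabels(x)), collapse = "\t")
  rows <- paste(rownames(v),
                apply(v, 1L, function(r) paste(.fmtNum(r), collapse = "\t")),
                sep = "\t")
  tmp <- paste0(path, ".tmp")
  writeLines(c(hdr1, hdr2, rows), tmp, useBytes = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a signature matrix written by [writeSignatureMatrix()]
#'
#' @param path TSV path.
#' @return A [SignatureMatrix-class] object.
#' @export
readSignatureMatrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  stage_line <- grep("^#stage\t", lines, value = TRUE)
  if (!length(stage_line)) stop("signature TSV lacks the '#stage' header row")
  stage <- strsplit(stage_line[1L], "\t", fixed = TRUE)[[1L]][-1L]
  body <- lines[-1L]
  body <- body[!startsWith(body, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1), 1L)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(hdr) - 1L)))
  dimnames(vals) <- list(genes, hdr[-1L])
  SignatureMatrix(vals, stage = stage)
}

# ---------------------------------------------------------------------------
# writeTable methods: canonical TSV export of tabular results
# ---------------------------------------------------------------------------

#' Write a tabular result as canonical TSV
#'
#' Deterministic column and row order, 12 significant digits, tab-separated,
#' UTF-8. Two writes of the same object are byte-identical, and reading the
#' file back (e.g. with `read.delim`) reproduces the table to the printed
#' precision.
#'
#' @param x a [CellStateFractions-class] object or a plain `data.frame`
#'   (e.g. an enrichment table).
#' @param path output TSV path.
#' @param ... unused.
#' @return Invisibly, `path`.
#' @rdname writeTable
#' @export
setMethod("writeTable", "data.frame", function(x, path, ...) {
  .writeTsv(x, path)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "CellStateFractions", function(x, path, ...) {
  .writeTsv(asFractionTable(x), path)
})

#' Flatten a CellStateFractions object to a data.frame
#'
#' Columns: `sample`, one column per cell state, `fetalness`, then the
#' solver diagnostics `rmse`, `r`, `nu`, `status`.
#'
#' @param x a [CellStateFractions-class] object.
#' @return A `data.frame`, one row per sample.
#' @export
asFractionTable <- function(x) {
  stopifnot(methods::is(x, "CellStateFractions"))
  f <- fractions(x)
  cd <- colData(x)
  df <- data.frame(sample = rownames(f), f,
                   fetalness = as.numeric(fetalnessIndex(x)),
                   rmse = cd$rmse, r = cd$r, nu = cd$nu,
                   status = cd$status,
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}
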
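# shared fixture: well-separated synthetic signature (K states, block markers)
syntheticSignature <- function(K = 5, n_genes = 200, seed = 1) {
  set.seed(seed)
  base <- rlnorm(n_genes, 2, 0.5)
  X <- vapply(seq_len(K), function(k) {
    v <- base
    idx <- ((k - 1) * 20 + 1):(k * 20)
    v[idx] <- v[idx] * 30
    v / sum(v) * 1e6
  }, numeric(n_genes))
  dimnames(X) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("st%02d", seq_len(K)))
  SignatureMatrix(X, stage = rep(c("fetal", "adult"), length.out = K))
}

test_that("fpkmToTpm matches the per-sample renormalization formula", {
  one <- BulkExpression(toyCounts(matrix(5), genes = "G1", cells = "s1"),
                        unit = "FPKM")
  expect_equal(unname(SummarizedExperiment::assay(fpkmToTpm(one))[1, 1]), 1e6)

  two <- BulkExpression(toyCounts(matrix(c(1, 3), 2), genes = c("G1", "G2"),
                                  cells = "s1"), unit = "FPKM")
  expect_equal(unname(SummarizedExperiment::assay(fpkmToTpm(two))[, 1]),
               c(250000, 750000))

  set.seed(31)
  v <- toyCounts(matrix(runif(60, 0, 50), 12, 5), cells = paste0("s", 1:5))
  bulk <- BulkExpression(v, unit = "FPKM")
  tpm <- SummarizedExperiment::assay(fpkmToTpm(bulk))
  oracle <- v
  for (k in seq_len(ncol(v))) for (i in seq_len(nrow(v)))
    oracle[i, k] <- v[i, k] / sum(v[, k]) * 1e6
  expect_equal(tpm, oracle)
  expect_lt(max(abs(colSums(tpm) - 1e6)) / 1e6, 1e-6)

  vz <- v; vz[, 2] <- 0
  expect_error(fpkmToTpm(BulkExpression(vz, unit = "FPKM")), "all-zero")
  expect_error(fpkmToTpm(fpkmToTpm(bulk)), "expected 'FPKM'")
})

test_that("alignGenes restricts both objects to the shared genes in signature order", {
  sig <- syntheticSignature()
  v <- SummarizedExperiment::assay(sig, "meanCPM")
  colnames(v) <- paste0("s", seq_len(ncol(v)))
  bulk <- BulkExpression(v, unit = "TPM")
  al <- suppressMessages(alignGenes(bulk, sig))
  expect_identical(rownames(al$bulk), rownames(sig))

  # shuffled bulk gene order gives identical aligned matrices
  set.seed(32)
  shuf <- BulkExpression(v[sample(nrow(v)), , drop = FALSE], unit = "TPM")
  al2 <- suppressMessages(alignGenes(shuf, sig))
  expect_identical(SummarizedExperiment::assay(al2$bulk),
                   SummarizedExperiment::assay(al$bulk))

  # dropping 10 genes shrinks the alignment accordingly
  toTpm <- function(m) sweep(m, 2, colSums(m), "/") * 1e6
  sub <- BulkExpression(toTpm(v[-(1:10), , drop = FALSE]), unit = "TPM")
  al3 <- suppressMessages(alignGenes(sub, sig))
  expect_identical(nrow(al3$signature), nrow(sig) - 10L)

  few <- BulkExpression(toTpm(v[1:3, , drop = FALSE]), unit = "TPM")
  expect_warning(suppressMessages(alignGenes(few, sig)), "signature genes")
  none <- BulkExpression(toTpm(toyCounts(matrix(1:4, 2),
                                          genes = c("ZZ1", "ZZ2"))),
                         unit = "TPM")
  expect_error(suppressMessages(alignGenes(none, sig)), "overlap")
})

test_that("both solvers recover a pure signature column and the uniform mixture", {
  sig <- syntheticSignature(K = 5)
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  for (solver in c("nu_svr", "nnls")) {
    res <- deconvolveSample(setNames(X[, 3], rownames(X)), sig, solver = solver)
    expect_equal(unname(res$fractions),
                 c(0, 0, 1, 0, 0), tolerance = 1e-6)
    resu <- deconvolveSample(setNames(rowMeans(X), rownames(X)), sig,
                             solver = solver)
    expect_equal(unname(resu$fractions), rep(0.2, 5), tolerance = 1e-3)
  }
})

test_that("a two-component mixture is recovered and nu-SVR agrees with the NNLS oracle", {
  sig <- syntheticSignature(K = 5)
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  y <- 0.3 * X[, 1] + 0.7 * X[, 2]
  truth <- c(0.3, 0.7, 0, 0, 0)
  # independent oracle: Lawson-Hanson NNLS solved directly
  oracle <- pracma::lsqnonneg(X, y)$x
  oracle <- oracle / sum(oracle)
  expect_equal(oracle, truth, tolerance = 1e-6)
  for (solver in c("nu_svr", "nnls")) {
    res <- deconvolveSample(setNames(y, rownames(X)), sig, solver = solver)
    expect_equal(unname(res$fractions), truth, tolerance = 1e-3,
                 label = solver)
  }
})

test_that("fractions are scale invariant, non-negative and sum to one", {
  sig <- syntheticSignature(K = 4)
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  set.seed(41)
  for (i in 1:5) {
    f <- rgamma(4, 1); f <- f / sum(f)
    y <- as.vector(X %*% f) * exp(rnorm(nrow(X), 0, 0.1))
    for (solver in c("nu_svr", "nnls")) {
      r1 <- deconvolveSample(setNames(y, rownames(X)), sig, solver = solver)
      r2 <- deconvolveSample(setNames(y * 37.5, rownames(X)), sig,
                             solver = solver)
      expect_true(all(r1$fractions >= 0))
      expect_equal(sum(r1$fractions), 1, tolerance = 1e-9)
      # nu-SVR is scale invariant up to the SMO stopping tolerance only
      tol <- if (solver == "nu_svr") 1e-3 else 1e-6
      expect_equal(r1$fractions, r2$fractions, tolerance = tol)
    }
  }
})

test_that("degenerate signatures and misaligned mixtures are rejected", {
  sig <- syntheticSignature(K = 3)
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  Xflat <- X; Xflat[, 2] <- 5
  expect_error(deconvolveSample(X[, 1], Xflat), "zero-variance")
  expect_error(deconvolveSample(X[1:10, 1], sig), "not aligned")
  expect_error(deconvolveSample(setNames(X[, 1], rev(rownames(X))), sig),
               "gene orders differ")
})

test_that("cohort decomposition matches per-sample calls and is order-equivariant", {
  sig <- syntheticSignature(K = 4)
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  mx <- simulateMixtures(X, n_samples = 6, seed = 7)
  res <- suppressMessages(decomposeCohort(mx$bulk, sig, solver = "nnls"))
  one <- deconvolveSample(
    setNames(SummarizedExperiment::assay(mx$bulk)[rownames(X), 1],
             rownames(X)), sig, solver = "nnls")
  expect_equal(fractions(res)[1, ], one$fractions)

  # permuting sample order permutes result rows identically
  perm <- c(4, 1, 6, 2, 5, 3)
  v <- SummarizedExperiment::assay(mx$bulk)[, perm]
  bulk_perm <- BulkExpression(v, unit = "TPM")
  res_perm <- suppressMessages(decomposeCohort(bulk_perm, sig, solver = "nnls"))
  expect_equal(fractions(res_perm), fractions(res)[perm, ])
})

test_that("noiseless Dirichlet cohorts are recovered with small error", {
  sig <- syntheticSignature(K = 5, n_genes = 300)
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  mx <- simulateMixtures(X, n_samples = 50, seed = 13)
  res <- suppressMessages(decomposeCohort(mx$bulk, sig, solver = "nnls"))
  err <- abs(fractions(res) - mx$fractions[, cellStates(res)])
  expect_lt(mean(err), 0.01)
  expect_lt(max(err), 1e-6)
})

test_that("failed samples are recorded without aborting the cohort", {
  sig <- syntheticSignature(K = 3)
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  v <- cbind(s1 = X[, 1], s2 = rep(1, nrow(X)))  # s2 is flat: solver-hostile
  v <- sweep(v, 2, colSums(v), "/") * 1e6
  bulk <- BulkExpression(v, unit = "TPM")
  res <- suppressMessages(decomposeCohort(bulk, sig, solver = "nnls"))
  expect_identical(SummarizedExperiment::colData(res)$status[1], "ok")
  # strict mode aborts on the first failure if any sample fails
  if (any(SummarizedExperiment::colData(res)$status == "failed"))
    expect_error(suppressMessages(
      decomposeCohort(bulk, sig, solver = "nnls", strict = TRUE)))
  else succeed()
})

test_that("fetalness is the exact fetal-state mass and saturates at the extremes", {
  sig <- syntheticSignature(K = 4)  # stages alternate fetal/adult
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  fr <- rbind(c(0.12, 0.80, 0.08, 0.00),
              c(0.50, 0.00, 0.50, 0.00),   # all mass on fetal states 1, 3
              c(0.00, 0.25, 0.00, 0.75))   # no fetal mass
  y <- X %*% t(fr)
  y <- sweep(y, 2, colSums(y), "/") * 1e6
  colnames(y) <- paste0("s", 1:3)
  bulk <- BulkExpression(y, unit = "TPM")
  res <- suppressMessages(decomposeCohort(bulk, sig, solver = "nnls"))
  fi <- fetalnessIndex(res)
  expect_equal(unname(fi), c(0.20, 1.00, 0.00), tolerance = 1e-6)
})

test_that("fetalness increases strictly along a fetal-mass ladder", {
  sig <- syntheticSignature(K = 4)
  X <- SummarizedExperiment::assay(sig, "meanCPM")
  fetal_states <- which(stageLabels(sig) == "fetal")
  adult_states <- which(stageLabels(sig) == "adult")
  ladder <- seq(0, 1, by = 0.1)
  y <- vapply(ladder, function(fm) {
    f <- numeric(4)
    f[fetal_states] <- fm / 2
    f[adult_states] <- (1 - fm) / 2
    v <- as.vector(X %*% f)
    v / sum(v) * 1e6
  }, numeric(nrow(X)))
  colnames(y) <- sprintf("lad%02d", seq_along(ladder))
  rownames(y) <- rownames(X)
  for (solver in c("nu_svr", "nnls")) {
    res <- suppressMessages(decomposeCohort(BulkExpression(y, unit = "TPM"),
                                            sig, solver = solver))
    fi <- fetalnessIndex(res)
    expect_equal(cor(fi, ladder, method = "spearman"), 1, label = solver)
  }
})
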
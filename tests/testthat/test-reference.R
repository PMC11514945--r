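test_that("filterCells applies the UMI threshold at the exact boundary", {
  m <- toyCounts(cbind(c(499, 0, 0), c(500, 0, 0), c(100, 200, 300)),
                 cells = c("low", "edge", "rich"))
  ann <- toyAnnotations(colnames(m))
  ref <- SingleCellReference(m, ann)
  kept <- suppressMessages(filterCells(ref, min_umi = 500))
  expect_identical(colnames(kept), c("edge", "rich"))

  # min_umi = 1 with no empty cells is the identity
  kept1 <- suppressMessages(filterCells(ref, min_umi = 1))
  expect_identical(colnames(kept1), colnames(m))

  expect_error(suppressMessages(filterCells(ref, min_umi = 10000)),
               "threshold")
})

test_that("filterCells matches a brute-force column-sum scan on random input", {
  set.seed(21)
  m <- toyCounts(matrix(rpois(50 * 40, 15), 50, 40))
  keep_oracle <- colnames(m)[vapply(seq_len(ncol(m)),
                                    function(j) sum(m[, j]) >= 500, NA)]
  ref <- SingleCellReference(m, toyAnnotations(colnames(m)))
  kept <- suppressMessages(filterCells(ref, min_umi = 500))
  expect_identical(colnames(kept), keep_oracle)
})

test_that("normalizeCPM rescales every cell to 10^6 and is scale invariant", {
  m <- toyCounts(matrix(c(1, 1, 2), ncol = 1))
  expect_equal(unname(normalizeCPM(m)[, 1]), c(250000, 250000, 500000))
  expect_equal(normalizeCPM(m * 3), normalizeCPM(m))

  set.seed(22)
  r <- toyCounts(matrix(rpois(200, 5) + 1, 20, 10))
  cpm <- normalizeCPM(r)
  # independent elementwise oracle
  oracle <- r
  for (j in seq_len(ncol(r))) for (i in seq_len(nrow(r)))
    oracle[i, j] <- 1e6 * r[i, j] / sum(r[, j])
  expect_equal(cpm, oracle)
  expect_lt(max(abs(colSums(cpm) - 1e6)) / 1e6, 1e-9)

  m0 <- toyCounts(cbind(c(1, 2), c(0, 0)))
  expect_error(normalizeCPM(m0), "zero total")
})

test_that("filterCellTypes drops states below the cell-count threshold", {
  ann <- rbind(toyAnnotations(sprintf("a%02d", 1:20), cell_type = "big"),
               toyAnnotations(sprintf("b%02d", 1:19), cell_type = "small"))
  states <- suppressMessages(filterCellTypes(ann, min_cells = 20))
  expect_identical(states$cell_type, "big")
  expect_identical(states$n_cells, 20L)

  all_states <- suppressMessages(filterCellTypes(ann, min_cells = 1))
  expect_identical(nrow(all_states), 2L)

  expect_error(suppressMessages(filterCellTypes(ann, min_cells = 100)),
               "no cell state")
})

test_that("filterCellTypes equals brute-force group tallying on random annotations", {
  set.seed(23)
  ann <- data.frame(cell_id = sprintf("c%03d", 1:200),
                    tissue = sample(c("liver", "lung"), 200, TRUE),
                    cell_type = sample(c("T", "B", "M"), 200, TRUE),
                    stage = sample(c("fetal", "adult"), 200, TRUE),
                    donor = "d1", stringsAsFactors = FALSE)
  states <- suppressMessages(filterCellTypes(ann, min_cells = 15))
  key <- paste(ann$tissue, ann$cell_type, ann$stage, sep = ":")
  oracle <- sort(names(which(table(key) >= 15)))
  expect_identical(states$cell_state, oracle)
})

test_that("mega replicates average the sampled cells and are seed-reproducible", {
  sim <- toyReference(n_genes = 100, n_cells = 10, K_fetal = 4, K_adult = 4,
                      seed = 31)
  hq <- suppressMessages(filterCells(sim$reference, min_umi = 1))
  cpm <- normalizeCPM(hq)
  reps <- suppressMessages(makeMegaReplicates(cpm, hq, n_replicates = 10,
                                              seed = 5))
  expect_identical(ncol(reps), 8L * 10L)
  expect_identical(max(SummarizedExperiment::colData(reps)$replicate), 10L)
  # every profile equals the mean CPM over its recorded member cells
  members <- S4Vectors::metadata(reps)$members
  for (j in c(1L, 17L, 80L)) {
    expect_equal(unname(SummarizedExperiment::assay(reps)[, j]),
                 unname(rowMeans(cpm[, members[[j]], drop = FALSE])))
  }
  reps2 <- suppressMessages(makeMegaReplicates(cpm, hq, n_replicates = 10,
                                               seed = 5))
  expect_identical(SummarizedExperiment::assay(reps),
                   SummarizedExperiment::assay(reps2))
  reps3 <- suppressMessages(makeMegaReplicates(cpm, hq, n_replicates = 10,
                                               seed = 6))
  expect_false(identical(S4Vectors::metadata(reps)$members,
                         S4Vectors::metadata(reps3)$members))
})

test_that("a 2-cell state at fraction 0.5 yields single-cell replicates", {
  m <- toyCounts(matrix(c(10, 0, 5, 5, 8, 2, 1, 9), nrow = 2),
                 cells = c("x1", "x2", "y1", "y2"))
  ann <- rbind(toyAnnotations(c("x1", "x2"), cell_type = "X"),
               toyAnnotations(c("y1", "y2"), cell_type = "Y"))
  cpm <- normalizeCPM(m)
  reps <- suppressMessages(makeMegaReplicates(cpm, ann, n_replicates = 6,
                                              fraction = 0.5, seed = 9))
  members <- S4Vectors::metadata(reps)$members
  for (j in seq_len(ncol(reps))) {
    expect_length(members[[j]], 1L)
    expect_equal(unname(SummarizedExperiment::assay(reps)[, j]),
                 unname(cpm[, members[[j]]]))
  }
  # fraction too small for a draw
  expect_error(suppressMessages(
    makeMegaReplicates(cpm, ann, fraction = 0.2, seed = 1)), "fraction")
})

test_that("replicate means concentrate around the state mean (sampling oracle)", {
  sim <- toyReference(n_genes = 60, n_cells = 40, K_fetal = 1, K_adult = 1,
                      seed = 41)
  hq <- suppressMessages(filterCells(sim$reference, min_umi = 1))
  cpm <- normalizeCPM(hq)
  ann <- SummarizedExperiment::colData(hq)
  state_cells <- colnames(hq)[ann$stage == "fetal"]
  state_mean <- rowMeans(cpm[, state_cells])
  reps <- suppressMessages(makeMegaReplicates(cpm, hq, n_replicates = 10,
                                              seed = 2))
  cs <- SummarizedExperiment::colData(reps)$cell_state
  fetal_cols <- grepl(":fetal$", cs)
  rep_mean <- rowMeans(SummarizedExperiment::assay(reps)[, fetal_cols])
  # direct Monte-Carlo oracle for the SE of a mean of 10 half-samples
  set.seed(77)
  draws <- replicate(2000, rowMeans(vapply(1:10, function(r)
    rowMeans(cpm[, sample(state_cells, 20), drop = FALSE]),
    numeric(nrow(cpm)))))
  se <- apply(draws, 1L, sd)
  expect_true(all(abs(rep_mean - state_mean) < pmax(6 * se, 1e-6)))
})

test_that("signature selection honors perfect separation, top-N truncation and adjusted-p gating", {
  set.seed(51)
  n_genes <- 300
  reps_per <- 10
  # two states; first 250 genes strongly up in state A, none in state B
  a <- matrix(rlnorm(n_genes * reps_per, 2, 0.1), n_genes, reps_per)
  b <- matrix(rlnorm(n_genes * reps_per, 2, 0.1), n_genes, reps_per)
  up <- 1:250
  a[up, ] <- a[up, ] * (10 + seq_along(up) / 25)  # distinct fold changes
  prof <- cbind(a, b)
  rownames(prof) <- sprintf("G%03d", seq_len(n_genes))
  reps <- MegaReplicates(prof, cell_state = rep(c("T:A:fetal", "T:B:adult"),
                                                each = reps_per),
                         stage = rep(c("fetal", "adult"), each = reps_per),
                         replicate = rep(1:reps_per, 2))
  tab <- selectSignatureGenes(reps, top_n = 200, alpha_adj = 0.01)
  selA <- tab$gene[tab$selected & tab$cell_state == "T:A:fetal"]
  expect_length(selA, 200L)
  # the 200 largest log2FC among eligible genes
  sub <- tab[tab$cell_state == "T:A:fetal" & tab$eligible, ]
  oracle <- sub$gene[order(-sub$log2fc, sub$p_adj, sub$gene)][1:200]
  expect_setequal(selA, oracle)
  expect_true(all(tab$p_adj[tab$selected] < 0.01))

  # a gene positive in all focal replicates and 0 elsewhere has maximal U
  prof2 <- prof
  prof2[1, ] <- c(rep(500, reps_per), rep(0, reps_per))
  reps2 <- MegaReplicates(prof2, rep(c("T:A:fetal", "T:B:adult"), each = reps_per),
                          rep(c("fetal", "adult"), each = reps_per),
                          rep(1:reps_per, 2))
  tab2 <- selectSignatureGenes(reps2, top_n = 200)
  row1 <- tab2[tab2$gene == "G001" & tab2$cell_state == "T:A:fetal", ]
  expect_equal(row1$U, reps_per^2)
  expect_true(row1$selected)
})

test_that("Mann-Whitney U and exact p match exhaustive enumeration on 3-vs-3 toys", {
  cases <- list(
    list(x = c(9.1, 7.3, 8.2), y = c(1.2, 3.4, 2.2)),
    list(x = c(5.0, 1.0, 4.0), y = c(2.0, 3.0, 6.0)),
    list(x = c(2.5, 2.6, 2.7), y = c(2.4, 2.8, 2.9)))
  for (cs in cases) {
    prof <- rbind(c(cs$x, cs$y))
    rownames(prof) <- "G1"
    reps <- MegaReplicates(rbind(G1 = c(cs$x, cs$y), G2 = rnorm(6) + 10),
                           rep(c("T:A:fetal", "T:B:adult"), each = 3),
                           rep(c("fetal", "adult"), each = 3), rep(1:3, 2))
    tab <- selectSignatureGenes(reps, top_n = 10, alpha_adj = 1)
    got <- tab[tab$gene == "G1" & tab$cell_state == "T:A:fetal", ]
    oracle <- enumMannWhitneyP(cs$x, cs$y)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p, oracle$p)
    # and against the standard reference implementation
    wt <- wilcox.test(cs$x, cs$y, alternative = "greater", exact = TRUE)
    expect_equal(got$p, wt$p.value)
  }
})

test_that("the normal-approximation path agrees with wilcox.test on larger tied groups", {
  set.seed(61)
  x <- round(rlnorm(10, 3, 1))
  y <- round(rlnorm(30, 2.8, 1))
  prof <- rbind(G1 = c(x, y), G2 = rnorm(40) + 50)
  reps <- MegaReplicates(prof,
                         rep(c("T:A:fetal", "T:B:adult"), c(10, 30)),
                         rep(c("fetal", "adult"), c(10, 30)),
                         c(1:10, 1:30))
  tab <- selectSignatureGenes(reps, top_n = 10, alpha_adj = 1)
  got <- tab[tab$gene == "G1" & tab$cell_state == "T:A:fetal", ]
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                     exact = FALSE, correct = TRUE))
  expect_equal(got$U, unname(wt$statistic))
  expect_equal(got$p, wt$p.value, tolerance = 1e-12)
})

test_that("exclusions are applied before top-N truncation and promote next-ranked genes", {
  set.seed(71)
  n_genes <- 50
  a <- matrix(rlnorm(n_genes * 5, 2, 0.05), n_genes, 5)
  b <- matrix(rlnorm(n_genes * 5, 2, 0.05), n_genes, 5)
  a[1:30, ] <- a[1:30, ] * (5 + (30:1))  # G001 highest FC, descending
  prof <- cbind(a, b)
  rownames(prof) <- sprintf("G%03d", seq_len(n_genes))
  reps <- MegaReplicates(prof, rep(c("T:A:fetal", "T:B:adult"), each = 5),
                         rep(c("fetal", "adult"), each = 5), rep(1:5, 2))
  tab <- selectSignatureGenes(reps, top_n = 10, alpha_adj = 0.05)

  expect_identical(applyExclusions(tab, NULL), tab)
  expect_identical(applyExclusions(tab, list()), tab)

  sel_before <- tab$gene[tab$selected & tab$cell_state == "T:A:fetal"]
  excl <- list(cell_cycle = sel_before[1:2])
  tab2 <- suppressMessages(applyExclusions(tab, excl))
  sel_after <- tab2$gene[tab2$selected & tab2$cell_state == "T:A:fetal"]
  expect_false(any(excl$cell_cycle %in% sel_after))
  expect_length(sel_after, 10L)  # quota refilled from next-ranked genes

  # brute force: filter the gene universe, re-rank, truncate
  sub <- tab[tab$cell_state == "T:A:fetal" & tab$eligible &
               !tab$gene %in% excl$cell_cycle, ]
  oracle <- sub$gene[order(-sub$log2fc, sub$p_adj, sub$gene)][1:10]
  expect_setequal(sel_after, oracle)
})

test_that("buildSignatureMatrix pools per-state mean CPM over all cells", {
  sim <- toyReference(n_genes = 120, n_cells = 15, K_fetal = 4, K_adult = 4,
                      seed = 81)
  hq <- suppressMessages(filterCells(sim$reference, min_umi = 1))
  cpm <- normalizeCPM(hq)
  reps <- suppressMessages(makeMegaReplicates(cpm, hq, seed = 3))
  tab <- selectSignatureGenes(reps, top_n = 15)
  sig <- buildSignatureMatrix(cpm, hq, tab)
  genes <- sort(unique(tab$gene[tab$selected]))
  expect_identical(rownames(sig), genes)
  expect_identical(ncol(sig), 8L)
  # every entry equals an independently computed group mean
  ann <- SummarizedExperiment::colData(hq)
  for (st in cellStates(sig)[c(1, 5)]) {
    parts <- strsplit(st, ":")[[1]]
    cells <- colnames(hq)[ann$tissue == parts[1] &
                            ann$cell_type == parts[2] & ann$stage == parts[3]]
    expect_equal(unname(SummarizedExperiment::assay(sig)[, st]),
                 unname(rowMeans(cpm[genes, cells])))
  }
  # one state, one cell: signature column equals that cell's CPM
  one <- cpm[, 1, drop = FALSE]
  ann1 <- toyAnnotations(colnames(one), cell_type = "solo", stage = "fetal")
  tab1 <- tab[tab$selected, ]
  tab1$cell_state <- "liver:solo:fetal"
  class(tab1) <- class(tab)
  attributes(tab1)[c("top_n", "alpha_adj")] <-
    attributes(tab)[c("top_n", "alpha_adj")]
  sig1 <- buildSignatureMatrix(one, ann1, tab1)
  expect_equal(unname(SummarizedExperiment::assay(sig1)[, 1]),
               unname(one[rownames(sig1), 1]))

  # selected gene missing from the CPM matrix is an error
  expect_error(buildSignatureMatrix(cpm[-1, ], hq, tab,
                                    provenance = list()), "absent")
})

test_that("planted exclusive markers are recovered in full when they fit the quota", {
  sim <- toyReference(n_genes = 240, n_cells = 25, n_markers = 12, seed = 91)
  sig <- suppressMessages(buildSignature(sim$reference, min_umi = 1,
                                         min_cells = 5, top_n = 50, seed = 4))
  for (st in names(sim$truth$markers)) {
    state_id <- paste("synthetic", st, sim$truth$stage[st], sep = ":")
    expect_true(all(sim$truth$markers[[st]] %in% rownames(sig)),
                label = paste("markers of", state_id, "in signature"))
  }
})

test_that("the full signature build is deterministic given input and seed", {
  sim <- toyReference(n_genes = 100, n_cells = 12, seed = 14)
  s1 <- suppressMessages(buildSignature(sim$reference, min_umi = 1,
                                        min_cells = 5, top_n = 20, seed = 8))
  s2 <- suppressMessages(buildSignature(sim$reference, min_umi = 1,
                                        min_cells = 5, top_n = 20, seed = 8))
  expect_identical(SummarizedExperiment::assay(s1),
                   SummarizedExperiment::assay(s2))
})

test_that("ortholog mapping renames, drops and inverts cleanly", {
  set.seed(101)
  m <- toyCounts(matrix(runif(10), 5), genes = paste0("H", 1:5),
                 cells = c("s1", "s2"))
  idmap <- data.frame(source = paste0("H", 1:5), target = paste0("H", 1:5))
  expect_equal(suppressMessages(mapOrthologs(m, idmap)), m)

  part <- data.frame(source = c("H1", "H3", "H5"),
                     target = c("M1", "M3", "M5"))
  out <- suppressMessages(mapOrthologs(m, part))
  expect_identical(rownames(out), c("M1", "M3", "M5"))
  expect_equal(unname(out), unname(m[c(1, 3, 5), ]))

  # round trip through the inverse bijection restores the mapped rows
  inv <- data.frame(source = part$target, target = part$source)
  back <- suppressMessages(mapOrthologs(out, inv))
  expect_equal(back, m[c("H1", "H3", "H5"), ])

  bad <- data.frame(source = c("H1", "H1"), target = c("M1", "M2"))
  expect_error(mapOrthologs(m, bad), "one-to-one")
})
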
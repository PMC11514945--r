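# small fixture builders shared across test files

# tiny annotated reference: K states x n cells, planted exclusive markers
toyReference <- function(n_genes = 200, n_cells = 30, n_markers = 8,
                         K_fetal = 2, K_adult = 2, seed = 1) {
  simulateReference(n_fetal_states = K_fetal, n_adult_states = K_adult,
                    n_genes = n_genes, n_cells_per_state = n_cells,
                    n_markers_per_state = n_markers, seed = seed)
}

# deterministic counts matrix with dimnames
toyCounts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("G%02d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotations for a counts matrix: one state per `per` cells
toyAnnotations <- function(cells, tissue = "liver", cell_type = "Hep",
                           stage = "adult", donor = "d1") {
  data.frame(cell_id = cells, tissue = tissue, cell_type = cell_type,
             stage = stage, donor = donor, stringsAsFactors = FALSE)
}

# exhaustive one-sided Mann-Whitney null: all ways to assign the observed
# ranks to the focal group, P(U >= u_obs)
enumMannWhitneyP <- function(x, y) {
  v <- c(x, y)
  r <- rank(v)
  n1 <- length(x)
  idx <- utils::combn(length(v), n1)
  u_all <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(U = u_obs, p = mean(u_all >= u_obs))
}

# plug-in MI oracle via explicit 2 x n_bins contingency table
miOracle <- function(bin, member, n_bins) {
  tab <- table(factor(bin, levels = seq_len(n_bins)),
               factor(member, levels = c(FALSE, TRUE)))
  p <- tab / sum(tab)
  pb <- rowSums(p); pm <- colSums(p)
  s <- 0
  for (b in seq_len(nrow(p))) for (m in seq_len(ncol(p)))
    if (p[b, m] > 0) s <- s + p[b, m] * log2(p[b, m] / (pb[b] * pm[m]))
  as.numeric(s)
}
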
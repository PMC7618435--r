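# Shared fixtures: all data is built in code at test time.

# atlas from a dense cells x genes count matrix
dense_atlas <- function(m, cells = NULL) {
  atlas(Matrix::Matrix(m, sparse = TRUE), cells = cells)
}

# the standard two-parent study condition: a 1,000-gene panel at realistic
# per-gene coverage (~0.15 UMI/gene, as in ~3k UMI over ~20k genes), two
# 20-gene programs at fold 5, and an optional planted doublet subcluster
# hosted under parent A
two_parent_cfg <- function(seed, n_doublet = 50, mix_b = 0.5, fold = 5,
                           n_per_sample = 200, n_genes = 1000) {
  sim_config(
    n_genes = n_genes,
    cell_types = list(
      cell_type_spec("A", 1:20, program_fold = fold,
                     abundance_by_stage = c("15" = 1)),
      cell_type_spec("B", 21:40, program_fold = fold,
                     abundance_by_stage = c("15" = 1))),
    samples = list(sample_spec("s1", "d1", 15, "whole", n_per_sample),
                   sample_spec("s2", "d2", 15, "whole", n_per_sample)),
    doublet_clusters = if (n_doublet > 0)
      list(doublet_spec("A", "B", n_cells = n_doublet, mix_b = mix_b))
    else list(),
    library_size_mean = 150, seed = seed)
}

# stage/region gradient condition used for parameter-recovery checks
gradient_cfg <- function(seed, n_per_sample = 500) {
  mk_samples <- function() {
    out <- list(); i <- 0
    for (st in c(6, 11, 15, 20)) {
      for (rg in if (st >= 15) c("proximal", "distal") else "whole") {
        i <- i + 1
        out[[i]] <- sample_spec(sprintf("s%d_%s", st, substr(rg, 1, 1)),
                                paste0("d", st), st, rg, n_per_sample)
      }
    }
    out
  }
  sim_config(
    n_genes = 200,
    cell_types = list(
      cell_type_spec("early", 1:10, 5,
                     c("6" = 4, "11" = 2, "15" = 1, "20" = 0.5),
                     proximal_bias = 0.5),
      cell_type_spec("late", 11:20, 5,
                     c("6" = 0.5, "11" = 1, "15" = 2, "20" = 4),
                     proximal_bias = 0.5),
      cell_type_spec("prox", 21:30, 5,
                     c("6" = 1, "11" = 1, "15" = 1, "20" = 1),
                     proximal_bias = 0.8),
      cell_type_spec("dist", 31:40, 5,
                     c("6" = 1, "11" = 1, "15" = 1, "20" = 1),
                     proximal_bias = 0.25)),
    samples = mk_samples(),
    library_size_mean = 150, seed = seed)
}

# 12-cell toy matrix placing one cell/gene exactly on each QC boundary:
# c01 has exactly 200 genes (removed), c02 has 201 (kept); R5 is detected in
# exactly 5 cells (removed), R6 in 6 (kept); c03 sits at mito fraction
# exactly 0.20 (kept), c04 just above (removed)
qc_toy_atlas <- function() {
  genes <- c(sprintf("G%03d", 1:300), "R5", "R6", "MT-1")
  cells <- sprintf("c%02d", 1:12)
  m <- matrix(0L, 12, 303, dimnames = list(cells, genes))
  m["c01", 1:200] <- 1L
  m["c02", 1:201] <- 1L
  for (i in 3:12) m[i, 1:300] <- 1L
  m["c03", "G300"] <- 0L                       # 299 base genes for c03
  m[sprintf("c%02d", 3:7), "R5"] <- 1L         # 5 cells
  m[sprintf("c%02d", 3:8), "R6"] <- 1L         # 6 cells
  m[sprintf("c%02d", 5:12), "MT-1"] <- 1L      # keep MT-1 past the gene filter
  m["c03", "MT-1"] <- 75L                      # 75 / (299 + 1 + 75) = 0.20
  m["c04", "MT-1"] <- 76L                      # 76 / (300 + 1 + 76) > 0.20
  dense_atlas(m)
}

# independent oracle: two-sided Fisher exact p by hypergeometric enumeration
# (sum of table probabilities not exceeding the observed one)
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# independent oracle: BH step-up adjustment by direct enumeration
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# independent oracle: Pearson chi-squared statistic from first principles
chi2_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
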